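#' Fit a four-parameter logistic to a cumulative-angle series
#'
#' Least-squares fit of the cumulative signed angle by
#' `f(t) = c + (d - c) / (1 + exp(-b (t - a)))`, where `a` is the midpoint
#' time (min), `b` the steepness (1/min) and `c`, `d` the low and high
#' asymptotes (deg). Fitting uses deterministic multi-starts: `a` over the
#' observed time quartiles, `b` over {0.01, 0.05, 0.1, 0.5} per min, and
#' `c`/`d` from the first/last decile means; candidate fits are ranked by
#' residual RMS, ties broken by the lower `b`. Non-convergence of every start
#' is reported through the `converged` flag, never silently.
#'
#' @param series an [angle_series()], or a numeric vector of cumulative angles
#'   (then `times` is required).
#' @param times observation times in minutes (ignored when `series` is an
#'   `angle_series`).
#' @return object of class `logistic_fit`: list with `a`, `b`, `c`, `d`,
#'   `rms`, `converged`, `n`, `time_range`.
#' @export
fit_phase_logistic <- function(series, times = NULL) {
  if (inherits(series, "angle_series")) {
    y <- series$cum_deg
    t <- series$time_min
  } else {
    y <- as.numeric(series)
    t <- as.numeric(times)
  }
  stopifnot(length(y) == length(t))
  fail <- structure(
    list(
      a = NA_real_, b = NA_real_, c = NA_real_, d = NA_real_,
      rms = NA_real_, converged = FALSE, n = length(y),
      time_range = range(t)
    ),
    class = "logistic_fit"
  )
  if (length(y) < 10) {
    return(fail)
  }
  k <- max(1L, floor(length(y) / 10))
  c0 <- mean(head(y, k))
  d0 <- mean(tail(y, k))
  if (abs(d0 - c0) < 1e-6 || sd(y) < 1e-9) {
    # asymptotes indistinguishable: b unidentifiable
    return(fail)
  }
  dat <- data.frame(t = t, y = y)
  starts <- expand.grid(
    a = unname(quantile(t, c(0.25, 0.5, 0.75))),
    b = c(0.01, 0.05, 0.1, 0.5)
  )
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ c + (d - c) / (1 + exp(-b * (t - a))),
        data = dat,
        start = list(a = starts$a[i], b = starts$b[i], c = c0, d = d0),
        lower = c(a = -Inf, b = 1e-6, c = -Inf, d = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL,
      warning = function(w) NULL
    )
    if (is.null(fit)) next
    p <- coef(fit)
    rms <- sqrt(mean(residuals(fit)^2))
    cand <- list(
      a = unname(p["a"]), b = unname(p["b"]),
      c = unname(p["c"]), d = unname(p["d"]), rms = rms
    )
    if (is.null(best) ||
      cand$rms < best$rms - 1e-12 ||
      (abs(cand$rms - best$rms) <= 1e-12 && cand$b < best$b)) {
      best <- cand
    }
  }
  if (is.null(best)) {
    return(fail)
  }
  structure(
    c(best, list(converged = TRUE, n = length(y), time_range = range(t))),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  if (!x$converged) {
    cat("logistic_fit: did not converge (n =", x$n, ")\n")
  } else {
    cat(sprintf(
      "logistic_fit: a=%.3f min, b=%.5f /min, c=%.3f deg, d=%.3f deg (rms %.3f deg, n=%d)\n",
      x$a, x$b, x$c, x$d, x$rms, x$n
    ))
  }
  invisible(x)
}

#' Evaluate a fitted four-parameter logistic
#'
#' @param fit a `logistic_fit`.
#' @param t times in minutes.
#' @return fitted cumulative angles in degrees.
#' @export
predict_logistic <- function(fit, t) {
  stopifnot(inherits(fit, "logistic_fit"), fit$converged)
  fit$c + (fit$d - fit$c) / (1 + exp(-fit$b * (t - fit$a)))
}

#' Phase boundaries from a logistic fit
#'
#' The rotation onset `Ic` and termination `Id` are the times where the
#' tangent line through the inflection point meets the low and high
#' asymptotes. For `f(t) = c + (d - c)/(1 + exp(-b (t - a)))` the tangent at
#' the inflection `t = a` has slope `b (d - c) / 4` and passes through
#' `(a, (c + d)/2)`, so it reaches `y = c` at `a - 2/b` and `y = d` at
#' `a + 2/b`. Boundaries falling outside the observed time range are clamped,
#' with a flag.
#'
#' @param fit a converged `logistic_fit`.
#' @param time_range optional length-2 numeric to clamp against; defaults to
#'   the fitted series' range; `NULL` disables clamping.
#' @return list with `Ic`, `Id` (minutes), `duration = Id - Ic`, and
#'   `clamped` flag.
#' @export
phase_boundaries <- function(fit, time_range = fit$time_range) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (!fit$converged) stop("cannot derive boundaries from a failed fit", call. = FALSE)
  if (!is.finite(fit$b) || fit$b <= 0) stop("steepness b must be > 0", call. = FALSE)
  ic <- fit$a - 2 / fit$b
  id <- fit$a + 2 / fit$b
  clamped <- FALSE
  if (!is.null(time_range)) {
    lo <- min(time_range)
    hi <- max(time_range)
    if (ic < lo || id > hi) clamped <- TRUE
    ic <- min(max(ic, lo), hi)
    id <- min(max(id, lo), hi)
  }
  list(Ic = ic, Id = id, duration = id - ic, clamped = clamped)
}
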