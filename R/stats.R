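#' Two-sample Anderson-Darling test
#'
#' Rank-based two-sample Anderson-Darling statistic
#' \eqn{A^2 = \frac{1}{N}\sum_{j=1}^{N-1}\frac{(N B_j - j n_1)^2}{j (N - j)}
#' \left(\frac{1}{n_1} + \frac{1}{n_2}\right)} computed over the pooled order
#' statistics (`B_j` counts first-sample observations among the `j` smallest
#' pooled values), with a permutation p-value: group labels are reshuffled
#' `n_perm` times and the p-value is the fraction of permuted statistics at
#' least as large as the observed one (add-one estimator). The statistic is
#' sensitive to any distributional difference, with extra weight in the tails.
#'
#' @param x,y numeric samples.
#' @param n_perm number of label permutations.
#' @return list with `statistic`, `p_value`, `n_perm`, `method`.
#' @export
ad_test <- function(x, y, n_perm = 1999) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  n1 <- length(x)
  n2 <- length(y)
  stopifnot(n1 >= 2, n2 >= 2)
  pooled <- c(x, y)
  lab <- rep(c(TRUE, FALSE), c(n1, n2))
  obs <- ad_stat(pooled, lab)
  perm <- replicate(n_perm, ad_stat(pooled, sample(lab)))
  list(
    statistic = obs,
    p_value = (1 + sum(perm >= obs)) / (n_perm + 1),
    n_perm = n_perm,
    method = "two-sample Anderson-Darling (permutation)"
  )
}

ad_stat <- function(pooled, is_first) {
  n <- length(pooled)
  n1 <- sum(is_first)
  n2 <- n - n1
  ord <- order(pooled)
  b <- cumsum(is_first[ord])[-n] # first-sample count among j smallest
  j <- seq_len(n - 1)
  sum((n * b - j * n1)^2 / (j * (n - j))) / n * (1 / n1 + 1 / n2)
}

#' Pairwise statistical comparison of genotype cohorts
#'
#' Reproduces the study's statistical battery on a per-pair metrics table
#' (see [analyze_pairs()]):
#' inversion frequency by a two-sided binomial test of each group against the
#' reference group's observed frequency; trajectory noise by the two-sample
#' Anderson-Darling test and a one-sided Wilcoxon-Mann-Whitney test
#' (alternative: the reference distribution is stochastically less than the
#' group's); onset, Phase-2 duration and final turn by unpaired two-sided
#' Student's t-tests; and the final-angle distribution (folded to 0-180
#' degrees) by a two-sample Kolmogorov-Smirnov test. Groups with fewer than
#' `min_n` observations for a metric are skipped with a reason.
#'
#' @param metrics data.frame from [analyze_pairs()] (columns `genotype`,
#'   `inverting`, `noise`, `noise_excluded`, `onset_min`, `duration_min`,
#'   `final_turn_deg`, `final_angle_0180_deg`).
#' @param reference reference genotype label (default `"wild-type"`).
#' @param min_n minimal per-group sample size (default 3).
#' @param n_perm permutations for the Anderson-Darling p-value.
#' @return data.frame with one row per (metric, comparison): columns `metric`,
#'   `reference`, `group`, `test`, `alternative`, `statistic`, `p_value`,
#'   `n_ref`, `n_grp`, `note`.
#' @export
compare_genotypes <- function(metrics, reference = "wild-type", min_n = 3,
                              n_perm = 1999) {
  stopifnot("genotype" %in% names(metrics))
  groups <- setdiff(unique(metrics$genotype), reference)
  if (!reference %in% metrics$genotype) {
    stop("reference genotype '", reference, "' absent from metrics", call. = FALSE)
  }
  if (length(groups) == 0) stop("need at least two genotypes", call. = FALSE)

  rows <- list()
  add <- function(metric, group, test, alternative, statistic, p, n_ref, n_grp,
                  note = NA_character_) {
    rows[[length(rows) + 1]] <<- data.frame(
      metric = metric, reference = reference, group = group, test = test,
      alternative = alternative, statistic = statistic, p_value = p,
      n_ref = n_ref, n_grp = n_grp, note = note, stringsAsFactors = FALSE
    )
  }

  ref <- metrics[metrics$genotype == reference, , drop = FALSE]
  for (g in groups) {
    grp <- metrics[metrics$genotype == g, , drop = FALSE]

    # inversion frequency vs the reference group's observed frequency
    if (nrow(ref) >= min_n && nrow(grp) >= min_n) {
      p_ref <- mean(ref$inverting)
      if (p_ref > 0 && p_ref < 1) {
        bt <- binom.test(sum(grp$inverting), nrow(grp), p = p_ref)
        add(
          "inversion_frequency", g, "binomial", "two.sided",
          unname(bt$statistic) / nrow(grp), bt$p.value, nrow(ref), nrow(grp)
        )
      } else {
        add(
          "inversion_frequency", g, "binomial", "two.sided", NA, NA,
          nrow(ref), nrow(grp), "reference frequency degenerate (0 or 1)"
        )
      }
    } else {
      add(
        "inversion_frequency", g, "binomial", "two.sided", NA, NA,
        nrow(ref), nrow(grp), "insufficient group size"
      )
    }

    # continuous metrics
    cont <- function(metric, col, sub = function(d) d) {
      xr <- sub(ref)[[col]]
      xg <- sub(grp)[[col]]
      xr <- xr[is.finite(xr)]
      xg <- xg[is.finite(xg)]
      list(xr = xr, xg = xg, ok = length(xr) >= min_n && length(xg) >= min_n)
    }
    noise_sub <- function(d) d[!d$noise_excluded, , drop = FALSE]
    nz <- cont("noise", "noise", noise_sub)
    if (nz$ok) {
      ad <- ad_test(nz$xr, nz$xg, n_perm = n_perm)
      add(
        "noise", g, "Anderson-Darling", "two.sided", ad$statistic, ad$p_value,
        length(nz$xr), length(nz$xg)
      )
      wt <- suppressWarnings(wilcox.test(nz$xr, nz$xg, alternative = "less"))
      add(
        "noise", g, "Wilcoxon-Mann-Whitney", "less (reference < group)",
        unname(wt$statistic), wt$p.value, length(nz$xr), length(nz$xg)
      )
    } else {
      add(
        "noise", g, "Anderson-Darling", "two.sided", NA, NA,
        length(nz$xr), length(nz$xg), "insufficient group size"
      )
    }

    tcols <- c(
      onset = "onset_min", duration = "duration_min",
      final_turn = "final_turn_deg"
    )
    for (lbl in names(tcols)) {
      cc <- cont(lbl, tcols[[lbl]])
      if (cc$ok) {
        tt <- t.test(cc$xr, cc$xg)
        add(
          lbl, g, "t-test (unpaired)", "two.sided", unname(tt$statistic),
          tt$p.value, length(cc$xr), length(cc$xg)
        )
      } else {
        add(
          lbl, g, "t-test (unpaired)", "two.sided", NA, NA,
          length(cc$xr), length(cc$xg), "insufficient group size"
        )
      }
    }

    fa <- cont("final_angle", "final_angle_0180_deg")
    if (fa$ok) {
      kt <- suppressWarnings(ks.test(fa$xr, fa$xg))
      add(
        "final_angle", g, "Kolmogorov-Smirnov", "two.sided",
        unname(kt$statistic), kt$p.value, length(fa$xr), length(fa$xg)
      )
    } else {
      add(
        "final_angle", g, "Kolmogorov-Smirnov", "two.sided", NA, NA,
        length(fa$xr), length(fa$xg), "insufficient group size"
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
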