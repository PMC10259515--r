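#' Wrap an angle difference to the minimal representative
#'
#' Maps any angle (degrees) to the half-open interval (-180, 180]. Used for
#' frame-to-frame angle changes under the assumption that no rotation exceeds
#' 180 degrees between consecutive observations.
#'
#' @param a numeric vector of angles in degrees.
#' @return numeric vector in (-180, 180].
#' @export
#' @examples
#' wrap_angle_180(c(350, -350, 180, -180))
wrap_angle_180 <- function(a) {
  w <- (a + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}

#' Reduce an angle to the undirected-axis range [0, 180)
#'
#' The inter-cell axis has no orientation, so positional angles that differ by
#' 180 degrees are equivalent; this folds any angle to `[0, 180)` by taking it
#' modulo 180.
#'
#' @param a numeric vector of angles in degrees.
#' @return numeric vector in `[0, 180)`.
#' @export
#' @examples
#' normalize_angle_0_180(c(210, 350, 90))
normalize_angle_0_180 <- function(a) {
  a %% 180
}

#' Circular mean of angles in degrees
#'
#' Unit-vector (resultant) mean; correct across the -180/180 branch cut where
#' an arithmetic mean is not.
#'
#' @param a numeric vector of angles in degrees.
#' @return mean angle in (-180, 180], or `NA` if the resultant length is
#'   numerically zero (antipodal inputs).
#' @export
circular_mean_deg <- function(a) {
  s <- mean(sin(a * pi / 180))
  c <- mean(cos(a * pi / 180))
  if (sqrt(s^2 + c^2) < 1e-12) {
    return(NA_real_)
  }
  atan2(s, c) * 180 / pi
}

#' First-quadrant deviation of the inter-cell axis from the A-P axis
#'
#' The axis through the two cells is undirected, so its deviation from the
#' horizontal (anteroposterior) axis is computed from the absolute components
#' of the connecting vector `v = pos_a - pos_b`, which folds all angles into
#' `[0, 90]`.
#'
#' @param pos_a,pos_b numeric length-2 vectors (x, y) of the two cell
#'   positions, in any common units.
#' @return angle in degrees, in `[0, 90]`.
#' @export
#' @examples
#' final_angle_first_quadrant(c(1, 0), c(-1, 0)) # 0
#' final_angle_first_quadrant(c(0, 1), c(0, -1)) # 90
final_angle_first_quadrant <- function(pos_a, pos_b) {
  v <- as.numeric(pos_a) - as.numeric(pos_b)
  if (all(abs(v) < 1e-12)) {
    stop("coincident positions: axis angle undefined", call. = FALSE)
  }
  atan2(abs(v[2]), abs(v[1])) * 180 / pi
}
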