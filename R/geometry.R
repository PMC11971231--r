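# Target geometry: spherical sites under mu-randomness.

# Canonical (diameter, electron cut-off) pairs: the cut-off Delta is the
# electron energy whose penetration range equals the mean chord 2d/3.
.ml_delta_table <- data.frame(
  d_nm = c(10, 100, 1000),
  delta_keV = c(0.180, 1.37, 5.56)
)

#' Spherical target site
#'
#' A liquid-water sphere of diameter `d_nm` with mean chord length
#' 2d/3 (mu-randomness) and an electron cut-off energy Delta whose range
#' equals the mean chord.  For the canonical diameters 10, 100 and
#' 1000 nm the bundled Delta constants (0.180, 1.37, 5.56 keV) are used;
#' other diameters interpolate log-log between them (an approximation of
#' the range-inversion, flagged by a message).
#'
#' @param d_nm Sphere diameter in nm, positive.
#' @param delta_keV Optional explicit cut-off override, keV.
#' @return Object of class `target_sphere` with fields `d_nm`, `lbar_nm`,
#'   `lbar_um`, `delta_keV`.
#' @export
target_sphere <- function(d_nm, delta_keV = NULL) {
  stopifnot(length(d_nm) == 1, is.finite(d_nm))
  if (d_nm <= 0) stop("diameter must be positive")
  if (is.null(delta_keV)) {
    hit <- match(d_nm, .ml_delta_table$d_nm)
    if (!is.na(hit)) {
      delta_keV <- .ml_delta_table$delta_keV[hit]
    } else {
      lx <- log(.ml_delta_table$d_nm); ly <- log(.ml_delta_table$delta_keV)
      delta_keV <- exp(.interp_lin_extrap(lx, ly, log(d_nm)))
      message(sprintf(
        "cut-off for d = %g nm interpolated log-log from canonical values: %.4g keV",
        d_nm, delta_keV))
    }
  }
  stopifnot(delta_keV > 0)
  structure(list(d_nm = d_nm, lbar_nm = 2 * d_nm / 3,
                 lbar_um = 2 * d_nm / 3 * 1e-3, delta_keV = delta_keV),
            class = "target_sphere")
}

# Piecewise-linear interpolation with linear extrapolation from end slopes.
.interp_lin_extrap <- function(x, y, x0) {
  n <- length(x)
  if (x0 <= x[1]) return(y[1] + (y[2] - y[1]) / (x[2] - x[1]) * (x0 - x[1]))
  if (x0 >= x[n]) return(y[n] + (y[n] - y[n - 1]) / (x[n] - x[n - 1]) * (x0 - x[n]))
  stats::approx(x, y, xout = x0)$y
}

#' @export
print.target_sphere <- function(x, ...) {
  cat(sprintf("water sphere d = %g nm: mean chord %.4g nm, Delta = %.4g keV\n",
              x$d_nm, x$lbar_nm, x$delta_keV))
  invisible(x)
}

#' Chord-length distribution of a sphere under mu-randomness
#'
#' The chord pdf is c(l) = 2l/d^2 on (0, d], with mean 2d/3 and
#' diameter-independent relative variance 1/8.  Sampling uses the inverse
#' CDF l = d sqrt(u).
#'
#' @param sphere A [target_sphere()].
#' @return List with `pdf`, `cdf`, `quantile`, `sampler` (function of n,
#'   uses the current RNG stream), `mean_nm`, `relative_variance`.
#' @export
chord_distribution <- function(sphere) {
  stopifnot(inherits(sphere, "target_sphere"))
  d <- sphere$d_nm
  list(
    pdf = function(l) ifelse(l > 0 & l <= d, 2 * l / d^2, 0),
    cdf = function(l) pmin(1, pmax(0, (l / d)^2)),
    quantile = function(u) d * sqrt(u),
    sampler = function(n) d * sqrt(stats::runif(n)),
    mean_nm = 2 * d / 3,
    second_moment_nm2 = d^2 / 2,
    relative_variance = 1 / 8
  )
}
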