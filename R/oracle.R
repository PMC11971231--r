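# Seeded Monte Carlo twin of the direct-event analytic machinery: sample
# chords and per-chord energy deposits, build empirical lineal-energy
# moments with standard errors, and so verify the analytic spectra.

#' Monte Carlo simulation of direct events
#'
#' Per history, draws a chord from c(l) = 2l/d^2 (inverse CDF), then an
#' energy deposit from the per-chord straggling distribution (mean
#' f_ion x LET x l, relative variance delta2 / mean; the logistic family
#' is sampled with rejection of negatives, i.e. exactly from the
#' truncated law), and records y = x / mean chord.  Sampling order is
#' fixed (all chords, then all deposits) so runs are replayable; the same
#' seed reproduces the sample vector bit-for-bit.
#'
#' @param sphere A [target_sphere()].
#' @param kin A [proton_kinematics()].
#' @param LET_keV_um Stopping power, keV/um.
#' @param delta2_keV Straggling factor, keV.
#' @param family Straggling family.
#' @param seed Integer seed.
#' @param n Number of histories, >= 1000.
#' @return Object of class `oracle_run` with the sample vector `y`,
#'   empirical `yF`, `yD` and delta-method standard errors `se_yF`,
#'   `se_yD`.
#' @export
simulate_direct <- function(sphere, kin, LET_keV_um, delta2_keV,
                            family = "lognormal", seed, n = 1e5) {
  stopifnot(inherits(sphere, "target_sphere"),
            inherits(kin, "proton_kinematics"))
  if (!is.finite(seed) || length(seed) != 1) stop("invalid seed")
  n <- as.integer(n)
  if (is.na(n) || n < 1000) stop("need at least 1000 histories")
  fi <- f_ion(kin, sphere$delta_keV)
  y <- .with_preserved_rng(seed, function() {
    l_um <- sphere$d_nm * 1e-3 * sqrt(stats::runif(n))   # chords first
    mean_l <- fi * LET_keV_um * l_um
    Vl <- delta2_keV / mean_l
    x <- switch(family,                                  # then deposits
      lognormal = {
        sig <- sqrt(log(1 + Vl))
        stats::rlnorm(n, log(mean_l) - sig^2 / 2, sig)
      },
      erlang_gamma = stats::rgamma(n, shape = 1 / Vl,
                                   rate = 1 / (Vl * mean_l)),
      logistic = {
        s <- sqrt(3) / pi * mean_l * sqrt(Vl)
        v <- stats::rlogis(n, mean_l, s)
        bad <- which(v < 0)
        while (length(bad)) {                # reject negatives, redraw
          v[bad] <- stats::rlogis(length(bad), mean_l[bad], s[bad])
          bad <- bad[v[bad] < 0]
        }
        v
      },
      stop("unknown family: ", family))
    x / sphere$lbar_um
  })
  m1 <- mean(y); m2 <- mean(y^2)
  yD <- m2 / m1
  # delta method for the ratio of sample moments
  v11 <- stats::var(y); v22 <- stats::var(y^2); v12 <- stats::cov(y, y^2)
  se_yD <- sqrt((v22 / m1^2 - 2 * m2 * v12 / m1^3 + m2^2 * v11 / m1^4) / n)
  structure(list(seed = seed, n = n, family = family, y = y,
                 yF = m1, yD = yD,
                 se_yF = sqrt(v11 / n), se_yD = se_yD,
                 T_MeV = kin$T_MeV, d_nm = sphere$d_nm,
                 f_ion = fi, LET_keV_um = LET_keV_um,
                 delta2_keV = delta2_keV),
            class = "oracle_run")
}

#' @export
print.oracle_run <- function(x, ...) {
  cat(sprintf(
    "oracle run (%s, n = %d, seed %s): yF = %.4g +/- %.2g, yD = %.4g +/- %.2g keV/um\n",
    x$family, x$n, format(x$seed), x$yF, x$se_yF, x$yD, x$se_yD))
  invisible(x)
}
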