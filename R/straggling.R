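# Straggling factor delta2, restricted-LET fraction f_ion, relative
# variance budget, and the parametric energy-loss straggling distributions.

#' Straggling factor (dose-weighted single-collision energy deposit)
#'
#' delta2 is the ratio of the second to the first (E + B_n)-weighted
#' moments of the ionization DICS, restricted to deposits below the
#' geometric cut-off Delta.  Methods:
#' \describe{
#'   \item{rpwba}{first-principles moments of the model's ionization DICS
#'     (the default; requires `model` and `kin`).}
#'   \item{kellerer}{\eqn{\Delta / (2 \ln(\Delta / I))}, the 1/E^2
#'     delta-ray-spectrum approximation.}
#'   \item{xapsos}{\eqn{0.195\,\Delta^{0.610}}.}
#'   \item{fitted}{\eqn{0.0074 + 0.174\,\Delta^{0.651}}, the single-Delta
#'     power-law summary of the rpwba values.}
#' }
#'
#' @param Delta_keV Cut-off energy in keV.
#' @param method One of "rpwba", "kellerer", "xapsos", "fitted".
#' @param model,kin Required for method "rpwba".
#' @param I_keV Mean excitation energy (keV) for method "kellerer".
#' @param density Quadrature densification factor (rpwba only).
#' @return delta2 in keV.
#' @export
delta2 <- function(Delta_keV, method = c("rpwba", "kellerer", "xapsos", "fitted"),
                   model = NULL, kin = NULL, I_keV = .ml_const$I_keV,
                   density = 1) {
  method <- match.arg(method)
  stopifnot(all(Delta_keV > 0))
  switch(method,
    kellerer = {
      if (any(Delta_keV <= I_keV))
        stop("Kellerer form requires Delta > I")
      Delta_keV / (2 * log(Delta_keV / I_keV))
    },
    xapsos = 0.195 * Delta_keV^0.610,
    fitted = 0.0074 + 0.174 * Delta_keV^0.651,
    rpwba = {
      stopifnot(inherits(model, "dielectric_model"),
                inherits(kin, "proton_kinematics"))
      vapply(Delta_keV, function(D) .delta2_rpwba(model, kin, D, density),
             numeric(1))
    })
}

.delta2_rpwba <- function(model, kin, Delta_keV, density = 1) {
  if (Delta_keV * 1e3 > kin$Emax_eV)
    stop(sprintf(
      "Delta = %g keV exceeds Emax = %g keV: restricted moments undefined",
      Delta_keV, kin$Emax_keV))
  key <- paste("d2", model$key, kin$T_MeV, Delta_keV, density, sep = "|")
  if (!is.null(.ml_cache[[key]])) return(.ml_cache[[key]])
  Delta_eV <- Delta_keV * 1e3
  shells <- list()
  for (j in which(model$kind == "ionization")) {
    # restriction on the single-collision deposit W = E + B_n <= Delta,
    # the reading consistent with both the chord-cut-off argument and the
    # Kellerer comparator; kinematic closure W <= Emax also applies
    E_hi <- min(Delta_eV, kin$Emax_eV) - model$B[j]
    if (E_hi <= 1e-2) next
    nE <- max(160, ceiling(36 * density * log10(E_hi / 1e-2)))
    E <- exp(seq(log(1e-2), log(E_hi), length.out = nE))
    v <- .dics_shell(model, kin, j, E, density)
    shells[[length(shells) + 1]] <-
      list(E = E, W = E + model$B[j], ds = v$long + v$trans)
  }
  num <- den <- 0
  for (s in shells) {
    num <- num + .trapz(log(s$E), s$W^2 * s$ds * s$E)
    den <- den + .trapz(log(s$E), s$W * s$ds * s$E)
  }
  out <- (num / den) * 1e-3             # eV -> keV
  .ml_cache[[key]] <- out
  out
}

#' Straggling factor from an explicit single-collision spectrum
#'
#' Moment ratio \eqn{\int W^2 w(W) dW / \int W w(W) dW} over deposits
#' W <= Delta for a user-supplied spectrum; the analytic counterpart used
#' by [delta2()] method "rpwba", exposed so toy spectra with closed-form
#' answers can exercise the same machinery.
#'
#' @param shells List of shells, each `list(B_eV =, dsdE = function(E))`
#'   giving the binding energy and differential spectrum in the ejected
#'   energy E.
#' @param Delta_keV Cut-off in keV (deposit W = E + B integrated over
#'   E in (0, Delta)).
#' @param E_min_eV Lower quadrature limit for E.
#' @param n Nodes per shell.
#' @return delta2 in keV.
#' @export
delta2_from_spectrum <- function(shells, Delta_keV, E_min_eV = 1e-2, n = 4000) {
  Delta_eV <- Delta_keV * 1e3
  num <- den <- 0
  for (s in shells) {
    if (Delta_eV <= E_min_eV) next
    E <- exp(seq(log(E_min_eV), log(Delta_eV), length.out = n))
    W <- E + s$B_eV
    ds <- s$dsdE(E)
    num <- num + .trapz(log(E), W^2 * ds * E)
    den <- den + .trapz(log(E), W * ds * E)
  }
  (num / den) * 1e-3
}

#' Fraction of proton energy loss retained in the site
#'
#' Restricted-to-unrestricted LET ratio with delta-ray corrections,
#' \deqn{f_{ion} = \ln[E_{max}(\Delta + \Delta_1 + \Delta_2)/I^2] /
#'       (2 \ln[E_{max}/I])}
#' with \eqn{\Delta_1 + \Delta_2 = (1 - \Delta/E_{max})(I + \Delta)}.
#' Equals 1 exactly at Delta = Emax and is monotone nondecreasing in
#' Delta.
#'
#' @param kin A [proton_kinematics()].
#' @param Delta_keV Cut-off energy, keV, in (0, Emax].
#' @param I_keV Mean excitation energy, keV.
#' @return Fraction in (0, 1].
#' @export
f_ion <- function(kin, Delta_keV, I_keV = .ml_const$I_keV) {
  stopifnot(inherits(kin, "proton_kinematics"))
  Emax <- kin$Emax_keV
  if (any(Delta_keV <= 0) || any(Delta_keV > Emax))
    stop("Delta must lie in (0, Emax]")
  d12 <- (1 - Delta_keV / Emax) * (I_keV + Delta_keV)
  log(Emax * (Delta_keV + d12) / I_keV^2) / (2 * log(Emax / I_keV))
}

#' Relative-variance budget of the direct-event energy deposit
#'
#' Combines the chord-length relative variance (V_s = 1/8 for a sphere),
#' the LET-fluctuation variance (0 for the thin targets considered) and
#' the straggling variance V_delta = delta2 / mean deposit into the total
#' relative variance V, with mean deposit
#' \eqn{\bar\varepsilon = f_{ion} \times LET \times \bar l}.
#'
#' @param sphere A [target_sphere()].
#' @param kin A [proton_kinematics()].
#' @param LET_keV_um Unrestricted stopping power, keV/um.
#' @param delta2_keV Straggling factor, keV.
#' @param Vs Chord-length relative variance.
#' @param Vlet LET-fluctuation relative variance.
#' @return Object of class `variance_budget`.
#' @export
variance_budget <- function(sphere, kin, LET_keV_um, delta2_keV,
                            Vs = 0.125, Vlet = 0) {
  stopifnot(inherits(sphere, "target_sphere"),
            inherits(kin, "proton_kinematics"),
            LET_keV_um > 0, delta2_keV >= 0)
  fi <- f_ion(kin, sphere$delta_keV)
  eps <- fi * LET_keV_um * sphere$lbar_um
  Vd <- delta2_keV / eps
  structure(list(
    Vs = Vs, Vlet = Vlet, Vdelta = Vd,
    V = Vs + Vs * Vlet + Vd + Vlet,
    eps_keV = eps, delta2_keV = delta2_keV, f_ion = fi,
    LET_keV_um = LET_keV_um, T_MeV = kin$T_MeV, d_nm = sphere$d_nm
  ), class = "variance_budget")
}

#' Parametric energy-loss straggling distribution
#'
#' Builds the straggling law used for direct events, matched to a target
#' mean and relative variance:
#' \describe{
#'   \item{lognormal}{\eqn{\sigma = \sqrt{\ln(1+V)}},
#'     \eqn{\mu = \ln\bar\varepsilon - \sigma^2/2}.}
#'   \item{erlang_gamma}{rate \eqn{\lambda = 1/(V\bar\varepsilon)}, shape
#'     \eqn{\kappa = 1/V}; the Erlang factorial is generalized to the
#'     Gamma function since \eqn{\kappa} is non-integer for realistic V.}
#'   \item{logistic}{location \eqn{\mu = \bar\varepsilon}, scale
#'     \eqn{s = (\sqrt3/\pi)\bar\varepsilon\sqrt V}, truncated at zero and
#'     renormalized (its untruncated support includes negative deposits).}
#' }
#'
#' @param family "lognormal", "erlang_gamma" or "logistic".
#' @param mean_keV Target (untruncated) mean deposit, keV.
#' @param relvar Target (untruncated) relative variance.
#' @return Object of class `straggling_distribution` with density `d`,
#'   cdf `p`, quantile `q`, sampler `r` (truncated where applicable),
#'   fields `params`, `truncated`, `trunc_mass` and the untruncated
#'   moments.
#' @export
make_straggling_distribution <- function(family = c("lognormal", "erlang_gamma",
                                                    "logistic"),
                                         mean_keV, relvar) {
  family <- match.arg(family)
  stopifnot(is.finite(mean_keV), is.finite(relvar), mean_keV > 0, relvar > 0)
  obj <- switch(family,
    lognormal = {
      sig <- sqrt(log(1 + relvar))
      mu <- log(mean_keV) - sig^2 / 2
      list(params = c(mu_lgn = mu, sigma_lgn = sig),
           d = function(x) stats::dlnorm(x, mu, sig),
           p = function(x) stats::plnorm(x, mu, sig),
           q = function(u) stats::qlnorm(u, mu, sig),
           r = function(n) stats::rlnorm(n, mu, sig),
           truncated = FALSE, trunc_mass = 0)
    },
    erlang_gamma = {
      lam <- 1 / (relvar * mean_keV)
      kap <- 1 / relvar
      list(params = c(lambda = lam, kappa = kap),
           d = function(x) stats::dgamma(x, shape = kap, rate = lam),
           p = function(x) stats::pgamma(x, shape = kap, rate = lam),
           q = function(u) stats::qgamma(u, shape = kap, rate = lam),
           r = function(n) stats::rgamma(n, shape = kap, rate = lam),
           truncated = FALSE, trunc_mass = 0)
    },
    logistic = {
      mu <- mean_keV
      s <- sqrt(3) / pi * mean_keV * sqrt(relvar)
      Z <- 1 - stats::plogis(0, mu, s)     # mass kept after truncation at 0
      list(params = c(mu_log = mu, s = s),
           d = function(x) ifelse(x >= 0, stats::dlogis(x, mu, s) / Z, 0),
           p = function(x) ifelse(x >= 0,
                                  (stats::plogis(x, mu, s) -
                                   stats::plogis(0, mu, s)) / Z, 0),
           q = function(u) stats::qlogis(stats::plogis(0, mu, s) + u * Z,
                                         mu, s),
           r = function(n) {
             # rejection of negatives: exact truncated sampling
             out <- numeric(0)
             while (length(out) < n) {
               x <- stats::rlogis(n - length(out), mu, s)
               out <- c(out, x[x >= 0])
             }
             out
           },
           truncated = TRUE, trunc_mass = stats::plogis(0, mu, s))
    })
  obj$family <- family
  obj$mean_keV <- mean_keV          # untruncated target moments
  obj$relvar <- relvar
  class(obj) <- "straggling_distribution"
  obj
}

#' Moments of a straggling distribution after truncation
#'
#' First and second moments of the (possibly zero-truncated) density by
#' quadrature; for untruncated families these recover the target mean and
#' relative variance to quadrature accuracy.
#'
#' @param dist A [make_straggling_distribution()] object.
#' @param n Quadrature nodes.
#' @return List with `m1`, `m2`, `relvar`.
#' @export
straggling_moments <- function(dist, n = 20000) {
  lo <- dist$q(1e-9); hi <- dist$q(1 - 1e-9)
  lo <- max(lo, hi * 1e-9)
  x <- exp(seq(log(lo), log(hi), length.out = n))
  f <- dist$d(x)
  m0 <- .trapz(log(x), f * x)
  m1 <- .trapz(log(x), x * f * x) / m0
  m2 <- .trapz(log(x), x^2 * f * x) / m0
  list(m1 = m1, m2 = m2, relvar = m2 / m1^2 - 1)
}
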