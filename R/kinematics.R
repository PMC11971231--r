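#' Relativistic proton kinematics
#'
#' Lorentz factor, squared scaled velocity and the maximum delta-electron
#' energy for a proton of kinetic energy `T_MeV`.  The exact two-body
#' maximum
#' \deqn{E_{max} = 2 m c^2 \beta^2 \gamma^2 /
#'       [1 + 2\gamma(m/M) + (m/M)^2]}
#' is the default; the familiar \eqn{2 m c^2 \beta^2 \gamma^2}
#' approximation is also carried (it always exceeds the exact value).
#'
#' @param T_MeV Proton kinetic energy in MeV, positive.
#' @return Object of class `proton_kinematics` with fields `T_MeV`,
#'   `beta2`, `gamma`, `Emax_keV` (exact), `Emax_approx_keV`.
#' @export
proton_kinematics <- function(T_MeV) {
  stopifnot(length(T_MeV) == 1, is.finite(T_MeV))
  if (T_MeV <= 0) stop("proton kinetic energy must be positive")
  mc2 <- .ml_const$mc2_eV; Mc2 <- .ml_const$Mc2_eV
  T_eV <- T_MeV * 1e6
  gamma <- 1 + T_eV / Mc2
  beta2 <- 1 - 1 / gamma^2
  b2g2 <- gamma^2 - 1
  r <- mc2 / Mc2
  Emax_approx <- 2 * mc2 * b2g2
  Emax <- Emax_approx / (1 + 2 * gamma * r + r^2)
  structure(list(T_MeV = T_MeV, T_eV = T_eV, beta2 = beta2, gamma = gamma,
                 Emax_eV = Emax, Emax_keV = Emax * 1e-3,
                 Emax_approx_keV = Emax_approx * 1e-3,
                 mc2_MeV = mc2 * 1e-6, Mc2_MeV = Mc2 * 1e-6),
            class = "proton_kinematics")
}

#' @export
print.proton_kinematics <- function(x, ...) {
  cat(sprintf(
    "proton %.4g MeV: beta^2 = %.5f, gamma = %.5f, Emax = %.4g keV\n",
    x$T_MeV, x$beta2, x$gamma, x$Emax_keV))
  invisible(x)
}

#' Recoil-energy limits of an inelastic proton collision
#'
#' Minimum and maximum recoil energy q transferable to the medium for a
#' total energy transfer W (W = E + B_n for ionization of shell n),
#' \deqn{q_{\pm} = \sqrt{[\,p c \pm p' c\,]^2 + (m c^2)^2} - m c^2}
#' with \eqn{pc = \sqrt{T(T + 2 M c^2)}} and \eqn{p'c} the outgoing proton
#' momentum.  The difference \eqn{pc - p'c} is evaluated in a
#' cancellation-free form so that q_min is accurate down to W of a few eV
#' at GeV proton energies.
#'
#' @param kin A [proton_kinematics()] object.
#' @param W_eV Energy transfer(s) in eV, 0 < W <= T.
#' @return List with vectors `q_min_eV`, `q_max_eV`.
#' @export
recoil_limits <- function(kin, W_eV) {
  stopifnot(inherits(kin, "proton_kinematics"))
  if (any(W_eV <= 0)) stop("energy transfer W must be positive")
  if (any(W_eV > kin$T_eV))
    stop("W exceeds the proton kinetic energy: transfer kinematically closed")
  mc2 <- .ml_const$mc2_eV; Mc2 <- .ml_const$Mc2_eV
  T <- kin$T_eV; Tr <- T - W_eV
  pc  <- sqrt(T * (T + 2 * Mc2))
  pcr <- sqrt(Tr * (Tr + 2 * Mc2))
  x_max <- pc + pcr
  # pc - pc' = [T(T+2M) - Tr(Tr+2M)] / (pc + pc') = W (2T - W + 2M) / (pc + pc')
  x_min <- W_eV * (2 * T - W_eV + 2 * Mc2) / x_max
  q_of <- function(x) x^2 / (sqrt(x^2 + mc2^2) + mc2)  # stable sqrt(x^2+m^2)-m
  list(q_min_eV = q_of(x_min), q_max_eV = q_of(x_max))
}
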