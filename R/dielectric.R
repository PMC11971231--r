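#' Oscillator channel of the liquid-water dielectric model
#'
#' One Drude-type channel of the energy-loss function (ELF).  Ionization
#' channels correspond to the molecular shells of water (1b1, 3a1, 1b2,
#' 2a1, 1a1) and carry a binding energy `threshold_eV`; excitation channels
#' correspond to the discrete electronic levels (A1B1, B1A1, Rydberg A+B,
#' Rydberg C+D, diffuse band) with `threshold_eV` equal to the transition
#' energy.
#'
#' @param kind "ionization" or "excitation".
#' @param label Unique channel name.
#' @param threshold_eV Binding (ionization) or transition (excitation)
#'   energy in eV; the channel contributes nothing below it.
#' @param amplitude Dimensionless Drude oscillator strength (electrons per
#'   molecule carried by the channel).
#' @param width_eV Drude damping width in eV.
#' @param resonance_eV Drude resonance energy in eV at zero recoil energy.
#' @return An object of class `oscillator_channel`.
#' @export
oscillator_channel <- function(kind = c("ionization", "excitation"), label,
                               threshold_eV, amplitude, width_eV, resonance_eV) {
  kind <- match.arg(kind)
  stopifnot(is.character(label), nzchar(label),
            threshold_eV > 0, amplitude >= 0, width_eV > 0, resonance_eV > 0)
  structure(list(kind = kind, label = label, threshold_eV = threshold_eV,
                 amplitude = amplitude, width_eV = width_eV,
                 resonance_eV = resonance_eV),
            class = "oscillator_channel")
}

#' Dielectric response model of liquid water
#'
#' Bundles a set of Drude oscillator channels into a model of the
#' energy-loss function Im\[-1/eps(W, q)\].  Each channel contributes a
#' Drude term
#' \deqn{f_j E_p^2 \gamma_j W / [(E_j(q)^2 - W^2)^2 + (\gamma_j W)^2]}
#' above its threshold, where \eqn{E_p} is the plasmon energy of the
#' electron gas at the model's molecular density.  Ionization resonances
#' disperse as \eqn{E_j(q) = E_j + q} (free-particle-like in the recoil
#' energy q); excitations are carried undispersed up to `excitation_q_cut_eV`
#' and excluded beyond it.
#'
#' Construction validates the model: at least one channel of each kind,
#' unique labels, non-negativity on a coarse grid, and the optical f-sum
#' rule (effective electron number within `sum_rule_tolerance` of 10 per
#' molecule).
#'
#' @param channels List of [oscillator_channel()] objects.
#' @param molecular_density_per_cm3 Molecules per cm^3 (unit-density water).
#' @param sum_rule_tolerance Allowed fractional deviation of the f-sum
#'   effective electron count from 10.
#' @param excitation_q_cut_eV Recoil energy beyond which excitation
#'   channels are dropped from q-integrals.
#' @param validate Set `FALSE` to skip the (quadrature) sum-rule check,
#'   e.g. for deliberately partial toy models in tests.
#' @return An object of class `dielectric_model`.
#' @export
dielectric_model <- function(channels,
                             molecular_density_per_cm3 = .ml_const$N_water,
                             sum_rule_tolerance = 0.10,
                             excitation_q_cut_eV = 100,
                             validate = TRUE) {
  stopifnot(length(channels) >= 1, molecular_density_per_cm3 > 0,
            sum_rule_tolerance > 0, excitation_q_cut_eV > 0)
  kinds <- vapply(channels, function(ch) ch$kind, character(1))
  labels <- vapply(channels, function(ch) ch$label, character(1))
  if (anyDuplicated(labels))
    stop("channel labels must be unique")
  if (validate && (!any(kinds == "ionization") || !any(kinds == "excitation")))
    stop("model needs at least one ionization and one excitation channel")
  model <- structure(list(
    kind      = kinds,
    label     = labels,
    B         = vapply(channels, function(ch) ch$threshold_eV, numeric(1)),
    f         = vapply(channels, function(ch) ch$amplitude, numeric(1)),
    gamma     = vapply(channels, function(ch) ch$width_eV, numeric(1)),
    Eres      = vapply(channels, function(ch) ch$resonance_eV, numeric(1)),
    N         = molecular_density_per_cm3,
    # squared plasma energy for ONE electron per molecule; amplitudes then
    # count electrons, so the f-sum integral recovers their total (~10)
    Ep2       = .ml_const$Ep2_coef * molecular_density_per_cm3,
    q_cut     = excitation_q_cut_eV,
    tol       = sum_rule_tolerance
  ), class = "dielectric_model")
  model$key <- paste(format(c(model$B, model$f, model$gamma, model$Eres,
                              model$N, model$q_cut), digits = 12),
                     collapse = ",")
  if (validate) {
    neff <- f_sum_electrons(model)
    if (abs(neff / 10 - 1) > sum_rule_tolerance)
      stop(sprintf(
        "optical f-sum gives %.3f electrons/molecule, outside 10 +/- %.0f%%",
        neff, 100 * sum_rule_tolerance))
    Wchk <- exp(seq(log(5), log(1e4), length.out = 200))
    if (any(optical_elf(model, Wchk) < 0))
      stop("optical ELF negative on validation grid")
  }
  model
}

#' @export
print.dielectric_model <- function(x, ...) {
  cat("Drude dielectric model of liquid water\n")
  cat(sprintf("  %d channels (%d ionization, %d excitation)\n",
              length(x$kind), sum(x$kind == "ionization"),
              sum(x$kind == "excitation")))
  cat(sprintf("  molecular density %.4g /cm^3, plasmon energy %.2f eV\n",
              x$N, sqrt(x$Ep2)))
  cat(sprintf("  f-sum effective electrons: %.3f / molecule\n",
              f_sum_electrons(x)))
  invisible(x)
}

# Per-channel ELF values: W and q vectors of equal length (or scalars).
# Returns a length(W) x n_channels matrix.
.elf_matrix <- function(model, W, q) {
  n <- max(length(W), length(q))
  W <- rep_len(W, n); q <- rep_len(q, n)
  out <- matrix(0, n, length(model$kind),
                dimnames = list(NULL, model$label))
  for (j in seq_along(model$kind)) {
    Ej <- if (model$kind[j] == "ionization") model$Eres[j] + q else model$Eres[j]
    v <- model$f[j] * model$Ep2 * model$gamma[j] * W /
      ((Ej^2 - W^2)^2 + (model$gamma[j] * W)^2)
    v[W < model$B[j]] <- 0
    if (model$kind[j] == "excitation") v[q > model$q_cut] <- 0
    out[, j] <- v
  }
  out
}

#' Optical energy-loss function of the model
#'
#' ELF at zero recoil energy, total or decomposed into channel
#' contributions (the total is their exact sum).
#'
#' @param model A [dielectric_model()].
#' @param W Energy transfer(s), eV; must be positive.
#' @param per_channel If `TRUE` return the full channel matrix.
#' @return Numeric vector (or matrix) of dimensionless ELF values.
#' @export
optical_elf <- function(model, W, per_channel = FALSE) {
  stopifnot(inherits(model, "dielectric_model"), all(W > 0))
  m <- .elf_matrix(model, W, 0)
  if (per_channel) m else rowSums(m)
}

#' Energy-loss function at finite recoil energy
#'
#' Extends the optical ELF to q > 0 via the model's dispersion relations;
#' `elf(model, W, 0)` reproduces [optical_elf()] exactly.
#'
#' @inheritParams optical_elf
#' @param q Recoil energy (eV), non-negative; recycled against `W`.
#' @export
elf <- function(model, W, q, per_channel = FALSE) {
  stopifnot(inherits(model, "dielectric_model"), all(W > 0))
  if (any(q < 0)) stop("negative recoil energy q")
  m <- .elf_matrix(model, W, q)
  if (per_channel) m else rowSums(m)
}

#' Effective electron number from the optical f-sum rule
#'
#' Evaluates \eqn{(2 / \pi E_p^2) \int W\,\mathrm{ELF}(W, 0)\, dW} by
#' quadrature; for a sane liquid-water parameterization the result is close
#' to 10 electrons per molecule.
#'
#' @param model A [dielectric_model()].
#' @param W_max Upper quadrature limit, eV.
#' @param n Number of log-grid nodes.
#' @return Effective electrons per molecule.
#' @export
f_sum_electrons <- function(model, W_max = 1e4, n = 4000) {
  W <- exp(seq(log(1), log(W_max), length.out = n))
  y <- W^2 * rowSums(.elf_matrix(model, W, 0))   # W * ELF * (W dlnW)
  2 / (pi * model$Ep2) * sum(diff(log(W)) * (y[-1] + y[-n]) / 2)
}

#' Mean excitation energy implied by the model
#'
#' Computes I from the optical ELF through
#' \eqn{\ln I = \int W \ln W\, \mathrm{ELF}\, dW / \int W\, \mathrm{ELF}\, dW},
#' the standard dipole (Bethe) definition.  Useful to verify that the
#' parameterization is consistent with the I = 78 eV recommendation for
#' liquid water.
#'
#' @inheritParams f_sum_electrons
#' @return Mean excitation energy in eV.
#' @export
mean_excitation_eV <- function(model, W_max = 1e6, n = 6000) {
  W <- exp(seq(log(1), log(W_max), length.out = n))
  e <- rowSums(.elf_matrix(model, W, 0))
  w1 <- W^2 * e
  w2 <- W^2 * e * log(W)
  tr <- function(y) sum(diff(log(W)) * (y[-1] + y[-n]) / 2)
  exp(tr(w2) / tr(w1))
}
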