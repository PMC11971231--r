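# Single-event lineal-energy spectra and the direct / indirect / total
# dose-mean lineal energy.

.spectrum_from_density <- function(y, f, provenance, meta) {
  n <- length(y)
  norm <- .trapz(log(y), f * y)
  # sub-grid mass sits at vanishing deposits (near-degenerate mixture
  # components); it carries no lineal energy, so renormalization is the
  # faithful treatment -- but a large deficit signals quadrature breakdown
  if (!is.finite(norm) || abs(norm - 1) > 2e-2)
    stop(sprintf("spectrum normalization failed: integral = %.6f", norm))
  f <- f / norm
  yF <- .trapz(log(y), y * f * y)
  yD <- .trapz(log(y), y^2 * f * y) / yF
  structure(c(list(y = y, f = f, yF = yF, yD = yD, provenance = provenance),
              meta),
            class = "lineal_spectrum")
}

#' @export
print.lineal_spectrum <- function(x, ...) {
  cat(sprintf(
    "f(y) spectrum [%s]: yF = %.4g keV/um, yD = %.4g keV/um (%d nodes)\n",
    x$provenance, x$yF, x$yD, length(x$y)))
  invisible(x)
}

#' Direct-event lineal-energy spectrum and dose mean
#'
#' Builds the single-event spectrum f(y) of direct (crosser) events,
#' y = x / mean chord, and its moments.  Mode `"single"` uses one
#' straggling distribution whose mean is \eqn{f_{ion} LET \bar l} and
#' whose relative variance is the full budget V = V_delta + V_s; mode
#' `"chord_convolved"` mixes per-chord distributions (mean proportional to
#' the chord, per-chord variance from straggling only) over the chord pdf.
#' For untruncated families both modes give
#' \eqn{y_{D,dir} = f_{ion} LET (1 + V_s) + \delta_2/\bar l} exactly.
#'
#' @param sphere A [target_sphere()].
#' @param kin A [proton_kinematics()].
#' @param LET_keV_um Unrestricted stopping power at the proton energy.
#' @param delta2_keV Straggling factor, keV.
#' @param family Straggling family, see [make_straggling_distribution()].
#' @param mode "single" or "chord_convolved".
#' @param n_y Spectrum grid size.
#' @param n_chord Number of chord nodes for the convolved mode.
#' @return A `lineal_spectrum` with extra fields `yD_dir`, `f_ion`,
#'   `T_MeV`, `d_nm`, `family`, `vb` (the [variance_budget()]).
#' @export
direct_yd <- function(sphere, kin, LET_keV_um, delta2_keV,
                      family = "lognormal",
                      mode = c("single", "chord_convolved"),
                      n_y = 2048, n_chord = 128) {
  mode <- match.arg(mode)
  vb <- variance_budget(sphere, kin, LET_keV_um, delta2_keV)
  lbar <- sphere$lbar_um
  meta <- list(T_MeV = kin$T_MeV, d_nm = sphere$d_nm, family = family,
               f_ion = vb$f_ion, vb = vb, mode = mode)
  if (mode == "single") {
    dist <- make_straggling_distribution(family, vb$eps_keV, vb$V)
    x_lo <- max(dist$q(1e-8), vb$eps_keV * 1e-9)
    x_hi <- dist$q(1 - 1e-7)
    x <- exp(seq(log(x_lo), log(x_hi), length.out = n_y))
    fx <- dist$d(x)
    y <- x / lbar
    spec <- .spectrum_from_density(y, fx * lbar, "analytic", meta)
  } else {
    # mixture over chords: l_i with equal weight under c(l) = 2l/d^2
    u <- (seq_len(n_chord) - 0.5) / n_chord
    l_um <- sphere$d_nm * 1e-3 * sqrt(u)
    mean_l <- vb$f_ion * LET_keV_um * l_um
    dists <- lapply(seq_len(n_chord), function(i)
      make_straggling_distribution(family, mean_l[i],
                                   delta2_keV / mean_l[i]))
    # support wide enough for every mixture component
    x_lo <- max(min(vapply(dists, function(d) d$q(1e-8), numeric(1))),
                vb$eps_keV * 1e-9)
    x_hi <- max(vapply(dists, function(d) d$q(1 - 1e-7), numeric(1)))
    x <- exp(seq(log(x_lo), log(x_hi), length.out = n_y))
    fx <- Reduce(`+`, lapply(dists, function(d) d$d(x))) / n_chord
    y <- x / lbar
    spec <- .spectrum_from_density(y, fx * lbar, "analytic", meta)
  }
  spec$yD_dir <- spec$yD
  spec
}

#' Closed-form direct dose-mean lineal energy
#'
#' The moment identity for untruncated straggling families:
#' \eqn{y_{D,dir} = f_{ion} LET (1 + V_s) + \delta_2 / \bar l}.
#'
#' @param f_ion Restricted-LET fraction.
#' @param LET_keV_um Stopping power, keV/um.
#' @param delta2_keV Straggling factor, keV.
#' @param lbar_um Mean chord, um.
#' @param Vs Chord relative variance.
#' @return keV/um.
#' @export
yd_direct_closed_form <- function(f_ion, LET_keV_um, delta2_keV, lbar_um,
                                  Vs = 0.125) {
  f_ion * LET_keV_um * (1 + Vs) + delta2_keV / lbar_um
}

#' Indirect (delta-ray) dose-mean lineal energy
#'
#' DICS-frequency-weighted average of the electron lineal-energy table
#' over secondary-electron energies from the cut-off Delta up to the
#' kinematic maximum, normalized by the same DICS integral.
#'
#' @param model A [dielectric_model()].
#' @param kin A [proton_kinematics()].
#' @param sphere A [target_sphere()].
#' @param table An [electron_yd_table()].
#' @param n_E Secondary-energy quadrature nodes.
#' @return List of class `indirect_yd` with `yD_ind` (keV/um), `T_MeV`,
#'   `d_nm`.
#' @export
indirect_yd <- function(model, kin, sphere, table, n_E = 240) {
  stopifnot(inherits(table, "electron_yd_table"))
  lo_eV <- sphere$delta_keV * 1e3
  hi_eV <- kin$Emax_eV
  if (lo_eV >= hi_eV)
    stop("integration range empty: Delta >= kinematic maximum")
  E <- exp(seq(log(lo_eV), log(hi_eV), length.out = n_E))
  w <- dics(model, kin, E)$total_sum
  yDe <- interp_electron_yd(table, E * 1e-3, sphere$d_nm)
  den <- .trapz(log(E), w * E)
  if (den <= 0) stop("DICS weight vanishes over the integration range")
  num <- .trapz(log(E), yDe * w * E)
  structure(list(yD_ind = num / den, T_MeV = kin$T_MeV, d_nm = sphere$d_nm),
            class = "indirect_yd")
}

#' Total dose-mean lineal energy from direct and indirect parts
#'
#' Combines the two components with the restricted-LET fraction:
#' \eqn{y_D = f_{ion} y_{D,dir} + (1 - f_{ion}) y_{D,ind}}.
#' The components must refer to the same proton energy and diameter.
#'
#' @param direct A [direct_yd()] result (or any list with `yD_dir`,
#'   `f_ion`, `T_MeV`, `d_nm`).
#' @param indirect An [indirect_yd()] result.
#' @param f_ion Mixing weight override; defaults to the direct
#'   component's.
#' @return List of class `yd_breakdown` with `yD_total`, `yD_dir`,
#'   `yD_ind`, `f_ion`, `T_MeV`, `d_nm`, `family`.
#' @export
total_yd <- function(direct, indirect, f_ion = direct$f_ion) {
  if (!isTRUE(all.equal(direct$T_MeV, indirect$T_MeV)) ||
      !isTRUE(all.equal(direct$d_nm, indirect$d_nm)))
    stop("direct and indirect components computed for different (T, d)")
  stopifnot(f_ion >= 0, f_ion <= 1)
  structure(list(
    yD_total = f_ion * direct$yD_dir + (1 - f_ion) * indirect$yD_ind,
    yD_dir = direct$yD_dir, yD_ind = indirect$yD_ind, f_ion = f_ion,
    T_MeV = direct$T_MeV, d_nm = direct$d_nm,
    family = direct$family
  ), class = "yd_breakdown")
}

#' @export
print.yd_breakdown <- function(x, ...) {
  cat(sprintf(
    "yD(%g MeV, %g nm, %s) = %.4g keV/um (dir %.4g, ind %.4g, f_ion %.3f)\n",
    x$T_MeV, x$d_nm, x$family, x$yD_total, x$yD_dir, x$yD_ind, x$f_ion))
  invisible(x)
}

#' Dose-mean lineal energy curve over proton energy
#'
#' Sweeps a grid of proton energies, computing stopping power, straggling
#' factor, restricted-LET fraction, and the direct, indirect and total
#' dose-mean lineal energies for one sphere and straggling family.
#'
#' @param model A [dielectric_model()].
#' @param T_MeV Vector of proton energies, MeV.
#' @param sphere A [target_sphere()].
#' @param table An [electron_yd_table()] for the indirect term.
#' @param family Straggling family.
#' @param mode Direct-event spectrum mode, see [direct_yd()].
#' @param delta2_method "rpwba" (first principles) or "fitted" (power-law
#'   summary; much faster).
#' @return Data frame with columns `energy_MeV`, `diameter_nm`,
#'   `distribution`, `f_ion`, `yD_dir`, `yD_ind`, `yD_total` (keV/um),
#'   energies ascending.
#' @export
yd_curve <- function(model, T_MeV, sphere, table, family = "logistic",
                     mode = "single", delta2_method = c("rpwba", "fitted")) {
  delta2_method <- match.arg(delta2_method)
  T_MeV <- sort(T_MeV)
  rows <- lapply(T_MeV, function(T) {
    kin <- proton_kinematics(T)
    LET <- stopping_power(model, T)
    # at low energies the kinematic maximum can fall below the geometric
    # cut-off: every delta electron then stays local, f_ion = 1 and the
    # indirect term is empty
    capped <- kin$Emax_keV <= sphere$delta_keV
    sph <- if (capped)
      target_sphere(sphere$d_nm, delta_keV = kin$Emax_keV)
    else sphere
    d2 <- if (delta2_method == "rpwba")
      delta2(sph$delta_keV, "rpwba", model = model, kin = kin)
    else delta2(sph$delta_keV, "fitted")
    dir <- direct_yd(sph, kin, LET, d2, family = family, mode = mode)
    if (capped) {
      data.frame(energy_MeV = T, diameter_nm = sphere$d_nm,
                 distribution = family, f_ion = 1,
                 yD_dir = dir$yD_dir, yD_ind = NA_real_,
                 yD_total = dir$yD_dir)
    } else {
      ind <- indirect_yd(model, kin, sph, table)
      tot <- total_yd(dir, ind)
      data.frame(energy_MeV = T, diameter_nm = sphere$d_nm,
                 distribution = family, f_ion = tot$f_ion,
                 yD_dir = tot$yD_dir, yD_ind = tot$yD_ind,
                 yD_total = tot$yD_total)
    }
  })
  do.call(rbind, rows)
}

#' Write a yD curve to CSV
#'
#' Plain CSV with the column contract of [yd_curve()].
#' @param curve Data frame from [yd_curve()].
#' @param path Output path.
#' @export
write_yd_curve <- function(curve, path) {
  utils::write.csv(curve, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
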