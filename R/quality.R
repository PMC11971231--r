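# TDRA-based RBE and quality factor, and relative-difference / mean
# percentage deviation statistics against track-structure baselines.

#' Tabulated yD(T) dataset from one source
#'
#' A dose-mean lineal-energy curve from one calculation method (for
#' instance one Monte Carlo track-structure code), with the source's
#' stated maximum valid proton energy.
#'
#' @param source Source label.
#' @param energy_MeV Strictly increasing proton energies, MeV.
#' @param yD Positive yD values, keV/um.
#' @param max_valid_energy_MeV Upper limit of the source's validity;
#'   must cover the grid.
#' @return Object of class `yd_dataset`.
#' @export
yd_dataset <- function(source, energy_MeV, yD,
                       max_valid_energy_MeV = max(energy_MeV)) {
  if (any(diff(energy_MeV) <= 0))
    stop("energies must be strictly increasing")
  if (any(!is.finite(yD)) || any(yD <= 0))
    stop("yD values must be positive and finite")
  if (max_valid_energy_MeV < max(energy_MeV))
    stop("max valid energy below the largest grid energy")
  structure(list(source = source, energy_MeV = energy_MeV, yD = yD,
                 max_valid_energy_MeV = max_valid_energy_MeV),
            class = "yd_dataset")
}

#' Read a yD dataset CSV
#'
#' Header `energy_MeV,yD_keV_per_um`; metadata lines `# source=<label>`
#' and `# max_valid_energy_MeV=<value>`.
#'
#' @param path CSV path.
#' @return A [yd_dataset()].
#' @export
read_yd_dataset <- function(path) {
  head <- grep("^#", readLines(path, n = 50), value = TRUE)
  src <- sub("^#\\s*source=", "", grep("^#\\s*source=", head, value = TRUE))
  mv <- sub("^#\\s*max_valid_energy_MeV=", "",
            grep("^#\\s*max_valid_energy_MeV=", head, value = TRUE))
  df <- tryCatch(utils::read.csv(path, comment.char = "#"),
                 error = function(e) stop("malformed yD dataset CSV: ",
                                          conditionMessage(e)))
  if (!all(c("energy_MeV", "yD_keV_per_um") %in% names(df)))
    stop("malformed yD dataset CSV: expected energy_MeV,yD_keV_per_um")
  yd_dataset(if (length(src)) src[1] else "unspecified",
             df$energy_MeV, df$yD_keV_per_um,
             if (length(mv)) as.numeric(mv[1]) else max(df$energy_MeV))
}

#' Write a yD dataset CSV
#' @param ds A [yd_dataset()].
#' @param path Output path.
#' @export
write_yd_dataset <- function(ds, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# source=%s", ds$source),
               sprintf("# max_valid_energy_MeV=%s",
                       format(ds$max_valid_energy_MeV, digits = 17)),
               "energy_MeV,yD_keV_per_um"), con)
  writeLines(sprintf("%s,%s",
                     format(ds$energy_MeV, digits = 17, trim = TRUE),
                     format(ds$yD, digits = 17, trim = TRUE)), con)
  invisible(path)
}

# Log-log interpolation of a dataset at requested energies; never
# extrapolates beyond the grid or the validity limit.
.yd_at <- function(ds, T_MeV) {
  ok <- T_MeV >= ds$energy_MeV[1] - 1e-12 &
    T_MeV <= min(max(ds$energy_MeV), ds$max_valid_energy_MeV) + 1e-12
  out <- rep(NA_real_, length(T_MeV))
  if (any(ok))
    out[ok] <- exp(stats::approx(log(ds$energy_MeV), log(ds$yD),
                                 xout = log(T_MeV[ok]), rule = 2)$y)
  out
}

#' TDRA relative biological effectiveness
#'
#' Site-model dual-radiation-action expression
#' \deqn{RBE = \frac{\sqrt{(c\,y_{D,ref})^2 + 4 D (c\,y_{D,test} + D)}
#'       - c\,y_{D,ref}}{2D}.}
#' In the low-dose limit it reduces to the ratio
#' \eqn{y_{D,test}/y_{D,ref}}, the quality factor.
#'
#' @param yD_test,yD_ref Dose-mean lineal energies, keV/um, positive.
#' @param c_const TDRA normalization constant (units Gy um/keV so the
#'   products are doses).
#' @param D_test Test dose, Gy, positive.
#' @return RBE (dimensionless).
#' @export
rbe_tdra <- function(yD_test, yD_ref, c_const, D_test) {
  stopifnot(all(yD_test > 0), all(yD_ref > 0), c_const > 0, all(D_test > 0))
  (sqrt((c_const * yD_ref)^2 +
          4 * D_test * (c_const * yD_test + D_test)) -
     c_const * yD_ref) / (2 * D_test)
}

#' TDRA quality factor curve
#'
#' Q(T) = yD(T) / yD(T_ref); Q equals 1 at the reference energy by
#' construction.  An off-grid reference inside the grid is interpolated
#' log-log with a message; a reference outside the grid (or the validity
#' range) is an error, never a silent extrapolation.
#'
#' @param curve A [yd_dataset()], or a data frame with columns
#'   `energy_MeV` and `yD_total` (or `yD_keV_per_um`).
#' @param ref_energy_MeV Reference proton energy, MeV.
#' @return Data frame with `energy_MeV` and `Q`.
#' @export
q_tdra <- function(curve, ref_energy_MeV = 100) {
  if (is.data.frame(curve)) {
    ycol <- intersect(c("yD_total", "yD_keV_per_um", "yD"), names(curve))[1]
    if (is.na(ycol)) stop("no yD column found in curve")
    curve <- yd_dataset("curve", curve$energy_MeV, curve[[ycol]])
  }
  stopifnot(inherits(curve, "yd_dataset"))
  lim <- min(max(curve$energy_MeV), curve$max_valid_energy_MeV)
  if (ref_energy_MeV < curve$energy_MeV[1] || ref_energy_MeV > lim)
    stop("reference energy outside the dataset's valid range")
  if (!ref_energy_MeV %in% curve$energy_MeV)
    message(sprintf("reference %g MeV interpolated log-log between grid points",
                    ref_energy_MeV))
  y_ref <- .yd_at(curve, ref_energy_MeV)
  data.frame(energy_MeV = curve$energy_MeV, Q = curve$yD / y_ref)
}

#' Arithmetic-mean track-structure baseline with validity filtering
#'
#' For each requested energy, averages the yD of those datasets whose
#' validity range covers it (log-log interpolating each source to the
#' requested energy).  An energy with no valid dataset is an error.
#'
#' @param datasets List of [yd_dataset()] objects.
#' @param T_MeV Energies at which to form the baseline.
#' @return Data frame with `energy_MeV`, `yD_mean`, `n_sources`, and a
#'   `sources` string listing the members used.
#' @export
mcts_baseline <- function(datasets, T_MeV) {
  stopifnot(length(datasets) >= 1)
  vals <- sapply(datasets, function(ds) .yd_at(ds, T_MeV))
  vals <- matrix(vals, nrow = length(T_MeV))
  n_src <- rowSums(!is.na(vals))
  if (any(n_src == 0))
    stop(sprintf("no dataset valid at %s MeV",
                 paste(T_MeV[n_src == 0], collapse = ", ")))
  labels <- vapply(datasets, function(ds) ds$source, character(1))
  data.frame(
    energy_MeV = T_MeV,
    yD_mean = rowMeans(vals, na.rm = TRUE),
    n_sources = as.integer(n_src),
    sources = apply(vals, 1, function(v)
      paste(labels[!is.na(v)], collapse = "+"))
  )
}

#' Relative difference and mean percentage deviation
#'
#' Per-energy relative difference of a candidate yD curve against the
#' arithmetic-mean baseline of the supplied datasets,
#' RD(T) = (yD - mean) / mean x 100%, and their absolute mean, the MPD.
#'
#' @param candidate A [yd_dataset()] or data frame (see [q_tdra()]).
#' @param datasets List of baseline [yd_dataset()] objects.
#' @param T_MeV Energies to compare at; defaults to the candidate grid.
#' @return Object of class `comparison_result`: `energy_MeV`,
#'   `rd_percent`, `mpd_percent`, `n`, `baseline`.
#' @export
rd_mpd <- function(candidate, datasets, T_MeV = NULL) {
  if (is.data.frame(candidate)) {
    ycol <- intersect(c("yD_total", "yD_keV_per_um", "yD"),
                      names(candidate))[1]
    candidate <- yd_dataset("candidate", candidate$energy_MeV,
                            candidate[[ycol]])
  }
  if (is.null(T_MeV)) T_MeV <- candidate$energy_MeV
  base <- mcts_baseline(datasets, T_MeV)
  yc <- .yd_at(candidate, T_MeV)
  if (any(is.na(yc)))
    stop("candidate does not cover all requested energies")
  rd <- (yc - base$yD_mean) / base$yD_mean * 100
  structure(list(energy_MeV = T_MeV, rd_percent = rd,
                 mpd_percent = mean(abs(rd)), n = length(T_MeV),
                 baseline = base),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("RD/MPD over %d energies: MPD = %.2f%%, RD range [%.2f, %.2f]%%\n",
              x$n, x$mpd_percent, min(x$rd_percent), max(x$rd_percent)))
  invisible(x)
}

#' Synthetic track-structure yD datasets
#'
#' Seed-reproducible fixture emulating a family of track-structure
#' results: a smooth decreasing yD(T) base curve per diameter, per-source
#' multiplicative perturbations (a constant source factor plus a mild
#' smooth wiggle), and a stated maximum valid energy per source -- four
#' sources valid to 300 MeV and two to 1000 MeV by default.
#'
#' @param seed Integer seed.
#' @param d_nm Sphere diameter the curves refer to, nm.
#' @param energy_MeV Energy grid, MeV.
#' @param spread Standard deviation of the log source factors.
#' @return Named list of [yd_dataset()] objects.
#' @export
synth_mcts_datasets <- function(seed, d_nm = 1000,
                                energy_MeV = c(1, 2, 5, 10, 20, 50, 100,
                                               200, 300, 400, 600, 800, 1000),
                                spread = 0.08) {
  stopifnot(length(seed) == 1, is.finite(seed))
  max_valid <- c(src_A = 300, src_B = 300, src_C = 300, src_D = 300,
                 src_E = 1000, src_F = 1000)
  base <- .yd_reference_shape(energy_MeV, d_nm)
  .with_preserved_rng(seed, function() {
    out <- lapply(seq_along(max_valid), function(i) {
      fac <- exp(stats::rnorm(1, 0, spread))
      wig <- exp(0.03 * sin(2 * pi * seq_along(energy_MeV) /
                              length(energy_MeV) + stats::runif(1, 0, 2 * pi)))
      keep <- energy_MeV <= max_valid[i]
      yd_dataset(names(max_valid)[i], energy_MeV[keep],
                 (base * fac * wig)[keep], max_valid[i])
    })
    names(out) <- names(max_valid)
    out
  })
}

# Smooth decreasing yD(T) shape used by the synthetic fixture: LET-like
# 1/T^0.8 fall-off flattening toward relativistic energies, scaled so the
# 1000 nm curve is a few keV/um at low energy.
.yd_reference_shape <- function(T_MeV, d_nm) {
  mag <- 18 * (1000 / d_nm)^0.15
  mag * (T_MeV^-0.8 + 0.012) / (1 + 0.012)
}
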