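# Pluggable electron dose-mean lineal-energy lookup tables.  The indirect
# term needs yD(E, d) for monoenergetic electrons; authoritative values
# come from track-structure transport, which is outside this package's
# scope, so tables are an explicit plug-in with a synthetic generator for
# tests and demonstrations.

#' Electron lineal-energy lookup table
#'
#' Rectangular table of electron dose-mean lineal energy yD(E, d) over
#' electron energy (keV) and sphere diameter (nm).
#'
#' @param energy_keV Strictly increasing electron energies, keV.
#' @param diameter_nm Strictly increasing diameters, nm.
#' @param yD Matrix (length(energy) x length(diameter)) of positive
#'   yD values, keV/um.
#' @param source Label recording where the values came from.
#' @return Object of class `electron_yd_table`.
#' @export
electron_yd_table <- function(energy_keV, diameter_nm, yD,
                              source = "unspecified") {
  yD <- as.matrix(yD)
  if (any(diff(energy_keV) <= 0))
    stop("electron energies must be strictly increasing")
  if (any(diff(diameter_nm) <= 0))
    stop("diameters must be strictly increasing")
  if (nrow(yD) != length(energy_keV) || ncol(yD) != length(diameter_nm))
    stop("yD matrix dimensions do not match the energy/diameter grids")
  if (any(!is.finite(yD)) || any(yD <= 0))
    stop("yD values must be positive and finite")
  structure(list(energy_keV = energy_keV, diameter_nm = diameter_nm,
                 yD = yD, source = source),
            class = "electron_yd_table")
}

#' Interpolate an electron yD table
#'
#' Bilinear interpolation in log(E) x log(d) on log(yD); exact at the
#' table nodes.  Requests outside the table's coverage raise an error
#' rather than extrapolating.
#'
#' @param table An [electron_yd_table()].
#' @param energy_keV Electron energies, keV.
#' @param diameter_nm Single diameter, nm.
#' @return Vector of yD values, keV/um.
#' @export
interp_electron_yd <- function(table, energy_keV, diameter_nm) {
  eg <- table$energy_keV; dg <- table$diameter_nm
  if (any(energy_keV < eg[1] - 1e-12) || any(energy_keV > eg[length(eg)] + 1e-9))
    stop(sprintf(
      "table coverage error: requested %.4g-%.4g keV, table spans %.4g-%.4g keV",
      min(energy_keV), max(energy_keV), eg[1], eg[length(eg)]))
  if (diameter_nm < dg[1] || diameter_nm > dg[length(dg)])
    stop("table coverage error: diameter outside tabulated range")
  # column interpolation in log d
  lz <- log(table$yD)
  if (length(dg) == 1) {
    col <- lz[, 1]
  } else {
    jd <- findInterval(diameter_nm, dg, rightmost.closed = TRUE)
    jd <- min(max(jd, 1), length(dg) - 1)
    t <- (log(diameter_nm) - log(dg[jd])) / (log(dg[jd + 1]) - log(dg[jd]))
    col <- (1 - t) * lz[, jd] + t * lz[, jd + 1]
  }
  exp(stats::approx(log(eg), col, xout = log(pmin(pmax(energy_keV, eg[1]),
                                                  eg[length(eg)])))$y)
}

#' Read an electron yD table from CSV
#'
#' Long-format CSV with header
#' `electron_energy_keV,diameter_nm,yD_keV_per_um` and optional
#' `#`-prefixed metadata lines (`# source=...`).  Malformed files,
#' non-monotone energy grids and non-positive values raise distinct
#' errors.
#'
#' @param path CSV path.
#' @return An [electron_yd_table()].
#' @export
read_electron_yd_table <- function(path) {
  meta <- grep("^#", readLines(path, n = 50), value = TRUE)
  src <- sub("^#\\s*source=", "", grep("^#\\s*source=", meta, value = TRUE))
  df <- tryCatch(utils::read.csv(path, comment.char = "#"),
                 error = function(e) stop("malformed electron table CSV: ",
                                          conditionMessage(e)))
  need <- c("electron_energy_keV", "diameter_nm", "yD_keV_per_um")
  if (!all(need %in% names(df)))
    stop("malformed electron table CSV: expected columns ",
         paste(need, collapse = ", "))
  eg <- sort(unique(df$electron_energy_keV))
  dg <- sort(unique(df$diameter_nm))
  yD <- matrix(NA_real_, length(eg), length(dg))
  yD[cbind(match(df$electron_energy_keV, eg), match(df$diameter_nm, dg))] <-
    df$yD_keV_per_um
  if (any(is.na(yD)))
    stop("malformed electron table CSV: incomplete (energy, diameter) grid")
  electron_yd_table(eg, dg, yD,
                    source = if (length(src)) src[1] else "unspecified")
}

#' Write an electron yD table to CSV
#'
#' Inverse of [read_electron_yd_table()]; values round-trip bit-exactly
#' (full-precision formatting).
#'
#' @param table An [electron_yd_table()].
#' @param path Output path.
#' @export
write_electron_yd_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# source=%s", table$source), con)
  writeLines("electron_energy_keV,diameter_nm,yD_keV_per_um", con)
  for (j in seq_along(table$diameter_nm))
    writeLines(sprintf("%s,%s,%s",
                       format(table$energy_keV, digits = 17, trim = TRUE),
                       format(table$diameter_nm[j], digits = 17, trim = TRUE),
                       format(table$yD[, j], digits = 17, trim = TRUE)), con)
  invisible(path)
}

# Electron LET-like reference curve (keV/um vs keV) used by the synthetic
# generator: a log-log interpolation through round-number anchors with the
# familiar 1/E-ish fall-off and a relativistic flattening above 1 MeV.
.electron_let_anchors <- data.frame(
  E_keV = c(0.1, 0.3, 1, 3, 10, 30, 100, 300, 1000, 3000, 10000),
  L_keV_um = c(25, 20, 13, 6.5, 2.3, 1.0, 0.42, 0.25, 0.19, 0.20, 0.22)
)

#' Synthetic electron yD table
#'
#' Seed-reproducible placeholder table for tests and demonstrations: a
#' smooth positive surface built from an electron LET-like magnitude
#' scaled by the idealized continuous-slowing-down conversion
#' yD = (9/8) yF, a mild diameter enhancement for small sites, and
#' log-normal perturbations.  It is NOT a track-structure result and
#' carries the source label "synthetic".
#'
#' @param seed Integer seed; same seed, same table.
#' @param diameter_nm Diameters, nm.
#' @param energy_keV Electron energies, keV.
#' @param jitter_sd Standard deviation of the log-normal perturbation.
#' @return An [electron_yd_table()].
#' @export
synth_electron_yd_table <- function(seed, diameter_nm = c(10, 100, 1000),
                                    energy_keV = exp(seq(log(0.1), log(4000),
                                                         length.out = 40)),
                                    jitter_sd = 0.05) {
  stopifnot(length(seed) == 1, is.finite(seed))
  anchors <- .electron_let_anchors
  le <- function(E) {
    lx <- log(anchors$E_keV); ly <- log(anchors$L_keV_um)
    exp(vapply(log(pmin(pmax(E, anchors$E_keV[1]),
                        anchors$E_keV[nrow(anchors)])),
               function(x) .interp_lin_extrap(lx, ly, x), numeric(1)))
  }
  diameter_nm <- sort(diameter_nm)
  energy_keV <- sort(energy_keV)
  runner <- function() {
    yD <- outer(9 / 8 * le(energy_keV),
                1 + 0.4 * (1000 / diameter_nm)^0.25)
    jit <- matrix(exp(stats::rnorm(length(yD), 0, jitter_sd)),
                  nrow(yD), ncol(yD))
    yD * jit
  }
  yD <- .with_preserved_rng(seed, runner)
  electron_yd_table(energy_keV, diameter_nm, yD,
                    source = sprintf("synthetic (seed %d)", as.integer(seed)))
}

# Run fn under set.seed(seed) without disturbing the caller's RNG stream.
.with_preserved_rng <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}
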