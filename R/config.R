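# YAML configuration: the dielectric parameterization and the bundled
# target / variance constants, swappable without code changes.

#' Path of the bundled configuration file
#' @return Path to the packaged `water_drude.yaml`.
#' @export
default_config_path <- function()
  system.file("extdata", "water_drude.yaml", package = "microlineal",
              mustWork = TRUE)

#' Load a configuration file
#'
#' Reads the YAML configuration (dielectric channels, molecular density,
#' sum-rule tolerance, target diameters with cut-off overrides, variance
#' constants) and builds the dielectric model.
#'
#' @param path YAML path; defaults to the bundled liquid-water file.
#' @return List with elements `model` (a [dielectric_model()]), `targets`
#'   (data frame of diameters and cut-offs), `variance` (list with `Vs`,
#'   `Vlet`), and the raw `config`.
#' @export
load_config <- function(path = default_config_path()) {
  cfg <- yaml::read_yaml(path)
  di <- cfg$dielectric
  channels <- lapply(di$channels, function(ch)
    oscillator_channel(ch$kind, ch$label, ch$threshold_eV,
                       ch$amplitude, ch$width_eV, ch$resonance_eV))
  model <- dielectric_model(
    channels,
    molecular_density_per_cm3 = as.numeric(di$molecular_density_per_cm3),
    sum_rule_tolerance = di$sum_rule_tolerance,
    excitation_q_cut_eV = di$excitation_q_cut_eV)
  targets <- do.call(rbind, lapply(cfg$targets, as.data.frame))
  list(model = model, targets = targets, variance = cfg$variance,
       config = cfg)
}

#' Bundled liquid-water dielectric model
#'
#' The packaged Drude parameterization (five ionization shells, five
#' discrete excitation channels), constructed once per session and
#' cached.
#'
#' @return A [dielectric_model()].
#' @export
water_model <- function() {
  if (is.null(.ml_cache$water_model))
    .ml_cache$water_model <- load_config()$model
  .ml_cache$water_model
}
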