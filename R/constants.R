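# Physical constants. Internal energy unit is eV throughout the dielectric
# and cross-section code; keV and MeV appear only at module boundaries.
.ml_const <- list(
  mc2_eV   = 0.511e6,     # electron rest energy
  Mc2_eV   = 938.272e6,   # proton rest energy
  a0_cm    = 5.29177e-9,  # Bohr radius
  I_keV    = 0.078,       # mean excitation energy of liquid water
  N_water  = 3.343e22,    # molecules / cm^3, unit-density liquid water
  # E_p^2 [eV^2] = C * n_e [cm^-3]; C = hbar^2 e^2 / (eps0 m_e), eV-converted
  Ep2_coef = 1.37889e-21
)

# Per-session cache for expensive per-(model, T) quantities (DICS tables).
.ml_cache <- new.env(parent = emptyenv())

#' Mean excitation energy adopted for liquid water
#'
#' Returns the I-value (keV) used in the restricted-LET fraction and in the
#' Kellerer-type straggling-factor formula.
#' @return Numeric scalar, keV.
#' @export
water_I_keV <- function() .ml_const$I_keV
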