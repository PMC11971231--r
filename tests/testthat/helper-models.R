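# Shared fixtures.  The bundled water model is loaded once; heavy
# derived quantities computed here are reused across files.

wm <- water_model()

# A deliberately partial toy model (one channel of each kind) for cheap
# structural tests; skips the sum-rule validation.
toy_model <- function() {
  dielectric_model(
    list(oscillator_channel("excitation", "exc", 8, 0.05, 2, 8.5),
         oscillator_channel("ionization", "ion", 12, 1.0, 10, 20)),
    validate = FALSE)
}

canonical_deltas <- c(0.180, 1.37, 5.56)
canonical_d_nm <- c(10, 100, 1000)
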