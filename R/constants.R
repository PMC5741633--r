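# Physical constants (SI)
.const <- list(
  e_charge   = 1.602176634e-19,  # C
  avogadro   = 6.02214076e23,    # 1/mol
  faraday    = 96485.33212,      # C/mol
  gas_const  = 8.31446261815324  # J/(mol K)
)

# RT/F in mV at temperature T (K)
rt_over_f_mV <- function(temperature_K = 298) {
  1000 * .const$gas_const * temperature_K / .const$faraday
}

# Nernst slope (RT ln10 / F) in mV per pH unit / per decade
nernst_slope_mV <- function(temperature_K = 298) {
  rt_over_f_mV(temperature_K) * log(10)
}

# molecules in a volume at a mM concentration
.molecules <- function(conc_mM, volume_l) {
  conc_mM * 1e-3 * volume_l * .const$avogadro
}

# mM concentration of a molecule count in a volume
.mM <- function(count, volume_l) {
  count / (1e-3 * volume_l * .const$avogadro)
}
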