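#' Initial proton pumping rate per pump implied by an acidification fit
#'
#' If `bound_count` protons are taken up by luminal buffers within one
#' acidification time constant, the initial pumping rate per proton pump is
#' `bound_count / (tau_s * n_pumps)`.
#'
#' @param bound_count protons bound within one time constant.
#' @param tau_s acidification time constant, s.
#' @param n_pumps proton pump copies per vesicle (fractional copy numbers
#'   are treated as deterministic rate scalings).
#' @return Pumping rate in protons per second per pump.
#' @export
infer_pump_rate <- function(bound_count, tau_s, n_pumps) {
  stopifnot(tau_s > 0, n_pumps > 0)
  bound_count / (tau_s * n_pumps)
}

#' Elementary charges needed to polarise a membrane capacitance
#'
#' `C * V / e`: with the ~50 aF capacitance of a synaptic vesicle, about 31
#' elementary charges suffice for a 100 mV membrane potential.
#'
#' @param capacitance_F membrane capacitance, farad.
#' @param voltage_V membrane potential, volt.
#' @return Number of elementary charges.
#' @export
charges_for_voltage <- function(capacitance_F, voltage_V) {
  stopifnot(capacitance_F > 0)
  capacitance_F * voltage_V / .const$e_charge
}

#' Molecule count corresponding to a concentration in a small volume
#'
#' @param conc_mM concentration, mM (>= 0).
#' @param volume_l compartment volume, litres.
#' @return Number of molecules, `conc * V * N_A`.
#' @examples
#' molecules_from_concentration(120, 20e-21)  # ~1445 glutamate molecules
#' @export
molecules_from_concentration <- function(conc_mM, volume_l = 20e-21) {
  stopifnot(all(conc_mM >= 0))
  .molecules(conc_mM, volume_l)
}

#' Nernst reversal potential of an ion
#'
#' \eqn{E = (RT/zF)\ln(c_{out}/c_{in})}, in mV. For chloride
#' (`z = -1`) with 145 mM outside and 14 mM inside at 298 K this gives
#' about -60 mV, the anion reversal potential of the whole-cell
#' configuration mimicking a freshly endocytosed vesicle.
#'
#' @param z ion valence (signed integer).
#' @param conc_out external concentration (> 0), any unit shared with
#'   `conc_in`.
#' @param conc_in internal concentration (> 0).
#' @param temperature_K temperature in kelvin.
#' @return Reversal potential in mV.
#' @export
nernst_potential <- function(z, conc_out, conc_in, temperature_K = 298) {
  if (z == 0) stop("valence z must be non-zero", call. = FALSE)
  if (any(conc_out <= 0) || any(conc_in <= 0)) {
    stop("concentrations must be positive", call. = FALSE)
  }
  rt_over_f_mV(temperature_K) / z * log(conc_out / conc_in)
}
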