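#' Parameters of the single-vesicle ion-flux model
#'
#' Pump, transporter, channel, buffer and geometry parameters of the
#' electro-chemical model of synaptic-vesicle re-acidification and
#' glutamate loading. The lumen is a fixed volume bounded by a membrane
#' capacitance; the membrane carries a V-ATPase proton pump, VGLUT-type
#' glutamate/H+ exchangers, and a channel-like anion conductance borne by
#' the same transporter copies.
#'
#' Copy numbers, maximal rates, volume and capacitance are the published
#' single-vesicle estimates. The kinetic shape parameters
#' (`v_stall_mV`, `dph_weight`, `cl_permeability`, `cl_rectification`,
#' `vglut_hill_pka`) are not directly measured; their defaults are
#' calibrated once so that the named scenarios reproduce the measured
#' acidification time constants and endpoints (see the package vignette).
#'
#' @param volume_l luminal volume, litres.
#' @param capacitance_F membrane capacitance, farad.
#' @param n_pumps V-ATPase copies per vesicle (fractional values scale the
#'   deterministic rate).
#' @param pump_rate_max maximal pumping rate, H+ per second per pump.
#' @param n_vglut VGLUT copies per vesicle.
#' @param vglut_rate_max maximal transport rate, glutamate per second per
#'   transporter.
#' @param n_h transported H+ per glutamate (coupling stoichiometry,
#'   between 1 and 2).
#' @param cl_permeability chloride conductance per VGLUT copy in the
#'   well-conducted (lumen-filling) direction, ions s^-1 mV^-1.
#' @param cl_rectification ratio of efflux to influx conductance of the
#'   anion channel (< 1: inwardly rectifying, as measured for the
#'   plasma-membrane-targeted transporter).
#' @param rb_block logical; Rose-Bengal inhibition: zeroes glutamate/H+
#'   transport and scales the anion conductance by `rb_cl_factor`.
#' @param rb_cl_factor residual fraction of the anion conductance under
#'   Rose Bengal.
#' @param v_stall_mV membrane potential at which the pump stalls at zero
#'   pH gradient.
#' @param dph_weight relative weight of the pH-gradient term in the pump
#'   stall criterion; the pump stops when
#'   `dpsi + dph_weight * Z * (ph_cyt - pH) >= v_stall_mV` with `Z` the
#'   Nernst slope. A value below 1 encodes the stronger voltage than
#'   pH-gradient sensitivity of the pump.
#' @param vglut_hill_pka pKa of the luminal proton-binding site of the
#'   transporter; its occupancy gates the H+-export limb.
#' @param osm_max_molecules osmotic ceiling on total luminal
#'   osmolyte-anion molecules (isosmotic maximum).
#' @param osm_ramp_mM width (mM) of the soft osmotic wall over which
#'   solute entry is ramped to zero.
#' @param ph_cyt cytosolic pH.
#' @param cl_cyt_mM cytosolic chloride, mM.
#' @param glu_cyt_mM cytosolic glutamate, mM.
#' @param temperature_K temperature, kelvin.
#' @param matrix_buffers list of endogenous [buffer_species()] fixed in
#'   the lumen.
#' @return An object of class `flux_params`.
#' @export
flux_params <- function(volume_l = 20e-21,
                        capacitance_F = 50e-18,
                        n_pumps = 1.5,
                        pump_rate_max = 200,
                        n_vglut = 10,
                        vglut_rate_max = 20,
                        n_h = 1.5,
                        cl_permeability = 1.4,
                        cl_rectification = 0.19,
                        rb_block = FALSE,
                        rb_cl_factor = 0.8,
                        v_stall_mV = 50,
                        dph_weight = 0.3,
                        vglut_hill_pka = 7.4,
                        osm_max_molecules = 1790,
                        osm_ramp_mM = 5,
                        ph_cyt = 7.3,
                        cl_cyt_mM = 14,
                        glu_cyt_mM = 10,
                        temperature_K = 298,
                        matrix_buffers = endogenous_buffers()) {
  stopifnot(volume_l > 0, capacitance_F > 0, n_pumps >= 0,
            pump_rate_max >= 0, n_vglut >= 0, vglut_rate_max >= 0,
            cl_permeability >= 0, v_stall_mV > 0,
            cl_cyt_mM > 0, glu_cyt_mM > 0)
  if (n_h > 2 || (n_h < 1 && n_h != 0)) {
    stop("n_h must lie between 1 and 2 (coupled glutamate/H+ exchange); ",
         "0 is allowed as the uncoupled diagnostic limit", call. = FALSE)
  }
  structure(as.list(environment()), class = "flux_params")
}

# Luminal buffer list of a run: engulfed exogenous solutes + fixed matrix
.luminal_buffers <- function(solution, params) {
  b <- params$matrix_buffers
  if (solution$hepes_mM > 0) {
    b <- c(b, list(buffer_species("HEPES", solution$hepes_mM, 7.55)))
  }
  if (solution$histidine_mM > 0) {
    b <- c(b, list(buffer_species("histidine", solution$histidine_mM, 6)))
  }
  if (solution$tris_mM > 0) {
    b <- c(b, list(buffer_species("TRIS", solution$tris_mM, 8.3)))
  }
  if (solution$substitute_anion != "none" && solution$substitute_mM > 0) {
    pka <- .substitute_pka[[solution$substitute_anion]]
    if (is.finite(pka)) {
      b <- c(b, list(buffer_species(solution$substitute_anion,
                                    solution$substitute_mM, pka)))
    }
  }
  b
}

# Total titratable proton content (molecules) of the lumen at a pH:
# free protons plus protons bound to every buffer species.
.proton_content <- function(pH, buffers, volume_l) {
  free <- 10^(-pH) * 1e3 * .molecules(1, volume_l)  # 10^-pH mol/l -> count
  bound <- sum(vapply(buffers, function(b) {
    .molecules(b$conc_mM, volume_l) * buffer_bound_fraction(pH, b$pKa)
  }, numeric(1)))
  free + bound
}

# Invert .proton_content: pH at which the lumen holds `content` protons.
# Content is strictly decreasing in pH, so bisection is safe.
.ph_from_content <- function(content, buffers, volume_l,
                             lower = 3, upper = 9.5) {
  f <- function(p) .proton_content(p, buffers, volume_l) - content
  if (f(lower) < 0) return(lower)
  if (f(upper) > 0) return(upper)
  stats::uniroot(f, c(lower, upper), tol = 1e-10)$root
}

# Instantaneous fluxes (molecules/s, influx positive) for a lumen state.
# Returns pump H+ influx, VGLUT glutamate influx (H+ efflux = n_h * that),
# channel chloride influx, plus the derived pH / membrane potential.
.vesicle_fluxes <- function(H, Cl, Glu, env) {
  p <- env$params
  pH <- .ph_from_content(env$content0 + H, env$buffers, p$volume_l)
  Q <- H - (Cl - env$Cl0) - (Glu - env$Glu0)
  dpsi <- Q * .const$e_charge / p$capacitance_F * 1e3  # mV
  Z <- nernst_slope_mV(p$temperature_K)
  rtf <- rt_over_f_mV(p$temperature_K)

  # V-ATPase: rate falls linearly with a voltage-dominated stall variable
  stall_arg <- dpsi + p$dph_weight * Z * (p$ph_cyt - pH)
  s_pump <- min(max(1 - stall_arg / p$v_stall_mV, 0), 1)
  j_pump <- p$n_pumps * p$pump_rate_max * s_pump

  cl_mM <- .mM(Cl, p$volume_l)
  glu_mM <- .mM(Glu, p$volume_l)
  anion_mM <- cl_mM + glu_mM + env$sub_mM
  osm_cap_mM <- .mM(p$osm_max_molecules, p$volume_l)
  osm_fac <- min(max((osm_cap_mM - anion_mM) / p$osm_ramp_mM, 0), 1)

  # VGLUT glutamate/H+ exchange (off under Rose Bengal)
  j_glu <- 0
  if (!p$rb_block && p$n_vglut > 0 && p$vglut_rate_max > 0) {
    dg_rt <- log(max(glu_mM, 1e-4) / p$glu_cyt_mM) +
      p$n_h * log(10) * (pH - p$ph_cyt) -
      (1 + p$n_h) * dpsi / rtf
    drive <- min(max(1 - exp(dg_rt), 0), 1)
    f_h <- 1 / (1 + 10^(pH - p$vglut_hill_pka))
    j_glu <- p$n_vglut * p$vglut_rate_max * drive * f_h * osm_fac
  }

  # channel-like anion conductance: linear in the electro-diffusive
  # driving force, inwardly rectifying (influx conducted better), with
  # solute influx subject to the osmotic wall
  j_cl <- 0
  g_tot <- p$n_vglut * p$cl_permeability *
    (if (p$rb_block) p$rb_cl_factor else 1)
  if (g_tot > 0 && Cl > 0.01) {
    e_cl <- rtf * log(cl_mM / p$cl_cyt_mM)  # equilibrium potential, mV
    dv <- dpsi - e_cl
    w_in <- 1 / (1 + exp(-dv / 0.5))        # smooth rectification blend
    g_eff <- g_tot * (w_in + p$cl_rectification * (1 - w_in))
    j_cl <- g_eff * dv
    if (j_cl > 0) j_cl <- j_cl * osm_fac
  }

  list(j_pump = j_pump, j_glu = j_glu, j_cl = j_cl,
       pH = pH, dpsi = dpsi, s_pump = s_pump, osm_fac = osm_fac)
}

#' Simulate the ion fluxes of a single re-acidifying vesicle
#'
#' Integrates the luminal state of one newly endocytosed vesicle: total
#' titratable protons, chloride and glutamate counts, with luminal buffers
#' held at fast equilibrium (the luminal pH is recovered at every step by
#' a monotone root solve of total proton content), the membrane potential
#' set by the running net charge on the membrane capacitance, and the
#' normalized reporter fluorescence predicted from pH through
#' [deltaF_from_pH()].
#'
#' Fluxes: the proton pump runs at a rate that falls linearly with a
#' voltage-dominated stall variable; the glutamate/H+ exchanger imports
#' glutamate (exporting `n_h` protons per molecule) with a thermodynamic
#' driving factor, a luminal proton-site occupancy factor and an osmotic
#' ceiling; the anion channel conducts chloride down its electrochemical
#' gradient with inward rectification. Cumulative flux ledgers are
#' integrated alongside the state so that charge and proton conservation
#' can be audited exactly.
#'
#' @param params a [flux_params()] object.
#' @param solution the engulfed [solution_spec()].
#' @param duration_s simulated time, seconds.
#' @param dt_s output sampling interval, seconds (the integrator itself is
#'   adaptive).
#' @param pp [photophysics_params()] used for the predicted fluorescence.
#' @return A data frame of class `vesicle_timecourse` with columns
#'   `time_s`, `ph`, `dpsi_mV`, `cl_mM`, `glu_mM`, `dF`, `h_total`,
#'   `charge`, and cumulative ledgers `cum_pump`, `cum_vglut_h`,
#'   `cum_cl_in`, `cum_glu_in`. The run inputs are attached as attributes
#'   `params`, `solution`, `buffers`.
#' @export
simulate_vesicle <- function(params = flux_params(),
                             solution = solution_spec(),
                             duration_s = 60, dt_s = 0.1,
                             pp = photophysics_params()) {
  stopifnot(duration_s > 0, dt_s > 0)
  buffers <- .luminal_buffers(solution, params)
  sub_mM <- if (solution$substitute_anion == "none") 0 else
    solution$substitute_mM
  Cl0 <- .molecules(solution$chloride_mM, params$volume_l)
  env <- list(params = params, buffers = buffers, sub_mM = sub_mM,
              Cl0 = Cl0, Glu0 = 0,
              content0 = .proton_content(solution$ph_external, buffers,
                                         params$volume_l))

  deriv <- function(t, y, parms) {
    fl <- .vesicle_fluxes(y[["H"]], y[["Cl"]], y[["Glu"]], env)
    dH <- fl$j_pump - parms$n_h * fl$j_glu
    list(c(H = dH, Cl = fl$j_cl, Glu = fl$j_glu,
           cum_pump = fl$j_pump, cum_vglut_h = parms$n_h * fl$j_glu,
           cum_cl_in = fl$j_cl, cum_glu_in = fl$j_glu))
  }

  y0 <- c(H = 0, Cl = Cl0, Glu = 0,
          cum_pump = 0, cum_vglut_h = 0, cum_cl_in = 0, cum_glu_in = 0)
  times <- seq(0, duration_s, by = dt_s)
  sol <- deSolve::lsoda(y0, times, deriv, params,
                        rtol = 1e-8, atol = 1e-6)
  if (attr(sol, "istate")[1] < 0) {
    stop("integration error: the solver did not complete the run",
         call. = FALSE)
  }
  sol <- as.data.frame(sol)

  ph <- vapply(sol$H, function(h)
    .ph_from_content(env$content0 + h, buffers, params$volume_l),
    numeric(1))
  charge <- sol$H - (sol$Cl - Cl0) - sol$Glu
  out <- data.frame(
    time_s = sol$time,
    ph = ph,
    dpsi_mV = charge * .const$e_charge / params$capacitance_F * 1e3,
    cl_mM = .mM(sol$Cl, params$volume_l),
    glu_mM = .mM(sol$Glu, params$volume_l),
    dF = deltaF_from_pH(pmin(pmax(ph, 3), 10), pp),
    h_total = sol$H,
    charge = charge,
    cum_pump = sol$cum_pump,
    cum_vglut_h = sol$cum_vglut_h,
    cum_cl_in = sol$cum_cl_in,
    cum_glu_in = sol$cum_glu_in)
  attr(out, "params") <- params
  attr(out, "solution") <- solution
  attr(out, "buffers") <- buffers
  class(out) <- c("vesicle_timecourse", "data.frame")
  out
}

#' Named experimental scenarios of the flux model
#'
#' Returns the engulfed solution and parameter overrides of the named
#' condition. Available scenarios: `control` (normal chloride),
#' `rb` (transport inhibitor, normal chloride), `uncoupled`
#' (inhibitor plus full methanesulfonate substitution, 25 mM HEPES; alias
#' `rb_mes_hepes25`), `rb_mes_hepes5`, `gluc_hepes25`, `gluc_hepes20`,
#' `gluc_hepes5`, `mes_hepes25` (substitutions with active transport),
#' `ko` (no transporter), and the chloride titration `cl100`, `cl70`,
#' `cl40`, `cl10.5`. Inhibitor conditions include the 10 mM histidine
#' added to the bath in those experiments.
#'
#' @param name scenario name.
#' @param params base [flux_params()] to modify.
#' @return List with elements `params` and `solution`.
#' @export
flux_scenario <- function(name, params = flux_params()) {
  rb <- function(p) { p$rb_block <- TRUE; p }
  sol <- function(cl, sub = "none", sub_mM = 0, hepes = 25, his = 0)
    solution_spec(chloride_mM = cl, substitute_anion = sub,
                  substitute_mM = sub_mM, hepes_mM = hepes,
                  histidine_mM = his)
  if (identical(name, "rb_mes_hepes25")) name <- "uncoupled"
  switch(
    name,
    control = list(params = params, solution = sol(129.5)),
    rb = list(params = rb(params), solution = sol(129.5, his = 10)),
    uncoupled = list(params = rb(params),
                     solution = sol(10.5, "methanesulfonate", 119,
                                    hepes = 25, his = 10)),
    rb_mes_hepes5 = list(params = rb(params),
                         solution = sol(10.5, "methanesulfonate", 119,
                                        hepes = 5, his = 10)),
    gluc_hepes25 = list(params = params,
                        solution = sol(10.5, "gluconate", 119, hepes = 25)),
    gluc_hepes20 = list(params = params,
                        solution = sol(10.5, "gluconate", 119, hepes = 20)),
    gluc_hepes5 = list(params = params,
                       solution = sol(10.5, "gluconate", 119, hepes = 5)),
    mes_hepes25 = list(params = params,
                       solution = sol(10.5, "methanesulfonate", 119,
                                      hepes = 25)),
    ko = { p <- params; p$n_vglut <- 0
           list(params = p, solution = sol(129.5)) },
    cl100 = list(params = params,
                 solution = sol(100, "gluconate", 29.5)),
    cl70 = list(params = params,
                solution = sol(70, "gluconate", 59.5)),
    cl40 = list(params = params,
                solution = sol(40, "gluconate", 89.5)),
    `cl10.5` = list(params = params,
                    solution = sol(10.5, "gluconate", 119)),
    stop("unknown scenario: ", name, call. = FALSE)
  )
}

#' Fit the acidification time constant of a simulated time course
#'
#' Mono-exponential fit of the predicted normalized fluorescence decay,
#' the same operation applied to measured traces.
#'
#' @param tc a `vesicle_timecourse` from [simulate_vesicle()].
#' @return An `exp_fit` object (see [fit_monoexponential()]).
#' @export
timecourse_tau <- function(tc) {
  fit_monoexponential(tc$time_s, tc$dF)
}

#' Run the standard scenario battery
#'
#' Simulates every named scenario and summarises each with the fitted
#' acidification time constant, the plateau (end-of-run) luminal pH and
#' the final glutamate and chloride concentrations.
#'
#' @param scenarios character vector of [flux_scenario()] names.
#' @param params base [flux_params()].
#' @param duration_s simulated seconds per scenario.
#' @param dt_s output sampling interval.
#' @return Data frame with one row per scenario: `scenario`, `tau_s`,
#'   `plateau_ph`, `glu_mM`, `cl_mM`, `converged`.
#' @export
scenario_suite <- function(scenarios = c("control", "rb", "uncoupled",
                                         "rb_mes_hepes5",
                                         "gluc_hepes25", "gluc_hepes20",
                                         "gluc_hepes5", "mes_hepes25",
                                         "ko", "cl100", "cl70", "cl40",
                                         "cl10.5"),
                           params = flux_params(),
                           duration_s = 60, dt_s = 0.1) {
  rows <- lapply(scenarios, function(nm) {
    sc <- flux_scenario(nm, params)
    tc <- simulate_vesicle(sc$params, sc$solution,
                           duration_s = duration_s, dt_s = dt_s)
    ft <- timecourse_tau(tc)
    n <- nrow(tc)
    data.frame(scenario = nm,
               tau_s = if (ft$converged) ft$tau else NA_real_,
               plateau_ph = tc$ph[n],
               glu_mM = tc$glu_mM[n],
               cl_mM = tc$cl_mM[n],
               converged = ft$converged)
  })
  do.call(rbind, rows)
}

#' Audit the conservation ledgers of a simulated time course
#'
#' Checks, at every output time, (i) charge conservation: the net charge
#' on the capacitance equals pumped-in protons minus exported protons
#' minus imported anions, and (ii) proton mass balance: the change in
#' total luminal protons (free plus buffer-bound) equals pumped-in minus
#' exported protons.
#'
#' @param tc a `vesicle_timecourse`.
#' @return List with `max_charge_err` and `max_proton_err` (molecules).
#' @export
conservation_ledger <- function(tc) {
  charge_pred <- tc$cum_pump - tc$cum_vglut_h - tc$cum_cl_in - tc$cum_glu_in
  proton_pred <- tc$cum_pump - tc$cum_vglut_h
  list(max_charge_err = max(abs(tc$charge - charge_pred)),
       max_proton_err = max(abs(tc$h_total - proton_pred)))
}
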