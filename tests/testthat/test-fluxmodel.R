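# Simulations here use coarse sampling where only endpoints matter and
# fine sampling where a fast decay is fitted.

test_that("zero-flux parameters leave the state constant and ledgers at
           zero", {
  p <- flux_params(n_pumps = 0, n_vglut = 0)
  tc <- simulate_vesicle(p, solution_spec(), duration_s = 10, dt_s = 0.5)
  expect_lt(max(abs(tc$ph - 7.3)), 1e-9)
  expect_equal(max(abs(tc$cl_mM - 129.5)), 0)
  expect_equal(max(abs(tc$glu_mM)), 0)
  led <- conservation_ledger(tc)
  expect_lt(led$max_charge_err, 1e-6)
  expect_lt(led$max_proton_err, 1e-6)
})

test_that("charge and proton ledgers balance exactly along a control run", {
  sc <- flux_scenario("control")
  tc <- simulate_vesicle(sc$params, sc$solution, duration_s = 60,
                         dt_s = 0.25)
  led <- conservation_ledger(tc)
  expect_lt(led$max_charge_err, 1e-6)   # fraction of one charge
  expect_lt(led$max_proton_err, 1e-6)
  # membrane potential is the standing charge over the capacitance
  expect_equal(tc$dpsi_mV,
               tc$charge * 1.602176634e-19 / 50e-18 * 1e3,
               tolerance = 1e-12)
})

test_that("control scenario reaches the measured kinetics and endpoints", {
  sc <- flux_scenario("control")
  tc <- simulate_vesicle(sc$params, sc$solution, duration_s = 60,
                         dt_s = 0.1)
  ft <- timecourse_tau(tc)
  expect_true(ft$converged)
  expect_equal(ft$tau, 4.9, tolerance = 0.3)        # measured 4.9 +/- 0.3 s
  n <- nrow(tc)
  expect_equal(tc$ph[n], 5.5, tolerance = 0.1)
  expect_equal(tc$glu_mM[n], 120, tolerance = 5)
  # most engulfed chloride is replaced by glutamate
  expect_lt(tc$cl_mM[n], 35)
  expect_gt(tc$cum_vglut_h[n] / tc$cum_pump[n], 0.75)  # H+ mostly shunted
})

test_that("uncoupled scenario acidifies an order of magnitude faster and
           matches the closed-form budget", {
  sc <- flux_scenario("uncoupled")
  tc <- simulate_vesicle(sc$params, sc$solution, duration_s = 20,
                         dt_s = 0.02)
  ft <- timecourse_tau(tc)
  expect_true(ft$converged)
  expect_equal(ft$tau, 0.5, tolerance = 0.1)        # measured 0.5 +/- 0.1 s
  # closed-form: protons bound down to the 1/e fluorescence point over
  # the maximal pump current
  b <- c(list(buffer_species("HEPES", 25, 7.55),
              buffer_species("histidine", 10, 6)), endogenous_buffers())
  tau_cf <- bound_protons(b, 7.3, 6.4, 20e-21) / (1.5 * 200)
  expect_equal(ft$tau, tau_cf, tolerance = 0.15 * tau_cf)
})

test_that("transport inhibition at normal chloride blocks re-acidification", {
  sc <- flux_scenario("rb")
  tc <- simulate_vesicle(sc$params, sc$solution, duration_s = 60,
                         dt_s = 0.25)
  n <- nrow(tc)
  expect_gt(tc$ph[n], 7.0)           # lumen stays near neutral
  expect_gt(tc$dF[n], 0.8)           # fluorescence does not recover
  # the chloride-generated membrane potential stalls the pump
  expect_gt(tc$dpsi_mV[n], 45)
})

test_that("plateau pH ranks with exogenous buffer under gluconate
           substitution", {
  ph_end <- sapply(c("gluc_hepes25", "gluc_hepes20", "gluc_hepes5"),
                   function(nm) {
                     sc <- flux_scenario(nm)
                     tc <- simulate_vesicle(sc$params, sc$solution,
                                            duration_s = 60, dt_s = 0.25)
                     tc$ph[nrow(tc)]
                   })
  expect_true(ph_end[1] > ph_end[2] && ph_end[2] > ph_end[3])
})

test_that("gluconate and methanesulfonate substitution give
           indistinguishable kinetics", {
  taus <- sapply(c("gluc_hepes25", "mes_hepes25"), function(nm) {
    sc <- flux_scenario(nm)
    tc <- simulate_vesicle(sc$params, sc$solution, duration_s = 30,
                           dt_s = 0.02)
    timecourse_tau(tc)$tau
  })
  expect_equal(unname(taus[1]), unname(taus[2]), tolerance = 0.05)
})

test_that("acidification slows monotonically with buffer concentration
           when transport is uncoupled", {
  taus <- sapply(c(10, 25, 40), function(h) {
    sc <- flux_scenario("uncoupled")
    sc$solution$hepes_mM <- h
    tc <- simulate_vesicle(sc$params, sc$solution, duration_s = 15,
                           dt_s = 0.02)
    timecourse_tau(tc)$tau
  })
  expect_true(all(diff(taus) > 0))
})

test_that("with pumps off, filling is electrically near-neutral", {
  p <- flux_params(n_pumps = 0, n_h = 0)
  tc <- simulate_vesicle(p, solution_spec(), duration_s = 30, dt_s = 0.1)
  gross <- tc$cum_glu_in[nrow(tc)] + abs(tc$cum_cl_in[nrow(tc)])
  expect_gt(gross, 500)                    # substantial exchange happened
  expect_lt(max(abs(tc$charge)) / gross, 0.02)
})

test_that("parameter validation and scenario lookup reject bad input", {
  expect_error(flux_params(n_h = 3), "n_h")
  expect_error(flux_params(n_h = 0.5), "n_h")
  expect_error(flux_params(volume_l = -1))
  expect_error(flux_scenario("nope"), "unknown scenario")
  expect_error(simulate_vesicle(duration_s = -5))
})

test_that("scenario suite returns one summarised row per scenario", {
  s <- scenario_suite(scenarios = c("control", "rb"), duration_s = 30,
                      dt_s = 0.25)
  expect_equal(s$scenario, c("control", "rb"))
  expect_true(s$converged[1])
  expect_false(s$converged[2])            # no decay to fit under block
  expect_gt(s$plateau_ph[2], 7)
  expect_lt(s$plateau_ph[1], 5.8)
})
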