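test_that("protocol arithmetic and validation", {
  p <- make_protocol(5, 200, 20)
  expect_equal(p$stim_duration_s, 10)
  p2 <- make_protocol(5, 240, 20, quench = TRUE)
  expect_equal(p2$stim_duration_s, 12)
  expect_equal(p2$quench_window[1], p2$stim_window[2])  # opens at stim end
  expect_error(make_protocol(5, 0, 20), "positive")
  expect_error(make_protocol(-1, 200, 20), "positive")
  # windows are disjoint and inside the stack
  expect_lte(p$baseline_window[2], p$stim_window[1])
  expect_lte(p$stim_window[2], p$n_frames)
})

test_that("trace generation is seed-deterministic and noiseless traces
           carry the exact time constant", {
  proto <- test_protocol()
  a <- simulate_truth_traces(proto, n_boutons = 5, noise_sd = 0.02,
                             seed = 99)
  b <- simulate_truth_traces(proto, n_boutons = 5, noise_sd = 0.02,
                             seed = 99)
  expect_identical(a$traces, b$traces)
  expect_error(simulate_truth_traces(proto, 5, noise_sd = -1), "noise_sd")

  clean <- simulate_truth_traces(proto, n_boutons = 1, noise_sd = 0,
                                 seed = 1)
  tr <- clean$traces[[1]]
  post <- seq.int(proto$stim_window[2] + 1L, proto$n_frames)
  ft <- fit_monoexponential(tr$time_s[post], tr$F[post])
  expect_true(ft$converged)
  expect_equal(ft$tau, 4.9, tolerance = 1e-4)
})

test_that("inhibited fraction is recovered by the classifier", {
  proto <- test_protocol()
  probe <- simulate_truth_traces(proto, n_boutons = 100,
                                 frac_inhibited = 0, noise_sd = 0.02,
                                 seed = 21)
  post <- simulate_truth_traces(proto, n_boutons = 100,
                                frac_inhibited = 0.3, noise_sd = 0.02,
                                seed = 22)
  cls <- classify_boutons(probe$traces, post$traces, proto)
  frac <- mean(cls$class == "inhibited")
  # binomial 95% band around 0.30 at n = 100
  expect_gt(frac, 0.30 - 1.96 * sqrt(0.3 * 0.7 / 100))
  expect_lt(frac, 0.30 + 1.96 * sqrt(0.3 * 0.7 / 100))
  expect_setequal(
    cls$class[post$truth$boutons$class == "inhibited"], "inhibited")
})

test_that("ground truth serialises losslessly", {
  proto <- test_protocol(quench = TRUE)
  sim <- simulate_truth_traces(proto, n_boutons = 7, seed = 3)
  f <- tempfile(fileext = ".json")
  write_ground_truth(sim$truth, f)
  back <- read_ground_truth(f)
  expect_equal(back$seed, sim$truth$seed)
  expect_equal(back$boutons, sim$truth$boutons, tolerance = 1e-12)
  expect_equal(back$protocol$stim_window, proto$stim_window)
  expect_equal(back$protocol$quench_window, proto$quench_window)
  expect_equal(back$protocol$solution$chloride_mM,
               proto$solution$chloride_mM)
  unlink(f)
})

test_that("trace CSV round trip preserves values and channels", {
  proto <- test_protocol()
  sim <- simulate_truth_traces(proto, n_boutons = 4,
                               frac_gabaergic = 0.25, seed = 8)
  f <- tempfile(fileext = ".csv")
  write_trace_csv(sim$traces, f)
  back <- read_trace_csv(f)
  expect_setequal(names(back), names(sim$traces))
  for (id in names(back)) {
    expect_equal(back[[id]]$F, sim$traces[[id]]$F, tolerance = 1e-9)
    expect_equal(attr(back[[id]], "channel"),
                 attr(sim$traces[[id]], "channel"))
  }
  unlink(f)
})

test_that("rendered spots integrate to the analytic Gaussian flux", {
  proto <- test_protocol(post_s = 5)
  sim <- simulate_truth_traces(
    proto, n_boutons = 1,
    kinetics = list(tau_glut = 4.9, tau_gaba = 4.9, plateau_glut = 0,
                    plateau_inhib = 0.985, amplitude_mean = 80,
                    amplitude_sd = 0, baseline = 500),
    noise_sd = 0, seed = 2)
  st <- render_image_stack(sim$traces, positions = cbind(24, 24),
                           field_size = 48, psf_sigma = 1.5,
                           background = 7, noise_model = "none")
  # frame at the stimulation climax: spot amplitude = 80
  f <- proto$stim_window[2]
  total <- sum(st$stack[f, , ]) - 7 * 48 * 48
  amp <- sim$traces[[1]]$F[f] - sim$traces[[1]]$F[1]
  expect_equal(total, amp * 2 * pi * 1.5^2, tolerance = 1e-3)
  # zero-amplitude traces give pure background
  zero <- sim
  zero$traces[[1]]$F[] <- 123
  st0 <- render_image_stack(zero$traces, positions = cbind(24, 24),
                            field_size = 48, background = 7,
                            noise_model = "none")
  expect_equal(max(abs(st0$stack - 7)), 0)
  expect_error(render_image_stack(sim$traces, positions = cbind(999, 2),
                                  field_size = 48), "outside")
})

test_that("Poisson-rendered flat regions have variance close to the mean", {
  proto <- test_protocol(post_s = 2)
  sim <- simulate_truth_traces(proto, n_boutons = 1, noise_sd = 0,
                               seed = 2)
  st <- render_image_stack(sim$traces, positions = cbind(8, 8),
                           field_size = 64, background = 50,
                           noise_model = "poisson", seed = 13)
  flat <- st$stack[, 33:64, 33:64]  # far from the spot
  expect_equal(var(as.numeric(flat)) / mean(flat), 1, tolerance = 0.05)
})

test_that("TIFF round trip preserves a 16-bit stack", {
  st <- array(round(runif(4 * 16 * 16, 0, 4000)), dim = c(4, 16, 16))
  f <- tempfile(fileext = ".tif")
  write_stack_tiff(st, f)
  back <- read_stack_tiff(f)
  expect_equal(dim(back), dim(st))
  expect_equal(back, st, tolerance = 0.51)  # integer quantisation only
  unlink(f)
})
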