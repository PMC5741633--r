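# a small stack with spots whose amplitude follows the stimulation window
synth_stack <- function(positions, amp = 50, noise = 0, seed = 1,
                        field = 48, proto = test_protocol(post_s = 10)) {
  sim <- simulate_truth_traces(
    proto, n_boutons = nrow(positions),
    kinetics = list(tau_glut = 4.9, tau_gaba = 4.9, plateau_glut = 0,
                    plateau_inhib = 0.985, amplitude_mean = amp,
                    amplitude_sd = 0, baseline = 100),
    noise_sd = 0, seed = seed)
  st <- render_image_stack(sim$traces, positions = positions,
                           field_size = field, psf_sigma = 1.5,
                           background = 10,
                           noise_model = if (noise > 0) "gaussian" else
                             "none",
                           noise_sd = noise, seed = seed)
  list(stack = st$stack, proto = proto, truth = sim$truth)
}

test_that("difference image isolates the stimulated spot amplitude", {
  pos <- cbind(24, 24)
  s <- synth_stack(pos)
  di <- difference_image(s$stack, s$proto)
  # peak of the difference equals the mean end-of-stimulation spot
  # amplitude times the PSF peak (= 1 at the centre pixel)
  tr <- s$truth
  sw <- seq.int(s$proto$stim_window[1] + 1L, s$proto$stim_window[2])
  tt <- protocol_times(s$proto)
  ramp <- (tt - s$proto$stim_start_s) / s$proto$stim_duration_s
  amp_end <- 50 * mean(utils::tail(ramp[sw], 3))
  expect_equal(max(di), amp_end, tolerance = 1e-6)
  expect_equal(which(di == max(di), arr.ind = TRUE)[1, ],
               c(row = 25, col = 25))
  # identical baseline and stimulation frames give a zero image
  flat <- s$stack
  for (f in seq_len(dim(flat)[1])) flat[f, , ] <- s$stack[1, , ]
  expect_equal(max(abs(difference_image(flat, s$proto))), 0)
})

test_that("negative-going channels are detected with the sign flag", {
  pos <- cbind(24, 24)
  s <- synth_stack(pos)
  neg <- -s$stack
  di <- difference_image(neg, s$proto, sign = -1)
  expect_gt(max(di), 40)
})

test_that("a bright spot yields one component within 1 px of truth", {
  pos <- cbind(20.0, 27.0)
  s <- synth_stack(pos, amp = 50, noise = 1, seed = 3)
  di <- difference_image(s$stack, s$proto)
  m <- detection_mask(atrous_transform(di, 4), detection_params())
  expect_equal(m$n_components, 1)
  expect_lt(abs(m$centroids$centroid_row - 20), 1)
  expect_lt(abs(m$centroids$centroid_col - 27), 1)
})

test_that("pure noise yields a tiny false-positive area; zero image none", {
  fp <- numeric(20)
  for (s in 1:20) {
    set.seed(100 + s)
    img <- matrix(rnorm(48 * 48), 48, 48)
    m <- detection_mask(atrous_transform(img, 4), detection_params())
    fp[s] <- sum(m$mask) / length(m$mask)
  }
  expect_lt(mean(fp), 0.005)
  m0 <- detection_mask(atrous_transform(matrix(0, 32, 32), 4))
  expect_equal(m0$n_components, 0)
  expect_false(accept_experiment(m0))
})

test_that("detection is equivariant under whole-pixel translation", {
  set.seed(5)
  base <- matrix(0, 64, 64)
  for (p in list(c(20, 20), c(40, 28), c(28, 44))) {
    g <- exp(-((row(base) - p[1])^2 + (col(base) - p[2])^2) / (2 * 1.5^2))
    base <- base + 40 * g
  }
  noise <- matrix(rnorm(64 * 64), 64, 64)
  img1 <- base + noise
  sh <- 4
  img2 <- rbind(matrix(0, sh, 64), base[1:(64 - sh), ]) + noise
  c1 <- detection_mask(atrous_transform(img1, 4))$centroids
  c2 <- detection_mask(atrous_transform(img2, 4))$centroids
  expect_equal(nrow(c1), 3)
  expect_equal(nrow(c2), 3)
  o1 <- c1[order(c1$centroid_row), ]
  o2 <- c2[order(c2$centroid_row), ]
  expect_equal(o2$centroid_row, o1$centroid_row + sh, tolerance = 0.3)
  expect_equal(o2$centroid_col, o1$centroid_col, tolerance = 0.3)
})

test_that("trace extraction returns exact means and cancels offsets", {
  pos <- rbind(c(15, 15), c(32, 34))
  s <- synth_stack(pos, amp = 60, seed = 4)
  di <- difference_image(s$stack, s$proto)
  m <- detection_mask(atrous_transform(di, 4))
  expect_equal(m$n_components, 2)
  tr <- extract_traces(s$stack, m, protocol = s$proto)
  expect_length(tr, 2)
  # uniform additive offset on every frame cancels through the ring
  off <- s$stack + 17
  tr2 <- extract_traces(off, m, protocol = s$proto)
  for (i in 1:2) expect_equal(tr2[[i]]$F, tr[[i]]$F, tolerance = 1e-9)
  # extracted kinetics match the generating time constants
  for (i in 1:2) {
    post <- seq.int(s$proto$stim_window[2] + 1L, s$proto$n_frames)
    ft <- fit_monoexponential(tr[[i]]$time_s[post], tr[[i]]$F[post])
    expect_true(ft$converged)
    expect_equal(ft$tau, 4.9, tolerance = 0.05)
  }
  # zero ring width returns plain component means
  tr3 <- extract_traces(s$stack, m, ring_width = 0, protocol = s$proto)
  i1 <- which(m$labels == 1)
  flat <- matrix(s$stack, nrow = dim(s$stack)[1])
  expect_equal(tr3[[1]]$F, rowMeans(flat[, i1, drop = FALSE]))
})

test_that("experiment acceptance uses a strict bouton-count inequality", {
  fake <- structure(list(n_components = 51), class = "bouton_mask")
  expect_true(accept_experiment(fake, detection_params()))
  fake$n_components <- 50
  expect_false(accept_experiment(fake, detection_params()))
})
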