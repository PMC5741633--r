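# Independent oracles used by the tests. These deliberately do not share
# code with the package implementation.

# brute-force separable convolution with an explicitly dilated B3 kernel
# and mirror boundaries, written index-by-index
oracle_b3_smooth <- function(img, dil) {
  w <- c(1, 4, 6, 4, 1) / 16
  off <- c(-2, -1, 0, 1, 2) * dil
  refl <- function(p, n) {
    while (p < 1 || p > n) {
      if (p < 1) p <- 2 - p
      if (p > n) p <- 2 * n - p
    }
    p
  }
  nr <- nrow(img); nc <- ncol(img)
  tmp <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    s <- 0
    for (u in 1:5) s <- s + w[u] * img[refl(i + off[u], nr), j]
    tmp[i, j] <- s
  }
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    s <- 0
    for (u in 1:5) s <- s + w[u] * tmp[i, refl(j + off[u], nc)]
    out[i, j] <- s
  }
  out
}

# bisection inversion of the forward fluorescence map
oracle_ph_from_dF <- function(dF, pp = photophysics_params()) {
  stats::uniroot(function(p) deltaF_from_pH(p, pp) - dF, c(3, 10),
                 tol = 1e-12)$root
}

# small default protocol for trace tests: 2 Hz acquisition, short tail
test_protocol <- function(quench = FALSE, post_s = 30, frame_rate = 2) {
  make_protocol(frame_rate = frame_rate, n_aps = 200, ap_rate = 20,
                quench = quench, baseline_s = 5, post_s = post_s)
}
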