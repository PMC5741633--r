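#' Render a synthetic fluorescence image stack from truth traces
#'
#' Places each bouton as an isotropic Gaussian spot at a fixed pixel
#' position; frame `f` is
#' `background + sum_i trace_i(f) * G(pos_i, psf_sigma) + noise`.
#' The noise-free integrated intensity of a spot equals
#' `trace_value * 2 * pi * psf_sigma^2`. Coordinates are 0-based,
#' row-major, with pixel centres at integers.
#'
#' @param traces named list of bouton trace data frames (e.g. from
#'   [simulate_truth_traces()]); trace values are used as spot amplitudes
#'   above background.
#' @param positions two-column matrix (row, col) of 0-based bouton
#'   centres; defaults to a seeded uniform draw away from the borders.
#' @param field_size image side length in pixels (square field).
#' @param psf_sigma Gaussian point-spread sigma, pixels (> 0).
#' @param background constant background level, counts.
#' @param baseline_subtract subtract each trace's first-frame value so
#'   spots ride on `background` rather than on the trace baseline.
#' @param noise_model `"none"`, `"gaussian"` (s.d. `noise_sd` counts) or
#'   `"poisson"`.
#' @param noise_sd Gaussian read-noise s.d., counts.
#' @param seed integer seed for positions and noise.
#' @return List with `stack` (array frame x row x col), `positions`, and
#'   `truth` carrying the generation parameters.
#' @export
render_image_stack <- function(traces, positions = NULL, field_size = 96,
                               psf_sigma = 1.5, background = 100,
                               baseline_subtract = TRUE,
                               noise_model = c("none", "gaussian",
                                               "poisson"),
                               noise_sd = 2, seed = 1) {
  noise_model <- match.arg(noise_model)
  if (psf_sigma <= 0) stop("psf_sigma must be positive", call. = FALSE)
  n_b <- length(traces)
  set.seed(seed)
  if (is.null(positions)) {
    m <- ceiling(4 * psf_sigma)
    positions <- cbind(
      row = stats::runif(n_b, m, field_size - 1 - m),
      col = stats::runif(n_b, m, field_size - 1 - m))
  }
  positions <- as.matrix(positions)
  if (any(positions < 0) || any(positions > field_size - 1)) {
    stop("bouton positions outside the field", call. = FALSE)
  }
  n_f <- nrow(traces[[1]])
  amp <- sapply(traces, function(tr) {
    a <- tr$F
    if (baseline_subtract) a <- a - a[1]
    a
  })                                       # n_f x n_b
  amp <- matrix(amp, nrow = n_f)

  rc <- 0:(field_size - 1)
  stack <- array(background, dim = c(n_f, field_size, field_size))
  spot <- vector("list", n_b)
  for (i in seq_len(n_b)) {
    gr <- exp(-(rc - positions[i, 1])^2 / (2 * psf_sigma^2))
    gc <- exp(-(rc - positions[i, 2])^2 / (2 * psf_sigma^2))
    spot[[i]] <- outer(gr, gc)
  }
  for (f in seq_len(n_f)) {
    frame <- matrix(0, field_size, field_size)
    for (i in seq_len(n_b)) frame <- frame + amp[f, i] * spot[[i]]
    stack[f, , ] <- stack[f, , ] + frame
  }
  if (noise_model == "gaussian") {
    stack <- stack + array(stats::rnorm(length(stack), 0, noise_sd),
                           dim = dim(stack))
  } else if (noise_model == "poisson") {
    stack <- array(stats::rpois(length(stack), pmax(stack, 0)),
                   dim = dim(stack))
  }
  list(stack = stack, positions = positions,
       truth = list(seed = seed, field_size = field_size,
                    psf_sigma = psf_sigma, background = background,
                    noise_model = noise_model, noise_sd = noise_sd))
}

#' Write / read an image stack as multi-page 16-bit TIFF
#'
#' Values are clipped to `[0, 65535]` and stored as unsigned 16-bit.
#'
#' @param stack array frame x row x col.
#' @param path TIFF path.
#' @return `write_stack_tiff` returns `path` invisibly; `read_stack_tiff`
#'   returns the stack array (counts).
#' @export
write_stack_tiff <- function(stack, path) {
  pages <- lapply(seq_len(dim(stack)[1]), function(f) {
    m <- pmin(pmax(stack[f, , ], 0), 65535)
    m / 65535                       # tiff stores [0,1] scaled samples
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  stack <- array(0, dim = c(length(pages), nrow(pages[[1]]),
                            ncol(pages[[1]])))
  for (f in seq_along(pages)) stack[f, , ] <- pages[[f]] * 65535
  stack
}
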