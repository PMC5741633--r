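# mirror (whole-sample) reflection of out-of-range indices into 1..n
.reflect_idx <- function(p, n) {
  p <- ((p - 1) %% (2 * n - 2)) + 1
  ifelse(p > n, 2 * n - p, p)
}

# separable convolution with the 1-D kernel [1,4,6,4,1]/16 dilated by
# `dil` (zeros inserted between taps), mirror boundary handling
.b3_smooth <- function(img, dil) {
  w <- c(1, 4, 6, 4, 1) / 16
  off <- c(-2, -1, 0, 1, 2) * dil
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (i in seq_along(w)) {                       # along rows
    out <- out + w[i] * img[.reflect_idx(seq_len(nr) + off[i], nr), ,
                            drop = FALSE]
  }
  out2 <- matrix(0, nr, nc)
  for (i in seq_along(w)) {                       # along columns
    out2 <- out2 + w[i] * out[, .reflect_idx(seq_len(nc) + off[i], nc),
                              drop = FALSE]
  }
  out2
}

#' Undecimated (a trous) B3-spline wavelet transform
#'
#' Starlet decomposition of a 2-D image into `k` detail planes and one
#' smooth residual. Plane `j` is the difference between successive
#' B3-spline smoothings with the kernel `[1,4,6,4,1]/16` dilated by
#' `2^(j-1)`; boundaries are handled by mirror reflection. The transform
#' is exactly invertible: `image = smooth + sum(details)`.
#'
#' @param image 2-D numeric matrix with finite entries.
#' @param k decomposition depth (>= 1).
#' @return List with `details` (list of `k` matrices, fine to coarse) and
#'   `smooth` (the residual smooth plane).
#' @export
atrous_transform <- function(image, k = 4) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("image must be a 2-D numeric matrix", call. = FALSE)
  }
  if (!all(is.finite(image))) {
    stop("image must be finite everywhere", call. = FALSE)
  }
  stopifnot(k >= 1)
  details <- vector("list", k)
  cur <- image
  for (j in seq_len(k)) {
    sm <- .b3_smooth(cur, 2^(j - 1))
    details[[j]] <- cur - sm
    cur <- sm
  }
  list(details = details, smooth = cur)
}
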