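#' Detection parameters for wavelet bouton detection
#'
#' @param k wavelet decomposition depth.
#' @param ld detection level: scaling applied to the per-plane robust
#'   noise threshold.
#' @param k_mad threshold constant multiplying the MAD-based plane noise
#'   estimate (the published detection level `ld` scales this).
#' @param min_boutons minimum number of active boutons for an experiment
#'   to be accepted (strictly more than this are required).
#' @param min_area_px discard components smaller than this (sub-PSF).
#' @param connectivity pixel connectivity for component labelling (8 is
#'   used; recorded for provenance).
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(k = 4, ld = 1.0, k_mad = 3, min_boutons = 50,
                             min_area_px = 4, connectivity = 8) {
  stopifnot(k >= 1)
  if (ld <= 0) stop("ld must be positive", call. = FALSE)
  structure(list(k = k, ld = ld, k_mad = k_mad, min_boutons = min_boutons,
                 min_area_px = min_area_px, connectivity = connectivity),
            class = "detection_params")
}

#' Stimulation difference image of a stack
#'
#' Mean of the frames at the end of the stimulation window (the
#' fluorescence climax) minus the mean of the baseline frames — the image
#' in which functional boutons light up.
#'
#' @param stack array frame x row x col.
#' @param protocol the [make_protocol()] object describing the windows.
#' @param end_frames number of frames at the end of stimulation to
#'   average.
#' @param sign `+1` for reporters that brighten on stimulation, `-1` for
#'   negative-going (CypHer-like) channels.
#' @return Matrix of the same field size.
#' @export
difference_image <- function(stack, protocol, end_frames = 3, sign = 1) {
  bl <- .window_idx(protocol$baseline_window)
  sw <- .window_idx(protocol$stim_window)
  if (length(bl) == 0 || length(sw) == 0) {
    stop("empty baseline or stimulation window", call. = FALSE)
  }
  se <- sw[seq.int(max(1, length(sw) - end_frames + 1), length(sw))]
  m_end <- apply(stack[se, , , drop = FALSE], c(2, 3), mean)
  m_base <- apply(stack[bl, , , drop = FALSE], c(2, 3), mean)
  sign * (m_end - m_base)
}

# robust noise scale of a detail plane (MAD / 0.6745)
.plane_sigma <- function(p) {
  stats::median(abs(p - stats::median(p))) / 0.6745
}

# l2 norms of the equivalent wavelet filters per level: the factor by
# which unit white noise appears in each detail plane. Computed exactly
# from the impulse response of the transform.
.atrous_noise_factors <- function(k) {
  L <- 8 * 2^k + 1
  delta <- matrix(0, L, L)
  delta[(L + 1) / 2, (L + 1) / 2] <- 1
  at <- atrous_transform(delta, k)
  vapply(at$details, function(d) sqrt(sum(d^2)), numeric(1))
}

# two-pass 8-connected labelling via union-find
.label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  nxt <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j]) next
    nb <- integer(0)
    if (i > 1 && lab[i - 1, j] > 0) nb <- c(nb, lab[i - 1, j])
    if (j > 1) {
      if (lab[i, j - 1] > 0) nb <- c(nb, lab[i, j - 1])
      if (lab[i - 1, j - 1] > 0 && i > 1) nb <- c(nb, lab[i - 1, j - 1])
      if (i < nr && lab[i + 1, j - 1] > 0) nb <- c(nb, lab[i + 1, j - 1])
    }
    if (length(nb) == 0) {
      nxt <- nxt + 1L; parent[nxt] <- nxt; lab[i, j] <- nxt
    } else {
      roots <- vapply(unique(nb), find, integer(1))
      r <- min(roots)
      lab[i, j] <- r
      for (x in roots) parent[x] <- r
    }
  }
  if (nxt > 0) {
    roots <- vapply(seq_len(nxt), find, integer(1))
    remap <- integer(nxt)
    remap[sort(unique(roots))] <- seq_along(unique(roots))
    pos <- which(lab > 0)
    lab[pos] <- remap[roots[lab[pos]]]
  }
  lab
}

#' Bouton mask from thresholded wavelet planes
#'
#' Each detail plane `j` from [atrous_transform()] is hard-thresholded at
#' `ld * k_mad * sigma_j`. The per-plane noise scale `sigma_j` is the
#' image noise propagated through the transform: the robust noise of the
#' finest plane (median absolute deviation / 0.6745, which is
#' signal-insensitive there) divided by that plane's equivalent-filter
#' norm and multiplied by plane `j`'s norm. The mask is the support of
#' the multiscale product of the thresholded planes 2..k (the finest
#' plane is noise-dominated and excluded); components smaller than
#' `min_area_px` are discarded.
#'
#' @param planes output of [atrous_transform()].
#' @param params a [detection_params()] object.
#' @return An object of class `bouton_mask`: list with `mask` (logical
#'   matrix), `labels` (integer component labels), `centroids` (0-based
#'   data frame `id`, `centroid_row`, `centroid_col`, `area_px`,
#'   `on_border`), `n_components`.
#' @export
detection_mask <- function(planes, params = detection_params()) {
  k <- length(planes$details)
  use <- if (k >= 2) 2:k else 1
  fac <- .atrous_noise_factors(k)
  sigma0 <- .plane_sigma(planes$details[[1]]) / fac[1]
  prod_plane <- NULL
  for (j in use) {
    p <- planes$details[[j]]
    thr <- params$ld * params$k_mad * sigma0 * fac[j]
    w <- ifelse(p > thr, p, 0)
    prod_plane <- if (is.null(prod_plane)) w else prod_plane * w
  }
  mask <- prod_plane > 0
  lab <- .label_components(mask)
  n0 <- max(lab)
  cent <- NULL
  if (n0 > 0) {
    areas <- tabulate(lab[lab > 0], nbins = n0)
    keep <- which(areas >= params$min_area_px)
    remap <- integer(n0)
    remap[keep] <- seq_along(keep)
    pos <- which(lab > 0)
    lab[pos] <- remap[lab[pos]]
    mask <- lab > 0
    if (length(keep) > 0) {
      idx <- which(lab > 0, arr.ind = TRUE)
      l <- lab[lab > 0]
      cr <- tapply(idx[, 1], l, mean) - 1   # 0-based coordinates
      cc <- tapply(idx[, 2], l, mean) - 1
      ar <- tabulate(l, nbins = length(keep))
      nr <- nrow(mask); nc <- ncol(mask)
      border <- vapply(seq_along(keep), function(i) {
        sel <- idx[l == i, , drop = FALSE]
        any(sel[, 1] == 1 | sel[, 1] == nr | sel[, 2] == 1 |
              sel[, 2] == nc)
      }, logical(1))
      cent <- data.frame(id = seq_along(keep),
                         centroid_row = as.numeric(cr),
                         centroid_col = as.numeric(cc),
                         area_px = ar, on_border = border,
                         row.names = NULL)
    }
  }
  if (is.null(cent)) {
    cent <- data.frame(id = integer(0), centroid_row = numeric(0),
                       centroid_col = numeric(0), area_px = integer(0),
                       on_border = logical(0))
  }
  structure(list(mask = mask, labels = lab, centroids = cent,
                 n_components = nrow(cent)), class = "bouton_mask")
}

#' Extract per-bouton fluorescence time series from a stack
#'
#' For every labelled component: the mean pixel value inside the
#' component per frame, minus the median of a surrounding background ring
#' (pixels within `ring_width` of the component, excluding all
#' components). Components touching the image border are flagged
#' `on_border` in the mask centroids, not dropped.
#'
#' @param stack array frame x row x col.
#' @param mask a [detection_mask()] result sharing the stack geometry.
#' @param ring_width background ring width in pixels; 0 disables
#'   background subtraction.
#' @param protocol optional [make_protocol()]; supplies frame times
#'   (frame indices are used when absent).
#' @return Named list of trace data frames (columns `time_s`, `F`),
#'   names `b001`, `b002`, ... in label order; ids are stable across
#'   calls on the same mask.
#' @export
extract_traces <- function(stack, mask, ring_width = 2, protocol = NULL) {
  if (!all(dim(stack)[2:3] == dim(mask$labels))) {
    stop("stack and mask geometries differ", call. = FALSE)
  }
  n_f <- dim(stack)[1]
  tt <- if (is.null(protocol)) seq_len(n_f) - 1 else
    protocol_times(protocol)
  n_c <- mask$n_components
  out <- vector("list", n_c)
  any_comp <- mask$labels > 0
  nr <- nrow(any_comp); nc <- ncol(any_comp)
  flat <- matrix(stack, nrow = n_f)   # frames x (row-major pixels)
  for (i in seq_len(n_c)) {
    inside <- which(mask$labels == i)
    f_in <- rowMeans(flat[, inside, drop = FALSE])
    f_bg <- 0
    if (ring_width > 0) {
      sel <- which(mask$labels == i, arr.ind = TRUE)
      rmin <- max(1, min(sel[, 1]) - ring_width)
      rmax <- min(nr, max(sel[, 1]) + ring_width)
      cmin <- max(1, min(sel[, 2]) - ring_width)
      cmax <- min(nc, max(sel[, 2]) + ring_width)
      box <- matrix(FALSE, nr, nc)
      box[rmin:rmax, cmin:cmax] <- TRUE
      ring <- which(box & !any_comp)
      if (length(ring) > 0) {
        f_bg <- apply(flat[, ring, drop = FALSE], 1, stats::median)
      }
    }
    tr <- data.frame(time_s = tt, F = f_in - f_bg)
    attr(tr, "channel") <- "SpH"
    out[[i]] <- tr
  }
  names(out) <- sprintf("b%03d", seq_len(n_c))
  out
}

#' Does an experiment contain enough active boutons?
#'
#' Experiments are accepted only when strictly more than
#' `params$min_boutons` active boutons were detected.
#'
#' @param mask a [detection_mask()] result.
#' @param params a [detection_params()] object.
#' @return Logical.
#' @export
accept_experiment <- function(mask, params = detection_params()) {
  mask$n_components > params$min_boutons
}

#' Write the component table of a mask as CSV
#' @param mask a [detection_mask()] result.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_component_csv <- function(mask, path) {
  utils::write.csv(mask$centroids, path, row.names = FALSE)
  invisible(path)
}
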