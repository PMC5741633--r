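#' Normalize a bouton fluorescence trace
#'
#' Standard normalization of a stimulated reporter trace:
#' \eqn{\Delta F(t) = (F(t) - \bar F_{baseline}) /
#'   (\bar F_{stim\,end} - \bar F_{baseline})},
#' so the baseline maps to 0 and the mean over the last frames of the
#' stimulation window (the fluorescence climax) maps to 1. With
#' `mode = "quench_first_point"` the trace is instead rescaled so that the
#' first frame of the post-stimulus acid-quench window is 1, the
#' normalization used when comparing re-acidification kinetics across
#' conditions with different surface fractions.
#'
#' @param trace data frame with columns `time_s` and `F`.
#' @param protocol a [make_protocol()] object describing the windows.
#' @param mode `"stim_end"` (default) or `"quench_first_point"`.
#' @param stim_end_frames number of frames at the end of the stimulation
#'   window averaged as the climax estimate.
#' @param channel `"SpH"` or `"CypHer"`; CypHer-type traces (quenched at
#'   neutral pH, negative-going response) are sign-inverted before
#'   normalization.
#' @return The trace with an added column `dF`.
#' @export
normalize_trace <- function(trace, protocol,
                            mode = c("stim_end", "quench_first_point"),
                            stim_end_frames = 3, channel = c("SpH", "CypHer")) {
  mode <- match.arg(mode)
  channel <- match.arg(channel)
  stopifnot(all(c("time_s", "F") %in% names(trace)))
  f <- trace$F
  if (channel == "CypHer") f <- -f
  bl <- .window_idx(protocol$baseline_window)
  sw <- .window_idx(protocol$stim_window)
  if (length(bl) == 0 || length(sw) == 0) {
    stop("empty baseline or stimulation window", call. = FALSE)
  }
  se <- sw[seq.int(max(1, length(sw) - stim_end_frames + 1), length(sw))]
  f0 <- mean(f[bl])
  fmax <- mean(f[se])
  if (abs(fmax - f0) < 1e-12 * max(abs(f), 1)) {
    stop("degenerate trace: zero dynamic range between baseline and ",
         "stimulation end", call. = FALSE)
  }
  dF <- (f - f0) / (fmax - f0)
  if (mode == "quench_first_point") {
    if (is.null(protocol$quench_window)) {
      stop("protocol has no quench window", call. = FALSE)
    }
    q1 <- protocol$quench_window[1] + 1L
    if (abs(dF[q1]) < 1e-12) {
      stop("degenerate trace: zero fluorescence at first quench frame",
           call. = FALSE)
    }
    dF <- dF / dF[q1]
  }
  trace$dF <- dF
  trace
}

#' Mono-exponential decay fit
#'
#' Least-squares fit of \eqn{y(t) = a + b\,e^{-t/\tau}} to a decaying
#' segment, the standard model for re-acidification time courses. The
#' plateau guess is the mean of the last 10% of the segment; the initial
#' time constant comes from a log-linear regression of the
#' plateau-subtracted signal, refined by Levenberg-Marquardt least
#' squares with \eqn{\tau > 0} enforced.
#'
#' Non-convergence (including non-decaying input) is reported through the
#' `converged` flag rather than an error.
#'
#' @param time_s time stamps (seconds), strictly increasing, length >= 5.
#' @param y signal values.
#' @return An object of class `exp_fit`: list with `tau` (s), `amplitude`
#'   (`b`), `plateau` (`a`), `rms` of residuals, and `converged`.
#' @export
fit_monoexponential <- function(time_s, y) {
  if (length(time_s) < 5 || length(y) != length(time_s)) {
    stop("need >= 5 points with matching time stamps", call. = FALSE)
  }
  t0 <- time_s - time_s[1]
  n <- length(y)
  fail <- structure(list(tau = NA_real_, amplitude = NA_real_,
                         plateau = NA_real_, rms = NA_real_,
                         converged = FALSE), class = "exp_fit")
  plateau0 <- mean(y[seq.int(max(1, floor(0.9 * n)), n)])
  amp0 <- y[1] - plateau0
  if (!(amp0 > 0)) return(fail)          # not a decay towards the tail
  z <- y - plateau0
  ok <- z > max(1e-12, 1e-6 * amp0) & t0 < max(t0)
  if (sum(ok) < 3) return(fail)
  lin <- stats::lm(log(z[ok]) ~ t0[ok])
  slope <- unname(stats::coef(lin)[2])
  tau0 <- if (is.finite(slope) && slope < 0) -1 / slope else max(t0) / 3
  residual <- function(p) y - (p[1] + p[2] * exp(-t0 / p[3]))
  jacobian <- function(p) {
    e <- exp(-t0 / p[3])
    -cbind(1, e, p[2] * e * t0 / p[3]^2)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(a = plateau0, b = amp0, tau = tau0),
                       fn = residual, jac = jacobian,
                       lower = c(-Inf, -Inf, 1e-6),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || !(fit$info %in% 1:4)) return(fail)
  cf <- fit$par
  if (!is.finite(cf[["tau"]]) || cf[["tau"]] <= 0 || cf[["b"]] <= 0) {
    return(fail)
  }
  # a time constant far beyond the observed span is not identifiable
  # (the segment is effectively flat, not a decay)
  if (cf[["tau"]] > 3 * max(t0)) return(fail)
  structure(list(tau = unname(cf[["tau"]]),
                 amplitude = unname(cf[["b"]]),
                 plateau = unname(cf[["a"]]),
                 rms = sqrt(mean(fit$fvec^2)),
                 converged = TRUE), class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("mono-exponential fit: tau = %.4g s, plateau = %.4g, ",
                x$tau, x$plateau),
        sprintf("amplitude = %.4g (rms %.3g)\n", x$amplitude, x$rms))
  } else {
    cat("mono-exponential fit: not converged\n")
  }
  invisible(x)
}

#' Steady-state luminal pH from the post-stimulus plateau of a trace
#'
#' Normalizes the trace, fits the post-stimulus decay with
#' [fit_monoexponential()] and converts the fitted plateau fluorescence to
#' luminal pH through [pH_from_deltaF()]. A plateau of 0 means full
#' re-acidification to the resting pH; a plateau near 1 means no
#' re-acidification.
#'
#' @param trace data frame with `time_s`, `F`.
#' @param protocol the [make_protocol()] object.
#' @param pp [photophysics_params()].
#' @param ... passed to [normalize_trace()].
#' @return List with `ph` (plateau pH), `fit` (the `exp_fit`) and
#'   `plateau_dF`.
#' @export
plateau_pH <- function(trace, protocol, pp = photophysics_params(), ...) {
  nt <- normalize_trace(trace, protocol, ...)
  post <- seq.int(protocol$stim_window[2] + 1L, protocol$n_frames)
  if (length(post) < 5) {
    stop("fewer than 5 post-stimulus frames", call. = FALSE)
  }
  ft <- fit_monoexponential(nt$time_s[post], nt$dF[post])
  if (!ft$converged) {
    return(list(ph = NA_real_, fit = ft, plateau_dF = NA_real_))
  }
  lo <- deltaF_from_pH(3, pp)
  hi <- deltaF_from_pH(10, pp)
  plat <- min(max(ft$plateau, lo), hi)
  list(ph = pH_from_deltaF(plat, pp), fit = ft, plateau_dF = ft$plateau)
}

#' Classify boutons as transport-inhibited or not
#'
#' Compares, per bouton, a probe-condition trace with the paired trace
#' recorded after applying the transport inhibitor at the end of the
#' experiment. The recovery fraction of a trace is
#' `1 - plateau(dF)` of its post-stimulus fit; a bouton is labelled
#' `inhibited` when it recovers under control conditions but fails to
#' recover (recovery below `recovery_threshold`) under the inhibitor.
#'
#' @param traces_probe named list of control traces (data frames with
#'   `time_s`, `F`), names are bouton ids.
#' @param traces_post named list of inhibitor traces with the same ids.
#' @param protocol the shared [make_protocol()] object.
#' @param recovery_threshold recovery fraction below which a trace counts
#'   as non-recovering.
#' @param pp [photophysics_params()].
#' @return Data frame with `bouton_id`, `recovery_probe`, `recovery_post`,
#'   `class` (`"inhibited"` / `"uninhibited"`).
#' @export
classify_boutons <- function(traces_probe, traces_post, protocol,
                             recovery_threshold = 0.5,
                             pp = photophysics_params()) {
  ids <- names(traces_probe)
  if (is.null(ids) || !setequal(ids, names(traces_post))) {
    stop("probe and post traces must carry matching bouton ids",
         call. = FALSE)
  }
  rec <- function(trace) {
    pf <- plateau_pH(trace, protocol, pp)
    if (!pf$fit$converged) {
      # no decaying component at all: nothing recovered
      nt <- normalize_trace(trace, protocol)
      post <- seq.int(protocol$stim_window[2] + 1L, protocol$n_frames)
      return(1 - mean(nt$dF[utils::tail(post, max(3, length(post) %/% 10))]))
    }
    1 - pf$plateau_dF
  }
  r_probe <- vapply(traces_probe[ids], rec, numeric(1))
  r_post <- vapply(traces_post[ids], rec, numeric(1))
  cls <- ifelse(r_probe >= recovery_threshold &
                  r_post < recovery_threshold, "inhibited", "uninhibited")
  data.frame(bouton_id = ids, recovery_probe = unname(r_probe),
             recovery_post = unname(r_post), class = unname(cls),
             row.names = NULL)
}
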