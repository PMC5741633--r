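#' Composition of the extracellular (and hence engulfed) solution
#'
#' Chloride plus an optional large-anion substitute, the exogenous proton
#' buffers, and the external pH. By convention the total substitutable
#' anion concentration is 129.5 mM, so chloride removed from the bath is
#' replaced mole-for-mole by the substitute.
#'
#' @param chloride_mM chloride concentration, mM.
#' @param substitute_anion one of `"none"`, `"gluconate"`,
#'   `"methanesulfonate"`, `"iodide"`.
#' @param substitute_mM concentration of the substitute anion, mM.
#' @param hepes_mM,histidine_mM,tris_mM exogenous buffer concentrations, mM.
#' @param ph_external bath pH.
#' @return An object of class `solution_spec`.
#' @export
solution_spec <- function(chloride_mM = 129.5,
                          substitute_anion = c("none", "gluconate",
                                               "methanesulfonate", "iodide"),
                          substitute_mM = 0,
                          hepes_mM = 25, histidine_mM = 0, tris_mM = 0,
                          ph_external = 7.3) {
  substitute_anion <- match.arg(substitute_anion)
  conc <- c(chloride_mM, substitute_mM, hepes_mM, histidine_mM, tris_mM)
  if (any(conc < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (substitute_anion == "none" && substitute_mM > 0) {
    stop("substitute_mM > 0 requires a named substitute anion",
         call. = FALSE)
  }
  structure(list(chloride_mM = chloride_mM,
                 substitute_anion = substitute_anion,
                 substitute_mM = substitute_mM,
                 hepes_mM = hepes_mM, histidine_mM = histidine_mM,
                 tris_mM = tris_mM, ph_external = ph_external),
            class = "solution_spec")
}

# pKa of the substitutable anions: gluconate is a weak proton buffer,
# methanesulfonate effectively none, iodide none
.substitute_pka <- c(gluconate = 3.7, methanesulfonate = -1.2,
                     iodide = -Inf)

#' Stimulation / acquisition protocol
#'
#' Describes one imaging experiment: acquisition frame rate, a baseline
#' window, a stimulation train of `n_aps` action potentials at `ap_rate`,
#' and optionally a rapid acid-quench window opening immediately after the
#' end of stimulation. Frame indices are 0-based half-open ranges.
#'
#' @param frame_rate acquisition rate, Hz (> 0).
#' @param n_aps number of action potentials in the train (> 0).
#' @param ap_rate stimulation frequency, Hz (> 0).
#' @param quench logical; apply the impermeant acid surface quench right
#'   after stimulation ends.
#' @param baseline_s seconds of baseline before stimulation onset.
#' @param post_s seconds recorded after the end of stimulation.
#' @param solution a [solution_spec()].
#' @return An object of class `stim_protocol` with fields `frame_rate`,
#'   `n_frames`, `baseline_window`, `stim_start_s`, `stim_duration_s`,
#'   `stim_window`, `quench_window` (or `NULL`) and `solution`.
#' @examples
#' p <- make_protocol(5, 200, 20)        # 200 APs at 20 Hz -> 10 s train
#' p$stim_duration_s
#' @export
make_protocol <- function(frame_rate = 5, n_aps = 200, ap_rate = 20,
                          quench = FALSE, baseline_s = 10, post_s = 60,
                          solution = solution_spec()) {
  if (frame_rate <= 0 || ap_rate <= 0 || n_aps <= 0) {
    stop("frame_rate, ap_rate and n_aps must all be positive",
         call. = FALSE)
  }
  stim_duration_s <- n_aps / ap_rate
  n_frames <- ceiling((baseline_s + stim_duration_s + post_s) * frame_rate)
  stim_start <- floor(baseline_s * frame_rate)
  stim_end <- ceiling((baseline_s + stim_duration_s) * frame_rate)
  proto <- structure(list(
    frame_rate = frame_rate,
    n_frames = n_frames,
    baseline_window = c(0L, as.integer(stim_start)),
    stim_start_s = baseline_s,
    stim_duration_s = stim_duration_s,
    stim_window = c(as.integer(stim_start), as.integer(stim_end)),
    quench_window = if (quench) c(as.integer(stim_end),
                                  as.integer(n_frames)) else NULL,
    solution = solution), class = "stim_protocol")
  proto
}

#' Frame acquisition times of a protocol
#' @param protocol a [stim_protocol()][make_protocol] object.
#' @return Numeric vector of frame times in seconds (frame 0 at t = 0).
#' @export
protocol_times <- function(protocol) {
  (seq_len(protocol$n_frames) - 1) / protocol$frame_rate
}

# frame indices (1-based R) of a 0-based half-open window
.window_idx <- function(w) seq.int(w[1] + 1L, w[2])
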