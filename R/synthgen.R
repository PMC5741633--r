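#' Simulate ground-truth bouton fluorescence traces
#'
#' Generates a population of per-bouton reporter traces for a stimulation
#' protocol, with known kinetic parameters recorded in a ground-truth
#' object. Each trace is
#' `F(t) = baseline + amplitude * r(t) (+ noise)`, where the pool curve
#' `r(t)` rises piecewise-linearly from 0 to 1 during the stimulation
#' train (net exocytosis) and then relaxes exponentially towards the
#' bouton's plateau with its re-acidification time constant:
#' `r(t) = plateau + (1 - plateau) * exp(-(t - t_end)/tau)`.
#'
#' Bouton classes: `glutamatergic` (full recovery, plateau ~0),
#' `inhibited` (transport blocked: no recovery, plateau near 1) and
#' `GABAergic` (full recovery; rendered on the CypHer-like channel with
#' inverted sign). When the protocol has an acid-quench window, surface
#' reporter is masked during the quench: the trace drops to the still
#' fluorescent (not yet re-acidified) endocytosed fraction
#' `(1 - plateau) * exp(-(t - t_q)/tau) + plateau * 0`, read on top of a
#' quenched-surface baseline.
#'
#' @param protocol a [make_protocol()] object.
#' @param n_boutons number of boutons (>= 1).
#' @param kinetics named list of per-class parameters; see defaults.
#' @param frac_inhibited fraction of boutons drawn as `inhibited`.
#' @param frac_gabaergic fraction drawn as `GABAergic`.
#' @param noise_sd Gaussian noise s.d., relative to the response
#'   amplitude (0.02 = 2% of peak).
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return List with `traces` (named list of data frames `time_s`, `F`,
#'   plus attributes), `truth` (a `ground_truth` object: data frame of
#'   per-bouton `bouton_id`, `class`, `tau_true`, `amplitude`,
#'   `baseline`, `plateau`, `channel`, plus `seed` and the protocol).
#' @export
simulate_truth_traces <- function(protocol, n_boutons = 100,
                                  kinetics = list(
                                    tau_glut = 4.9, tau_gaba = 4.9,
                                    plateau_glut = 0, plateau_inhib = 0.985,
                                    amplitude_mean = 200, amplitude_sd = 40,
                                    baseline = 1000),
                                  frac_inhibited = 0, frac_gabaergic = 0,
                                  noise_sd = 0.02, seed = 1) {
  stopifnot(n_boutons >= 1)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  set.seed(seed)
  n_inh <- round(frac_inhibited * n_boutons)
  n_gaba <- round(frac_gabaergic * n_boutons)
  classes <- sample(c(rep("inhibited", n_inh), rep("GABAergic", n_gaba),
                      rep("glutamatergic", n_boutons - n_inh - n_gaba)))
  amp <- pmax(stats::rnorm(n_boutons, kinetics$amplitude_mean,
                           kinetics$amplitude_sd),
              0.2 * kinetics$amplitude_mean)
  tau <- ifelse(classes == "GABAergic", kinetics$tau_gaba,
                kinetics$tau_glut)
  plateau <- ifelse(classes == "inhibited", kinetics$plateau_inhib,
                    kinetics$plateau_glut)
  tt <- protocol_times(protocol)
  t_on <- protocol$stim_start_s
  t_off <- t_on + protocol$stim_duration_s

  traces <- vector("list", n_boutons)
  for (i in seq_len(n_boutons)) {
    r <- numeric(length(tt))
    rise <- tt > t_on & tt <= t_off
    r[rise] <- (tt[rise] - t_on) / (t_off - t_on)
    post <- tt > t_off
    r[post] <- plateau[i] + (1 - plateau[i]) * exp(-(tt[post] - t_off) /
                                                     tau[i])
    f <- kinetics$baseline + amp[i] * r
    if (!is.null(protocol$quench_window)) {
      qi <- .window_idx(protocol$quench_window)
      # impermeant acid masks surface reporter (a small fraction of the
      # resting fluorescence); the not-yet re-acidified endocytosed
      # fraction remains fluorescent and decays with the
      # re-acidification time constant
      qf <- kinetics$quench_floor %||% 0.95
      surv <- plateau[i] + (1 - plateau[i]) * exp(-(tt[qi] - t_off) / tau[i])
      f[qi] <- kinetics$baseline * qf + amp[i] * surv
    }
    if (classes[i] == "GABAergic") {
      f <- 2 * kinetics$baseline - f   # CypHer-like: negative-going
    }
    if (noise_sd > 0) {
      f <- f + stats::rnorm(length(f), 0, noise_sd * amp[i])
    }
    tr <- data.frame(time_s = tt, F = f)
    attr(tr, "channel") <- if (classes[i] == "GABAergic") "CypHer" else "SpH"
    traces[[i]] <- tr
  }
  ids <- sprintf("b%03d", seq_len(n_boutons))
  names(traces) <- ids
  truth <- structure(list(
    seed = seed,
    protocol = protocol,
    boutons = data.frame(
      bouton_id = ids, class = classes, tau_true = tau,
      amplitude = amp, baseline = kinetics$baseline, plateau = plateau,
      channel = ifelse(classes == "GABAergic", "CypHer", "SpH"),
      row.names = NULL)),
    class = "ground_truth")
  list(traces = traces, truth = truth)
}

#' Serialise / restore a ground-truth record
#'
#' Ground truth is persisted as JSON so every synthetic artifact can be
#' traced back to its generating parameters. The round trip is lossless
#' for the recorded fields.
#'
#' @param truth a `ground_truth` object.
#' @param path file path to write to.
#' @return `write_ground_truth` returns `path` invisibly;
#'   `read_ground_truth` returns the restored `ground_truth`.
#' @export
write_ground_truth <- function(truth, path) {
  payload <- list(seed = truth$seed,
                  protocol = truth$protocol[setdiff(names(truth$protocol),
                                                    "solution")],
                  solution = unclass(truth$protocol$solution),
                  boutons = truth$boutons)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sol <- do.call(solution_spec, x$solution)
  proto <- x$protocol
  proto$baseline_window <- as.integer(proto$baseline_window)
  proto$stim_window <- as.integer(proto$stim_window)
  if (!is.null(proto$quench_window)) {
    proto$quench_window <- as.integer(proto$quench_window)
  }
  proto$solution <- sol
  class(proto) <- "stim_protocol"
  structure(list(seed = x$seed, protocol = proto, boutons = x$boutons),
            class = "ground_truth")
}

#' Write / read a bouton trace table as CSV
#'
#' Long-format exchange table with columns `time_s`, `bouton_id`,
#' `channel`, `F`.
#'
#' @param traces named list of trace data frames.
#' @param path CSV path.
#' @return `write_trace_csv` returns `path` invisibly; `read_trace_csv`
#'   returns a named list of trace data frames.
#' @export
write_trace_csv <- function(traces, path) {
  rows <- lapply(names(traces), function(id) {
    tr <- traces[[id]]
    data.frame(time_s = tr$time_s, bouton_id = id,
               channel = attr(tr, "channel") %||% "SpH", F = tr$F)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(x, x$bouton_id), function(d) {
    tr <- data.frame(time_s = d$time_s, F = d$F)
    attr(tr, "channel") <- d$channel[1]
    tr
  })
  out[order(names(out))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Synthetic calibration dataset for the chloride/pH sensor
#'
#' Generates `(pH, [Cl-], R_pH, R_Cl)` calibration rows through the
#' forward sensor model [ratios_from_state()] with optional multiplicative
#' log-normal measurement noise, mimicking an ionophore-clamp calibration
#' series.
#'
#' @param cal_truth the generating [cloph_calibration()].
#' @param ph_grid pH levels.
#' @param cl_grid chloride levels, mM (include 0 for the pH arm).
#' @param noise_sd s.d. of the multiplicative noise (0 = exact).
#' @param seed integer seed.
#' @return Data frame `ph`, `cl_mM`, `R_pH`, `R_Cl` with the generating
#'   calibration attached as attribute `truth`.
#' @export
make_cl_calibration_dataset <- function(cal_truth = cloph_calibration(),
                                        ph_grid = seq(4.5, 9, by = 0.5),
                                        cl_grid = c(0, 5, 10, 20, 40, 80,
                                                    131),
                                        noise_sd = 0, seed = 1) {
  if (length(ph_grid) == 0 || length(cl_grid) == 0) {
    stop("calibration grids must be non-empty", call. = FALSE)
  }
  if (any(cl_grid < 0)) stop("chloride must be >= 0", call. = FALSE)
  set.seed(seed)
  g <- expand.grid(ph = ph_grid, cl_mM = cl_grid)
  r <- ratios_from_state(g$ph, g$cl_mM, cal_truth)
  if (noise_sd > 0) {
    r$R_pH <- r$R_pH * exp(stats::rnorm(nrow(g), 0, noise_sd))
    r$R_Cl <- r$R_Cl * exp(stats::rnorm(nrow(g), 0, noise_sd))
  }
  out <- data.frame(ph = g$ph, cl_mM = g$cl_mM,
                    R_pH = r$R_pH, R_Cl = r$R_Cl)
  attr(out, "truth") <- cal_truth
  out
}
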