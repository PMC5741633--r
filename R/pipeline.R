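#' Validate a raw run configuration
#'
#' Checks a plain list (e.g. parsed from YAML/JSON) against the run
#' schema, injects defaults (wavelet depth 4, detection level 1.0,
#' minimum 50 boutons, reporter pKa 7.09 / Hill 1.35) and rejects unknown
#' keys. Exactly one input source must be given: a stack path, a traces
#' path, or a synthetic specification.
#'
#' @param raw named list of configuration values.
#' @return A validated `run_config` object.
#' @export
validate_config <- function(raw = list()) {
  known <- c("stack_path", "traces_path", "synthetic", "detection",
             "photophysics", "calibration", "scenarios", "output_dir",
             "seed")
  errs <- character(0)
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    errs <- c(errs, paste("unknown keys:", paste(unknown, collapse = ", ")))
  }
  sources <- c(!is.null(raw$stack_path), !is.null(raw$traces_path),
               !is.null(raw$synthetic))
  if (sum(sources) != 1) {
    errs <- c(errs, paste("exactly one input source required",
                          "(stack_path | traces_path | synthetic)"))
  }
  for (p in c("stack_path", "traces_path")) {
    if (!is.null(raw[[p]]) && !file.exists(raw[[p]])) {
      errs <- c(errs, paste0(p, " does not exist: ", raw[[p]]))
    }
  }
  det <- tryCatch(do.call(detection_params, raw$detection %||% list()),
                  error = function(e) {
                    errs <<- c(errs, paste("detection:",
                                           conditionMessage(e)))
                    NULL
                  })
  pp <- tryCatch(do.call(photophysics_params, raw$photophysics %||% list()),
                 error = function(e) {
                   errs <<- c(errs, paste("photophysics:",
                                          conditionMessage(e)))
                   NULL
                 })
  if (length(errs) > 0) {
    stop("config error:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  }
  structure(list(stack_path = raw$stack_path,
                 traces_path = raw$traces_path,
                 synthetic = raw$synthetic,
                 detection = det, photophysics = pp,
                 calibration = raw$calibration,
                 scenarios = raw$scenarios %||% character(0),
                 output_dir = raw$output_dir,
                 seed = raw$seed %||% 1L),
            class = "run_config")
}

#' Run the end-to-end analysis pipeline
#'
#' Generates or ingests the input, detects boutons where a stack is
#' involved, extracts and normalizes traces, fits the post-stimulus
#' re-acidification kinetics, converts plateaus to luminal pH, and
#' reports per-bouton and population summaries. For synthetic inputs the
#' report includes a truth-versus-estimate table. An imaging experiment
#' whose detected bouton count does not exceed the configured minimum is
#' rejected.
#'
#' @param config a validated `run_config` from [validate_config()].
#' @param protocol the [make_protocol()] of the experiment (required for
#'   stack or trace inputs; a synthetic spec may carry its own).
#' @return A `run_report`: list with `per_bouton` (data frame with
#'   `bouton_id`, `tau_s`, `plateau_dF`, `plateau_ph`), `summary`
#'   (population mean and s.e.m. of tau and plateau pH), `accepted`,
#'   `n_boutons`, and optionally `truth_vs_estimate`.
#' @export
run_pipeline <- function(config, protocol = make_protocol()) {
  truth <- NULL
  if (!is.null(config$synthetic)) {
    spec <- config$synthetic
    proto <- spec$protocol %||% protocol
    sim <- do.call(simulate_truth_traces,
                   c(list(protocol = proto),
                     spec[setdiff(names(spec), "protocol")],
                     if (is.null(spec$seed)) list(seed = config$seed)))
    traces <- sim$traces
    truth <- sim$truth
    protocol <- proto
    n_boutons <- length(traces)
  } else if (!is.null(config$traces_path)) {
    traces <- read_trace_csv(config$traces_path)
    n_boutons <- length(traces)
  } else {
    stack <- read_stack_tiff(config$stack_path)
    di <- difference_image(stack, protocol)
    mask <- detection_mask(atrous_transform(di, config$detection$k),
                           config$detection)
    n_boutons <- mask$n_components
    if (!accept_experiment(mask, config$detection)) {
      return(structure(list(accepted = FALSE, n_boutons = n_boutons,
                            per_bouton = NULL, summary = NULL),
                       class = "run_report"))
    }
    traces <- extract_traces(stack, mask, protocol = protocol)
  }

  post <- seq.int(protocol$stim_window[2] + 1L, protocol$n_frames)
  rows <- lapply(names(traces), function(id) {
    tr <- traces[[id]]
    ch <- attr(tr, "channel") %||% "SpH"
    res <- tryCatch(
      plateau_pH(tr, protocol, config$photophysics, channel = ch),
      error = function(e) NULL)
    if (is.null(res) || !res$fit$converged) {
      return(data.frame(bouton_id = id, tau_s = NA_real_,
                        plateau_dF = NA_real_, plateau_ph = NA_real_))
    }
    data.frame(bouton_id = id, tau_s = res$fit$tau,
               plateau_dF = res$plateau_dF, plateau_ph = res$ph)
  })
  per_bouton <- do.call(rbind, rows)
  ok <- is.finite(per_bouton$tau_s)
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  summary <- data.frame(
    n_boutons = n_boutons, n_fit = sum(ok),
    tau_mean = mean(per_bouton$tau_s[ok]),
    tau_sem = sem(per_bouton$tau_s[ok]),
    ph_mean = mean(per_bouton$plateau_ph[ok], na.rm = TRUE),
    ph_sem = sem(per_bouton$plateau_ph[ok][
      is.finite(per_bouton$plateau_ph[ok])]))

  report <- list(accepted = TRUE, n_boutons = n_boutons,
                 per_bouton = per_bouton, summary = summary,
                 seed = config$seed)
  if (!is.null(truth)) {
    tv <- merge(per_bouton, truth$boutons[, c("bouton_id", "class",
                                              "tau_true", "plateau")],
                by = "bouton_id")
    report$truth_vs_estimate <- tv
    report$truth <- truth
  }
  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  if (!x$accepted) {
    cat(sprintf("run rejected: %d active boutons (minimum not exceeded)\n",
                x$n_boutons))
    return(invisible(x))
  }
  cat(sprintf("run accepted: %d boutons, %d fitted\n",
              x$summary$n_boutons, x$summary$n_fit))
  cat(sprintf("  tau  = %.3g +/- %.2g s (mean +/- s.e.m.)\n",
              x$summary$tau_mean, x$summary$tau_sem))
  cat(sprintf("  plateau pH = %.3g +/- %.2g\n",
              x$summary$ph_mean, x$summary$ph_sem))
  invisible(x)
}
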