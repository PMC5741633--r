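#' Calibration constants of the dual ratiometric chloride/pH sensor
#'
#' Holds every constant of the excitation-ratiometric chloride/pH sensor
#' (an E2GFP/TdTomato fusion of the ClopHensor family targeted to the
#' vesicle lumen). The pH arm reads the emission ratio
#' \eqn{R_{pH} = F_{488}/F_{458}}; the chloride arm reads
#' \eqn{R_{Cl} = F_{458}/F_{565}}.
#'
#' The default numerical values of `R_A`, `R_B`, `R_free`, `R_bound_pH0`
#' and `Kd1` are synthetic: they are plausible ratio limits chosen for
#' simulation, not published constants. `Kd1` is chosen so that the
#' chloride dissociation constant at the resting luminal pH of 5.6 is
#' about 9.8 mM, which places 90% sensor saturation near 88 mM chloride.
#' `pKa` (7.49) and the `R_bound` slope `M` (0.061 per pH unit) are the
#' empirically determined sensor constants.
#'
#' @param pKa acid dissociation constant of the sensor chromophore.
#' @param R_A value of `R_pH` for the fully acidic sensor.
#' @param R_B value of `R_pH` for the fully basic sensor.
#' @param R_free `R_Cl` with no chloride bound.
#' @param R_bound_pH0 intercept of the linear pH dependence of `R_bound`,
#'   the `R_Cl` value at chloride saturation.
#' @param M slope of `R_bound` versus pH (per pH unit).
#' @param Kd1 chloride dissociation constant of the fully protonated
#'   sensor, mM.
#' @return An object of class `cloph_calibration`.
#' @export
cloph_calibration <- function(pKa = 7.49, R_A = 0.4, R_B = 2.4,
                              R_free = 0.8, R_bound_pH0 = 1.9,
                              M = 0.061, Kd1 = 9.7) {
  if (!(R_A < R_B)) stop("R_A must be below R_B", call. = FALSE)
  if (Kd1 <= 0) stop("Kd1 must be positive", call. = FALSE)
  structure(list(pKa = pKa, R_A = R_A, R_B = R_B, R_free = R_free,
                 R_bound_pH0 = R_bound_pH0, M = M, Kd1 = Kd1),
            class = "cloph_calibration")
}

# R_Cl at chloride saturation; increases linearly with pH
r_bound_at_ph <- function(pH, cal) cal$M * pH + cal$R_bound_pH0

#' pH from the pH-arm emission ratio
#'
#' \deqn{pH = pK_a + \log_{10}\frac{R_{pH} - R_A}{R_B - R_{pH}}}
#'
#' @param R_pH emission ratio of the pH arm; must lie strictly between
#'   `R_A` and `R_B`.
#' @param cal a [cloph_calibration()] object.
#' @return pH, vectorised over `R_pH`.
#' @export
ph_from_rph <- function(R_pH, cal = cloph_calibration()) {
  if (any(R_pH <= cal$R_A | R_pH >= cal$R_B)) {
    stop(sprintf("R_pH outside the open interval (R_A, R_B) = (%g, %g)",
                 cal$R_A, cal$R_B), call. = FALSE)
  }
  cal$pKa + log10((R_pH - cal$R_A) / (cal$R_B - R_pH))
}

#' pH-dependent chloride dissociation constant of the sensor
#'
#' Chloride binds the protonated sensor only, so the apparent dissociation
#' constant rises with pH:
#' \deqn{K_d^{Cl}(pH) = {}^1K_d^{Cl}\,
#'   \frac{1 + 10^{pK_a - pH}}{10^{pK_a - pH}}.}
#' At `pH = pKa` this equals `2 * Kd1`; it tends to `Kd1` in the fully
#' protonated (acidic) limit.
#'
#' @param pH pH at which to evaluate the constant.
#' @param cal a [cloph_calibration()] object.
#' @return Dissociation constant in mM, vectorised over `pH`.
#' @export
kd_at_ph <- function(pH, cal = cloph_calibration()) {
  r <- 10^(cal$pKa - pH)
  cal$Kd1 * (1 + r) / r
}

#' Chloride concentration from the chloride-arm emission ratio
#'
#' \deqn{[Cl^-] = K_d^{Cl}(pH)\,\frac{R_{Cl} - R_{free}}
#'   {R_{bound}(pH) - R_{Cl}}}
#' with \eqn{R_{bound}(pH) = M\,pH + R_{bound,pH0}}.
#'
#' @param R_Cl emission ratio of the chloride arm.
#' @param pH luminal pH at which the measurement was taken (sets both
#'   `K_d` and `R_bound`).
#' @param cal a [cloph_calibration()] object.
#' @return Chloride concentration in mM.
#' @export
cl_from_rcl <- function(R_Cl, pH, cal = cloph_calibration()) {
  rb <- r_bound_at_ph(pH, cal)
  if (any(R_Cl < cal$R_free)) {
    stop("R_Cl below R_free: not attainable by the binding model",
         call. = FALSE)
  }
  if (any(R_Cl >= rb)) {
    stop(sprintf(paste0(
      "R_Cl at or beyond sensor saturation (R_bound = %.3f); ",
      "concentrations above the 90%%-saturation bound of %.1f mM ",
      "cannot be quantified"),
      min(rb), 9 * min(kd_at_ph(pH, cal))), call. = FALSE)
  }
  kd_at_ph(pH, cal) * (R_Cl - cal$R_free) / (rb - R_Cl)
}

#' Forward model: emission ratios expected for a luminal state
#'
#' Exact algebraic inverse of [ph_from_rph()] and [cl_from_rcl()]; used to
#' generate synthetic calibration data and in round-trip tests.
#'
#' @param pH luminal pH.
#' @param cl_mM chloride concentration, mM (non-negative).
#' @param cal a [cloph_calibration()] object.
#' @return A list with components `R_pH` and `R_Cl` (vectorised).
#' @export
ratios_from_state <- function(pH, cl_mM, cal = cloph_calibration()) {
  stopifnot(all(cl_mM >= 0))
  a <- 10^(pH - cal$pKa)
  R_pH <- (cal$R_A + cal$R_B * a) / (1 + a)
  rb <- r_bound_at_ph(pH, cal)
  kd <- kd_at_ph(pH, cal)
  # binding isotherm: occupied fraction = cl/(kd + cl)
  R_Cl <- cal$R_free + (rb - cal$R_free) * cl_mM / (kd + cl_mM)
  list(R_pH = R_pH, R_Cl = R_Cl)
}

#' Fit sensor calibration constants from a calibration dataset
#'
#' Two-stage nonlinear least squares, mirroring how the two arms of the
#' sensor are calibrated experimentally. Stage 1 fits the pH sigmoid
#' (`pKa`, `R_A`, `R_B`) to `R_pH` against pH using the chloride-free rows.
#' Stage 2, with `pKa` fixed from stage 1, fits the chloride isotherm
#' (`R_free`, `R_bound_pH0`, `M`, `Kd1`) to `R_Cl` across all pH groups.
#'
#' @param dataset data frame with columns `ph`, `cl_mM`, `R_pH`, `R_Cl`,
#'   e.g. from [make_cl_calibration_dataset()].
#' @return A list with `cal` (the fitted [cloph_calibration()]), `ci`
#'   (95% confidence intervals, one row per parameter) and the two `nls`
#'   fits (`fit_ph`, `fit_cl`).
#' @export
fit_calibration <- function(dataset) {
  need <- c("ph", "cl_mM", "R_pH", "R_Cl")
  if (!all(need %in% names(dataset))) {
    stop("dataset must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  ph_rows <- dataset[dataset$cl_mM == 0, , drop = FALSE]
  if (length(unique(ph_rows$ph)) < 2) {
    stop("calibration-identifiability error: need >= 2 chloride-free pH levels",
         call. = FALSE)
  }
  cl_rows <- dataset[dataset$cl_mM > 0, , drop = FALSE]
  if (length(unique(cl_rows$cl_mM)) < 2 || length(unique(cl_rows$ph)) < 2) {
    stop(paste("calibration-identifiability error: need >= 2 chloride levels",
               "at >= 2 pH values"), call. = FALSE)
  }

  fit_ph <- minpack.lm::nlsLM(
    R_pH ~ (R_A + R_B * 10^(ph - pKa)) / (1 + 10^(ph - pKa)),
    data = ph_rows,
    start = list(pKa = stats::median(ph_rows$ph),
                 R_A = min(ph_rows$R_pH), R_B = max(ph_rows$R_pH)),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf1 <- stats::coef(fit_ph)

  pKa_hat <- unname(cf1["pKa"])
  fit_cl <- minpack.lm::nlsLM(
    R_Cl ~ R_free + (M * ph + R_bound_pH0 - R_free) * cl_mM /
      (Kd1 * (1 + 10^(pKa_hat - ph)) / 10^(pKa_hat - ph) + cl_mM),
    data = dataset,
    start = list(R_free = min(dataset$R_Cl),
                 R_bound_pH0 = max(dataset$R_Cl), M = 0.05,
                 Kd1 = stats::median(dataset$cl_mM[dataset$cl_mM > 0])),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf2 <- stats::coef(fit_cl)

  cal <- cloph_calibration(pKa = cf1[["pKa"]], R_A = cf1[["R_A"]],
                           R_B = cf1[["R_B"]], R_free = cf2[["R_free"]],
                           R_bound_pH0 = cf2[["R_bound_pH0"]],
                           M = cf2[["M"]], Kd1 = cf2[["Kd1"]])
  ci <- rbind(.nls_ci(fit_ph), .nls_ci(fit_cl))
  list(cal = cal, ci = ci, fit_ph = fit_ph, fit_cl = fit_cl)
}

# Wald 95% intervals from the fit covariance
.nls_ci <- function(fit) {
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  data.frame(parameter = names(cf), estimate = unname(cf),
             lower = unname(cf - 1.96 * se), upper = unname(cf + 1.96 * se),
             row.names = NULL)
}
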