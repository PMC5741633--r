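#' Photophysical parameters of the pH reporter
#'
#' Bundles the Hill-type pH titration of a pHluorin-class reporter together
#' with the two reference pH values that anchor the normalized fluorescence
#' scale: the resting luminal pH (where the normalized signal is 0) and the
#' cell-surface pH (where it is 1).
#'
#' @param pKa pH of half-maximal protonation of the fluorophore.
#' @param nH Hill coefficient of the titration.
#' @param ph_rest luminal pH of resting vesicles; normalized fluorescence is
#'   zero here by construction.
#' @param ph_surface extracellular pH seen by surface-stranded reporter;
#'   normalized fluorescence approaches one here.
#' @return An object of class `photophysics_params`.
#' @examples
#' pp <- photophysics_params()
#' deltaF_from_pH(7.3, pp)
#' @export
photophysics_params <- function(pKa = 7.09, nH = 1.35,
                                ph_rest = 5.6, ph_surface = 7.3) {
  stopifnot(is.numeric(pKa), is.numeric(nH), nH > 0)
  if (!(ph_rest < ph_surface)) {
    stop("ph_rest must be below ph_surface", call. = FALSE)
  }
  structure(list(pKa = pKa, nH = nH,
                 ph_rest = ph_rest, ph_surface = ph_surface),
            class = "photophysics_params")
}

# protonation-state occupancy of the deprotonated (fluorescent) form
.hill_frac <- function(pH, pKa, nH) 1 / (1 + 10^(nH * (pKa - pH)))

#' Normalized fluorescence change expected at a given luminal pH
#'
#' Maps luminal pH to the normalized fluorescence change
#' \eqn{\Delta F = (F - F_0)/F_{max}} of the reporter, where \eqn{F_0} is the
#' fluorescence at the resting pH and \eqn{F_{max}} the fluorescence of
#' surface reporter at extracellular pH:
#' \deqn{\Delta F = \left(\frac{1}{1+10^{n_H(pK_a-pH)}} -
#'   \frac{1}{1+10^{n_H(pK_a-pH_{rest})}}\right)
#'   \left(1+10^{n_H(pK_a-pH_{surf})}\right).}
#' By construction the map gives 0 at `ph_rest` and close to 1 at
#' `ph_surface`.
#'
#' @param pH luminal pH, in \[3, 10\].
#' @param pp a [photophysics_params()] object.
#' @return Normalized fluorescence change (dimensionless), vectorised over
#'   `pH`.
#' @export
deltaF_from_pH <- function(pH, pp = photophysics_params()) {
  stopifnot(is.numeric(pH))
  if (any(pH < 3 | pH > 10)) {
    stop("pH outside the supported range [3, 10]", call. = FALSE)
  }
  (.hill_frac(pH, pp$pKa, pp$nH) - .hill_frac(pp$ph_rest, pp$pKa, pp$nH)) *
    (1 + 10^(pp$nH * (pp$pKa - pp$ph_surface)))
}

#' Luminal pH implied by a normalized fluorescence change
#'
#' Exact algebraic inverse of [deltaF_from_pH()]:
#' \deqn{pH = pK_a - \frac{1}{n_H}\log_{10}\!\left[
#'   \frac{1}{\frac{1}{1+10^{n_H(pK_a-pH_{rest})}} +
#'   \frac{\Delta F}{1+10^{n_H(pK_a-pH_{surf})}}} - 1\right].}
#'
#' @param deltaF normalized fluorescence change; must lie in the range the
#'   forward map attains on pH in \[3, 10\].
#' @param pp a [photophysics_params()] object.
#' @return Luminal pH, vectorised over `deltaF`.
#' @export
pH_from_deltaF <- function(deltaF, pp = photophysics_params()) {
  stopifnot(is.numeric(deltaF))
  lo <- deltaF_from_pH(3, pp)
  hi <- deltaF_from_pH(10, pp)
  if (any(deltaF < lo | deltaF > hi)) {
    stop(sprintf(
      "deltaF outside the invertible range [%.4f, %.4f]", lo, hi),
      call. = FALSE)
  }
  y <- .hill_frac(pp$ph_rest, pp$pKa, pp$nH) +
    deltaF / (1 + 10^(pp$nH * (pp$pKa - pp$ph_surface)))
  pp$pKa - (1 / pp$nH) * log10(1 / y - 1)
}
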