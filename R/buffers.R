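#' A luminal proton buffer species
#'
#' @param name label of the species.
#' @param conc_mM concentration of buffering groups, mM (>= 0).
#' @param pKa acid dissociation constant of the buffering group.
#' @param mobile logical; `TRUE` for exogenous solutes engulfed with the
#'   extracellular medium, `FALSE` for groups fixed in the luminal protein
#'   matrix.
#' @return An object of class `buffer_species`.
#' @export
buffer_species <- function(name, conc_mM, pKa, mobile = TRUE) {
  stopifnot(conc_mM >= 0)
  structure(list(name = name, conc_mM = conc_mM, pKa = pKa,
                 mobile = mobile), class = "buffer_species")
}

#' Endogenous buffers of the vesicle lumen
#'
#' Histidine (pKa 6) and glutamate (pKa 4) residues of the luminal protein
#' matrix, the relevant endogenous proton buffers of a synaptic vesicle.
#'
#' @return List of [buffer_species()].
#' @export
endogenous_buffers <- function() {
  list(buffer_species("matrix histidine", 13, 6, mobile = FALSE),
       buffer_species("matrix glutamate", 47, 4, mobile = FALSE))
}

#' Protonated fraction of a buffer at a given pH
#'
#' From the Henderson-Hasselbalch relation
#' \eqn{pH = pK_a + \log_{10}([A^-]/[HA])}, the fraction of groups in the
#' protonated form is \eqn{1/(1 + 10^{pH - pK_a})}.
#'
#' @param pH pH.
#' @param pKa acid dissociation constant.
#' @return Fraction in \[0, 1\], vectorised.
#' @export
buffer_bound_fraction <- function(pH, pKa) {
  1 / (1 + 10^(pH - pKa))
}

#' Protons taken up by buffers during an acidification step
#'
#' Counts the protons that bind to a set of buffers when the luminal pH
#' moves from `pH_start` down to `pH_end` in a compartment of volume
#' `volume_l`:
#' \deqn{\sum_b N_b\,[f_b(pH_{end}) - f_b(pH_{start})],\qquad
#'   N_b = c_b V N_A.}
#'
#' @param buffers list of [buffer_species()].
#' @param pH_start initial pH (more basic).
#' @param pH_end final pH (more acidic).
#' @param volume_l compartment volume in litres.
#' @return Number of protons bound (molecules).
#' @examples
#' # exogenous HEPES + histidine plus the endogenous matrix buffers of a
#' # 20e-21 l vesicle acidifying from 7.3 to 6.4 bind ~156 protons
#' b <- c(list(buffer_species("HEPES", 25, 7.55),
#'             buffer_species("histidine", 10, 6)), endogenous_buffers())
#' bound_protons(b, 7.3, 6.4, 20e-21)
#' @export
bound_protons <- function(buffers, pH_start, pH_end, volume_l = 20e-21) {
  if (pH_end > pH_start) {
    stop("pH_end must not exceed pH_start (acidification step)",
         call. = FALSE)
  }
  sum(vapply(buffers, function(b) {
    .molecules(b$conc_mM, volume_l) *
      (buffer_bound_fraction(pH_end, b$pKa) -
         buffer_bound_fraction(pH_start, b$pKa))
  }, numeric(1)))
}
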