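## Water-potential and osmolarity arithmetic.
##
## Media conditions are reported in mOsm; their osmotic (solute) component
## of water potential follows the van't Hoff relation Psi_s = -i C R T with
## R in L MPa / (mol K), so a 1,800 mOsm solution at 298.15 K sits near
## -4.5 MPa and 12 mOsm near -0.03 MPa.

#' Gas constant in L MPa mol^-1 K^-1
#' @noRd
GAS_CONSTANT_L_MPA <- 0.008314

#' Solute (osmotic) potential of a solution
#'
#' Evaluates the van't Hoff relation \eqn{\Psi_s = -iCRT} with
#' \eqn{R = 0.008314} L MPa mol\eqn{^{-1}} K\eqn{^{-1}}. Osmolarity is given
#' in mOsm (milliosmoles per litre of osmotically effective particles) and
#' converted to osmol/L internally, so the van't Hoff factor defaults to 1:
#' dissociation is already counted in the osmolarity.
#'
#' @param osmolarityMosm osmolarity in mOsm (>= 0); vectorized.
#' @param temperatureK absolute temperature in K (> 0). Default 298.15 K.
#' @param ionization van't Hoff ionization factor i (>= 1).
#' @return Solute potential in MPa, always <= 0 (0 for pure water).
#' @examples
#' solutePotential(0)                    # pure water: 0 MPa
#' signif(solutePotential(1800), 2)      # -4.5 MPa
#' signif(solutePotential(12), 1)        # -0.03 MPa
#' @seealso [waterPotential()], [foldRange()]
#' @export
solutePotential <- function(osmolarityMosm, temperatureK = 298.15,
                            ionization = 1) {
  if (any(!is.finite(osmolarityMosm)) || any(osmolarityMosm < 0))
    pcoStop("invalid_input", "osmolarity must be finite and >= 0 mOsm")
  if (any(!is.finite(temperatureK)) || any(temperatureK <= 0))
    pcoStop("invalid_input", "temperature must be finite and > 0 K")
  if (any(!is.finite(ionization)) || any(ionization < 1))
    pcoStop("invalid_input", "ionization factor must be >= 1")
  -ionization * (osmolarityMosm / 1000) * GAS_CONSTANT_L_MPA * temperatureK
}

#' Total water potential from its components
#'
#' Sums the solute, pressure (turgor) and matric components,
#' \eqn{\Psi_w = \Psi_s + \Psi_p + \Psi_m}.
#'
#' @param psiS solute potential, MPa (<= 0).
#' @param psiP pressure (turgor) potential, MPa.
#' @param psiM matric potential, MPa.
#' @return Named numeric vector with \code{psi_s}, \code{psi_p},
#'   \code{psi_m} and their sum \code{psi_w}, all in MPa.
#' @examples
#' waterPotential(-1.0, 0.6, -0.1)["psi_w"]   # -0.5 MPa
#' @export
waterPotential <- function(psiS, psiP = 0, psiM = 0) {
  comps <- c(psiS, psiP, psiM)
  if (length(comps) != 3L || any(!is.finite(comps)))
    pcoStop("invalid_input", "psiS, psiP, psiM must be finite scalars")
  if (psiS > 0)
    pcoStop("invalid_input", "solute potential cannot be positive")
  c(psi_s = psiS, psi_p = psiP, psi_m = psiM, psi_w = psiS + psiP + psiM)
}

#' Fold difference between two osmolarities
#'
#' @param minMosm lower osmolarity, mOsm (> 0).
#' @param maxMosm upper osmolarity, mOsm (>= \code{minMosm}).
#' @return Dimensionless fold ratio \code{maxMosm / minMosm}.
#' @examples
#' foldRange(12, 1800)   # 150
#' @export
foldRange <- function(minMosm, maxMosm) {
  if (any(!is.finite(c(minMosm, maxMosm))) || minMosm <= 0)
    pcoStop("invalid_input", "minMosm must be finite and > 0")
  if (maxMosm < minMosm)
    pcoStop("invalid_input", "maxMosm must be >= minMosm")
  maxMosm / minMosm
}
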