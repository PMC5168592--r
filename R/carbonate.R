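#' Carbonate equilibrium constants
#'
#' Henry-type solubility coefficient and the two dissociation constants of the
#' carbonate system. Defaults are the values at 80 degrees C, the culture
#' temperature of a hyperthermophilic fermentation: K0 = 0.0127 mol L^-1
#' bar^-1, K1 = 4.93e-7 mol L^-1, K2 = 8.18e-11 mol L^-1. No temperature
#' interpolation is attempted; override the constants for other temperatures.
#'
#' @param K0 CO2 solubility, mol L^-1 bar^-1.
#' @param K1 first dissociation constant of carbonic acid, mol L^-1.
#' @param K2 second dissociation constant, mol L^-1.
#' @param T temperature the constants refer to, degrees Celsius (metadata).
#' @return An object of class `carbonate_constants`.
#' @export
carbonate_constants <- function(K0 = 0.0127, K1 = 4.93e-7, K2 = 8.18e-11,
                                T = 80) {
  if (K0 <= 0 || K1 <= 0 || K2 <= 0) {
    .stopf("equilibrium constants must all be positive")
  }
  structure(list(K0 = K0, K1 = K1, K2 = K2, T = T),
            class = "carbonate_constants")
}

#' Dissolved CO2 speciation from headspace partial pressure and pH
#'
#' Computes the three dissolved carbonate species in equilibrium with a CO2
#' partial pressure at a given pH: aqueous CO2 from Henry's law
#' (`K0 * pCO2`), bicarbonate from the first dissociation
#' (`K1 * [CO2]aq / [H+]`) and carbonate from the second
#' (`K2 * [HCO3-] / [H+]`), with `[H+] = 10^-pH`.
#'
#' @param pCO2 CO2 partial pressure in the headspace, bar.
#' @param pH culture pH; must lie in (0, 14).
#' @param constants a [carbonate_constants()] object.
#' @return An object of class `carbonate_speciation`: list with `co2_aq`,
#'   `hco3`, `co3` and `total`, all mol L^-1.
#' @examples
#' sp <- speciate(1, 7)
#' sp$co2_aq # 0.0127 mol/L
#' sp$hco3   # ~0.0626 mol/L
#' @export
speciate <- function(pCO2, pH, constants = carbonate_constants()) {
  if (!is.finite(pCO2) || pCO2 < 0) .stopf("'pCO2' must be non-negative")
  if (!is.finite(pH) || pH <= 0 || pH >= 14) {
    .stopf("'pH' must lie strictly between 0 and 14")
  }
  h <- 10^(-pH)
  co2_aq <- constants$K0 * pCO2
  hco3 <- constants$K1 * co2_aq / h
  co3 <- constants$K2 * hco3 / h
  structure(
    list(co2_aq = co2_aq, hco3 = hco3, co3 = co3,
         total = co2_aq + hco3 + co3, pH = pH, pCO2 = pCO2),
    class = "carbonate_speciation"
  )
}

#' @export
print.carbonate_speciation <- function(x, ...) {
  cat(sprintf("Carbonate speciation at pCO2 = %g bar, pH %g\n", x$pCO2, x$pH))
  cat(sprintf("  [CO2]aq : %.4g mol/L\n", x$co2_aq))
  cat(sprintf("  [HCO3-] : %.4g mol/L\n", x$hco3))
  cat(sprintf("  [CO3 2-]: %.4g mol/L\n", x$co3))
  cat(sprintf("  total   : %.4g mol/L\n", x$total))
  invisible(x)
}

#' Dissolved CO2 inventory of the liquid phase
#'
#' Total carbonate-system carbon held in the culture liquid at equilibrium
#' with the headspace, to be added to the cumulative gas-phase CO2 when
#' closing the carbon balance of a run.
#'
#' @inheritParams speciate
#' @param liquid_volume working liquid volume, L.
#' @return Dissolved CO2 inventory, mmol.
#' @examples
#' total_dissolved_co2(0.05, 7, 1.5)
#' @export
total_dissolved_co2 <- function(pCO2, pH, liquid_volume = 1.5,
                                constants = carbonate_constants()) {
  if (!is.finite(liquid_volume) || liquid_volume < 0) {
    .stopf("'liquid_volume' must be non-negative")
  }
  speciate(pCO2, pH, constants)$total * 1000 * liquid_volume
}
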