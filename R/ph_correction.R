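#' Protonation-state thermodynamic cycle
#'
#' Inputs of the pH correction for a titratable guest: the binding free
#' energies of the protonated (HL+) and neutral (L) species, the free-state
#' pKa, and the experimental pH.
#'
#' @param dG_protonated Binding free energy of the protonated species
#'   (kcal/mol).
#' @param dG_neutral Binding free energy of the neutral species (kcal/mol).
#' @param pKa_free pKa of the free guest (pH units).
#' @param pH Experimental pH.
#' @param temperature Temperature (K).
#' @return An object of class `protonation_cycle`.
#' @export
protonation_cycle <- function(dG_protonated, dG_neutral, pKa_free = 7.5,
                              pH = 7.4, temperature = 298.15) {
  stopifnot(is.finite(dG_protonated), is.finite(dG_neutral),
            is.finite(pKa_free), is.finite(pH), temperature > 0)
  structure(list(dG_protonated = dG_protonated, dG_neutral = dG_neutral,
                 pKa_free = pKa_free, pH = pH, temperature = temperature),
            class = "protonation_cycle")
}

# ln(1 + 10^x), overflow-safe.
log1p10 <- function(x) ifelse(x > 30, x * log(10), log1p(10^x))

#' Bound-state pKa from the binding free-energy gap
#'
#' \deqn{pK_a^{Bound} = pK_a^{Free} + \frac{\beta}{\ln 10}\,(\Delta A_{bind}^L
#' - \Delta A_{bind}^{HL^+})} -- binding that favours the protonated species
#' raises the bound-state pKa.
#'
#' @param cycle A [protonation_cycle()].
#' @return Bound-state pKa (pH units).
#' @export
pka_bound <- function(cycle) {
  kBT <- KB_KCAL * cycle$temperature
  cycle$pKa_free + (cycle$dG_neutral - cycle$dG_protonated) / (kBT * log(10))
}

#' pH-corrected binding free energy
#'
#' Thermodynamic-cycle correction for a guest whose protonation state is
#' uncertain at the experimental pH:
#' \deqn{\Delta G_{bind}^{pH} = \Delta G_{bind}^{HL^+} - k_B T \ln
#' \frac{1 + 10^{pH - pK_a^{Bound}}}{1 + 10^{pH - pK_a^{Free}}}}
#' evaluated with an overflow-safe log-sum form.  When the bound-state pKa far
#' exceeds the pH the bound guest is fully protonated and the result reduces
#' to `dG_protonated`.
#'
#' @param cycle A [protonation_cycle()].
#' @return Corrected binding free energy (kcal/mol), with the bound pKa in
#'   attribute `"pKa_bound"`.
#' @export
ph_corrected_dg <- function(cycle) {
  kBT <- KB_KCAL * cycle$temperature
  pkb <- pka_bound(cycle)
  val <- cycle$dG_protonated -
    kBT * (log1p10(cycle$pH - pkb) - log1p10(cycle$pH - cycle$pKa_free))
  attr(val, "pKa_bound") <- pkb
  val
}
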