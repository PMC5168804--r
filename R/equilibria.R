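#' Henry's-law equilibrium dissolved concentration
#'
#' Dissolved concentration in equilibrium with a headspace molar
#' concentration: `C* = Kh * R * T * C_gas`. With `Kh` in mol/L/Pa, `R` in
#' Pa L/mol/K and `T` in K, the relation is linear and homogeneous in
#' `gas_conc` and unit-consistent for `gas_conc` in mmol/L.
#'
#' @param gas_conc headspace molar concentration (mmol per L of gas),
#'   non-negative; vectorised.
#' @param species one of `"h2"`, `"co2"`, `"h2s"`.
#' @param cc a [physical_constants()] object.
#' @return equilibrium dissolved concentration (mmol/L).
#' @export
#' @examples
#' cc <- physical_constants()
#' # pure H2 at 1 atm: gas_conc = P/(R T)
#' henry_equilibrium(cc$gas_molar_density, "h2", cc)  # ~0.72 mmol/L
henry_equilibrium <- function(gas_conc, species = c("h2", "co2", "h2s"), cc) {
  species <- match.arg(species)
  if (any(gas_conc < 0)) stop("'gas_conc' must be non-negative")
  kh <- switch(species, h2 = cc$kh_h2, co2 = cc$kh_co2, h2s = cc$kh_h2s)
  kh * cc$r_gas * cc$temp_k * gas_conc
}

#' Acid-base interconversion rates at fixed pH
#'
#' Net relaxation rates of the CO2/HCO3- and H2S/HS- couples toward their
#' dissociation equilibria at the (controlled) culture pH. At equilibrium
#' `HCO3/CO2 = K1/10^-pH` and `HS/H2S = K2/10^-pH`; the couples relax there
#' with first-order rate constant `k_ab`. Protonation is fast relative to
#' fermentation, so the default rate constant used by the simulator keeps the
#' couples near equilibrium.
#'
#' @param co2_l,hco3,h2s_l,hs dissolved CO2, bicarbonate, H2S and bisulfide
#'   concentrations (mmol/L), non-negative.
#' @param cc a [physical_constants()] object.
#' @param k_ab interconversion rate constant (1/h), > 0.
#' @return list with `into_hco3` and `into_hs`, the net rates (mmol/L/h) into
#'   the ionic form of each couple (negative when the couple relaxes back).
#' @export
#' @examples
#' cc <- physical_constants()
#' speciation_rates(1, 13.7, 0, 0, cc, k_ab = 1)$into_hco3  # ~0 at equilibrium
speciation_rates <- function(co2_l, hco3, h2s_l, hs, cc, k_ab = 1000) {
  if (k_ab <= 0) stop("'k_ab' must be > 0")
  if (any(c(co2_l, hco3, h2s_l, hs) < 0))
    stop("concentrations must be non-negative")
  h <- 10^(-cc$ph)
  list(into_hco3 = k_ab * ((cc$k1 / h) * co2_l - hco3),
       into_hs   = k_ab * ((cc$k2 / h) * h2s_l - hs))
}
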