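## State vector layout of the batch fermentation ODE system.
## Liquid solutes in mmol/L (biomass g/L), headspace gases in mmol per L of
## gas volume, cumulative bookkeeping in mmol (swept out) or mmol/L of liquid
## (produced/consumed).
.state_names <- c(
  "X",        # biomass (g/L)
  "S1",       # glucose + glucose-equivalent pool (mmol/L)
  "Yeast",    # yeast extract (g/L)
  "S2",       # thiosulfate + thiosulfate-equivalent pool (mmol/L)
  "Act",      # acetate (mmol/L)
  "Lact",     # lactate (mmol/L)
  "H2l", "CO2l", "H2Sl",   # dissolved gases (mmol/L)
  "HCO3", "HS",            # ionic species (mmol/L)
  "H2g", "CO2g", "H2Sg",   # headspace gases (mmol/L gas)
  "cumH2out", "cumCO2out", "cumH2Sout",  # swept out of reactor (mmol)
  "cumH2prod", "cumH2cons", "cumGluCons" # mmol/L liquid, bookkeeping
)

#' Initial ODE state for a batch run
#'
#' Builds the named initial state vector. The glucose and thiosulfate pools
#' fold in the yeast-extract equivalents: `S1(0) = Glu0 + eps1 * Yeast0` and
#' `S2(0) = Thio0 + eps2 * Yeast0` (the model tracks the pooled sums, for
#' which the balance laws are written). Headspace starts as pure carrier gas
#' unless the inlet carries H2, in which case the headspace starts at the
#' inlet composition.
#'
#' @param p a [model_parameters()] object.
#' @param cc a [physical_constants()] object.
#' @param oc an [operating_conditions()] object.
#' @return named numeric state vector.
#' @export
initial_state <- function(p, cc, oc) {
  y <- stats::setNames(numeric(length(.state_names)), .state_names)
  y["X"] <- oc$x0
  y["S1"] <- oc$glu0 + p$eps1 * oc$yeast0
  y["Yeast"] <- oc$yeast0
  y["S2"] <- oc$thio0 + p$eps2 * oc$yeast0
  if (oc$y_h2_in > 0) {
    # H2-enriched sparging: headspace and medium are pre-equilibrated with
    # the inlet mixture before inoculation
    y["H2g"] <- oc$y_h2_in * cc$gas_molar_density
    y["H2l"] <- henry_equilibrium(y[["H2g"]], "h2", cc)
  }
  y
}

#' Specific growth rate
#'
#' Multi-substrate Monod kinetics with dissolved-H2 product inhibition:
#' `mu = mu_max * M(S1; Ks_glu) * M(Yeast; Ks_yeast) * M(S2; Ks_thio) *
#' max(0, 1 - (H2/H2crit)^N)` where `M(S; K) = S/(S + K)` and `S1`, `S2` are
#' the glucose and thiosulfate pools including yeast-extract equivalents.
#'
#' @param state named state vector (needs `S1`, `Yeast`, `S2`, `H2l`), all
#'   non-negative; see [initial_state()].
#' @param p a [model_parameters()] object.
#' @return specific growth rate (1/h), in `[0, mu_max]`.
#' @export
#' @examples
#' p <- model_parameters()
#' s <- c(S1 = 1e9, Yeast = 1e9, S2 = 1e9, H2l = 0)
#' growth_rate(s, p)  # mu_max = 0.9
growth_rate <- function(state, p) {
  for (nm in c("S1", "Yeast", "S2", "H2l")) {
    v <- state[[nm]]
    if (!is.finite(v)) stop("state field '", nm, "' is not finite")
    if (v < 0) stop("state field '", nm, "' is negative")
  }
  monod <- function(s, k) if (s == 0 && k == 0) 1 else s / (s + k)
  p$mu_max *
    monod(state[["S1"]], p$ks_glu) *
    monod(state[["Yeast"]], p$ks_yeast) *
    monod(state[["S2"]], p$ks_thio) *
    inhibition_factor(state[["H2l"]], p)
}

## Maintenance switches off smoothly as the glucose pool empties; the small
## half-saturation (mmol/L) only regularises depletion, it is far below Ks.
.maintenance_gate_k <- 0.02

#' Kinetic and transfer rate decomposition at a state
#'
#' Evaluates every elementary rate of the model at one state: specific growth
#' rate, specific glucose consumption, volumetric product formation and
#' H2-consumption rates, gas-liquid transfer rates and the outlet gas flow.
#' These components are exactly the terms summed by [fermentation_rhs()].
#'
#' @param state named state vector (see [initial_state()]); negative entries
#'   are clipped to zero (integrator round-off).
#' @param p,cc,oc parameter/constant/condition objects.
#' @param kla named per-gas transfer coefficients `c(h2=, co2=, h2s=)` (1/h).
#' @param k_ab acid-base interconversion rate constant (1/h).
#' @return list with `mu` (1/h), `q_glu` (mmol/g/h), volumetric rates
#'   (mmol/L/h) `r_act`, `r_lact`, `r_h2_prod`, `r_h2_cons`, `r_co2_prod`,
#'   `r_h2s_prod`, transfer rates `transfer_h2`, `transfer_co2`,
#'   `transfer_h2s` (mmol/L liquid/h, liquid to gas positive), and `q_g`
#'   outlet gas flow (L/h).
#' @export
rate_breakdown <- function(state, p, cc, oc, kla, k_ab = 1000) {
  if (any(!is.finite(unlist(state))))
    stop("non-finite state passed to rate_breakdown")
  s <- pmax(unlist(state), 0)

  mu <- growth_rate(s, p)
  # specific glucose consumption, growth + maintenance (gated at depletion)
  gate <- s[["S1"]] / (s[["S1"]] + .maintenance_gate_k)
  q_glu <- mu / p$y_x_glu_mmol + p$m_glu * gate

  a <- acetate_yield(s[["H2l"]], p)
  b <- lactate_yield(a, p)

  qx <- q_glu * s[["X"]]                       # mmol glucose/L/h
  r_act <- a * qx
  r_lact <- b * qx
  r_h2_prod <- 2 * a * qx
  r_co2_prod <- a * qx
  # thiosulfate reduction: H2S formed and H2 consumed scale with growth
  r_h2s_prod <- (p$y_h2s_thio / p$y_x_thio_h2s) * mu * s[["X"]]
  r_h2_cons <- p$y_h2_h2s * r_h2s_prod

  transfer_h2 <- kla[["h2"]] *
    (s[["H2l"]] - henry_equilibrium(s[["H2g"]], "h2", cc))
  transfer_co2 <- kla[["co2"]] *
    (s[["CO2l"]] - henry_equilibrium(s[["CO2g"]], "co2", cc))
  transfer_h2s <- kla[["h2s"]] *
    (s[["H2Sl"]] - henry_equilibrium(s[["H2Sg"]], "h2s", cc))

  # molar transfer -> volumetric gas flow at reactor T, P
  per_mmol <- 1 / cc$gas_molar_density          # L of gas per mmol
  q_g <- max(0, oc$q_n2 + oc$v_l * per_mmol *
               (transfer_h2 + transfer_co2 + transfer_h2s))

  list(mu = mu, q_glu = q_glu,
       r_act = r_act, r_lact = r_lact,
       r_h2_prod = r_h2_prod, r_h2_cons = r_h2_cons,
       r_co2_prod = r_co2_prod, r_h2s_prod = r_h2s_prod,
       transfer_h2 = transfer_h2, transfer_co2 = transfer_co2,
       transfer_h2s = transfer_h2s, q_g = q_g)
}

#' Right-hand side of the batch fermentation ODE system
#'
#' Time derivative of the full state: biomass growth and death, substrate
#' pools (glucose + maintenance, yeast extract, thiosulfate), acetate and
#' lactate with inhibition-dependent instantaneous yields, dissolved H2 / CO2
#' / H2S with production, consumption by thiosulfate reduction, acid-base
#' speciation and gas-liquid transfer, ionic species, headspace balances with
#' stripping by the (possibly H2-enriched) inlet gas, and cumulative
#' bookkeeping states.
#'
#' @param t time (h); the system is autonomous, `t` is unused.
#' @param state named state vector.
#' @param p,cc,oc parameter/constant/condition objects.
#' @param kla named per-gas transfer coefficients (1/h).
#' @param k_ab acid-base interconversion rate constant (1/h).
#' @return list whose first element is the derivative vector (deSolve
#'   convention), followed by diagnostic scalars `mu`, `q_g`, `r_h2_prod` and
#'   `inhibition` (the ratio H2l/H2crit).
#' @export
fermentation_rhs <- function(t, state, p, cc, oc, kla, k_ab = 1000) {
  rb <- rate_breakdown(state, p, cc, oc, kla, k_ab)
  s <- pmax(unlist(state), 0)
  x <- s[["X"]]

  spec <- speciation_rates(s[["CO2l"]], s[["HCO3"]], s[["H2Sl"]], s[["HS"]],
                           cc, k_ab)

  d <- stats::setNames(numeric(length(.state_names)), .state_names)
  d["X"] <- (rb$mu - p$mu_d) * x
  d["S1"] <- -rb$q_glu * x
  d["Yeast"] <- -rb$mu * x / p$y_x_yeast
  d["S2"] <- -rb$mu * x / p$y_x_thio_total
  d["Act"] <- rb$r_act
  d["Lact"] <- rb$r_lact
  d["H2l"] <- -rb$transfer_h2 + rb$r_h2_prod - rb$r_h2_cons
  d["CO2l"] <- -rb$transfer_co2 + rb$r_co2_prod - spec$into_hco3
  d["H2Sl"] <- -rb$transfer_h2s + rb$r_h2s_prod - spec$into_hs
  d["HCO3"] <- spec$into_hco3
  d["HS"] <- spec$into_hs

  vr <- oc$v_l / oc$v_g
  inlet_h2 <- oc$q_n2 * oc$y_h2_in * cc$gas_molar_density / oc$v_g
  d["H2g"] <- vr * rb$transfer_h2 - (rb$q_g / oc$v_g) * s[["H2g"]] + inlet_h2
  d["CO2g"] <- vr * rb$transfer_co2 - (rb$q_g / oc$v_g) * s[["CO2g"]]
  d["H2Sg"] <- vr * rb$transfer_h2s - (rb$q_g / oc$v_g) * s[["H2Sg"]]

  d["cumH2out"] <- rb$q_g * s[["H2g"]]
  d["cumCO2out"] <- rb$q_g * s[["CO2g"]]
  d["cumH2Sout"] <- rb$q_g * s[["H2Sg"]]
  d["cumH2prod"] <- rb$r_h2_prod
  d["cumH2cons"] <- rb$r_h2_cons
  d["cumGluCons"] <- rb$q_glu * x

  # guard against negative-state drift: never push a depleted pool negative
  at_zero <- unlist(state) <= 0 & d < 0
  d[at_zero] <- 0

  if (any(!is.finite(d))) {
    bad <- .state_names[!is.finite(d)]
    stop("non-finite derivative for state(s): ", paste(bad, collapse = ", "))
  }
  list(d, mu = rb$mu, q_g = rb$q_g, r_h2_prod = rb$r_h2_prod,
       inhibition = s[["H2l"]] / p$h2_crit)
}
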