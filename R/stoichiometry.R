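#' Dissolved-hydrogen inhibition factor
#'
#' The inhibition term `max(0, 1 - (H2/H2crit)^N)` applied to both the
#' specific growth rate and the acetate yield. At `h2_l = 0` there is no
#' inhibition; at `h2_l >= h2_crit` growth and acetate production stop.
#'
#' @param h2_l dissolved H2 concentration (mmol/L), non-negative.
#' @param p a [model_parameters()] object.
#' @return factor in `[0, 1]` (vectorised over `h2_l`).
#' @export
inhibition_factor <- function(h2_l, p) {
  if (any(h2_l < 0)) stop("'h2_l' must be non-negative")
  pmax(0, 1 - (h2_l / p$h2_crit)^p$n_inhib)
}

#' Instantaneous acetate yield on glucose
#'
#' Acetate yield declines with dissolved H2 as
#' `Y_act = Y_act_max * (1 - (H2/H2crit)^N)`; H2 inhibits its own production
#' and hence the acetate branch that generates it.
#'
#' @inheritParams inhibition_factor
#' @return yield in mol acetate / mol glucose, in `[0, y_act_glu_max]`.
#' @export
#' @examples
#' p <- model_parameters()
#' acetate_yield(0, p)      # 1.38, uninhibited maximum
#' acetate_yield(1.44, p)   # 0, fully inhibited
acetate_yield <- function(h2_l, p) {
  p$y_act_glu_max * inhibition_factor(h2_l, p)
}

#' Instantaneous lactate yield on glucose by carbon difference
#'
#' Lactate receives the consumed-glucose carbon not accounted for by acetate,
#' CO2, biomass and EPS. With acetate yield `a` (and hence CO2 yield `a`), and
#' fractions `f_biomass_c + f_eps_c` of glucose carbon retained in biomass and
#' EPS, the balance on 6 carbons per glucose gives
#' `b = (6 * (1 - f_biomass_c - f_eps_c) - 3 a) / 3`, floored at zero.
#' As dissolved H2 rises and `a` falls, `b` rises: the metabolic shift from
#' acetate toward lactate under inhibition.
#'
#' @param a acetate yield (mol/mol glucose), in `[0, y_act_glu_max]`.
#' @param p a [model_parameters()] object.
#' @return lactate yield in mol/mol glucose (vectorised over `a`).
#' @export
#' @examples
#' p <- model_parameters()
#' lactate_yield(1.38, p)  # 0.08: small lactate flux when uninhibited
#' lactate_yield(0, p)     # 1.46: all fermentable carbon to lactate
lactate_yield <- function(a, p) {
  if (any(a < 0)) stop("'a' must be non-negative")
  pmax(0, (6 * (1 - p$f_biomass_c - p$f_eps_c) - 3 * a) / 3)
}

#' Derived fermentation stoichiometry at a given acetate yield
#'
#' Closes the glucose fermentation equation
#' glucose -> a acetate + b lactate + 2a H2 + a CO2 + biomass + EPS
#' at a given instantaneous acetate yield: returns the product coefficients
#' and the carbon-closure term, and checks the 6-carbon balance.
#'
#' @inheritParams lactate_yield
#' @return list with `a` (acetate, = CO2 coefficient), `h2 = 2a`, `b`
#'   (lactate), `carbon_closure` (mol C per mol glucose retained in biomass +
#'   EPS) and `carbon_balance` (total C accounted per glucose; 6 exactly when
#'   the lactate floor is not active).
#' @export
stoichiometry_derived <- function(a, p) {
  if (length(a) != 1L || a < 0) stop("'a' must be a non-negative scalar")
  if (a > p$y_act_glu_max + 1e-9)
    stop("'a' exceeds the maximal acetate yield")
  b <- lactate_yield(a, p)
  list(a = a, h2 = 2 * a, b = b,
       carbon_closure = p$carbon_closure,
       carbon_balance = 2 * a + a + 3 * b + p$carbon_closure)
}

#' Pirt maintenance correction of an observed biomass yield
#'
#' Removes the maintenance share of substrate consumption from an observed
#' (total) yield: `1/y_true = 1/y_obs - m/mu`. Requires `1/y_obs > m/mu`;
#' otherwise maintenance alone would exceed the observed consumption and no
#' positive true yield exists.
#'
#' @param y_obs observed yield (g biomass / mol substrate).
#' @param m maintenance coefficient (mmol substrate / g biomass / h).
#' @param mu specific growth rate at which `y_obs` was observed (1/h).
#' @return true growth yield (g/mol).
#' @export
#' @examples
#' maintenance_correction(20.4, 2.2, 0.9)  # ~21.5 g/mol
maintenance_correction <- function(y_obs, m, mu) {
  if (y_obs <= 0 || m < 0 || mu <= 0)
    stop("require y_obs > 0, m >= 0, mu > 0")
  inv <- 1 / y_obs - (m / 1000) / mu   # m is mmol/g/h, yield is g/mol
  if (inv <= 0)
    stop("no positive growth yield: maintenance consumption (m/mu) ",
         "exceeds observed specific consumption (1/y_obs)")
  1 / inv
}
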