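#' Physical constants of the fermentation system
#'
#' Builds the set of physico-chemical constants used throughout the model:
#' acid dissociation constants of the CO2/HCO3- and H2S/HS- couples, Henry
#' constants of the three product gases, aqueous diffusivities at 80 degC,
#' the gas constant, operating temperature, pH and headspace pressure.
#' Defaults are the values used for *T. maritima* cultivated at 80 degC,
#' pH 7 and atmospheric headspace pressure.
#'
#' The default H2 diffusivity is 1.4e-4 cm2/s. Published tabulations of this
#' system sometimes carry 1.4e-5, but only 1.4e-4 is consistent with the
#' reference volumetric transfer coefficient KlaH2 = 114 1/h at 100 mL/min
#' (see [scale_kla()]) and with H2 diffusing faster than O2 in water.
#'
#' @param k1 CO2/HCO3- dissociation constant (mol/kg).
#' @param k2 H2S/HS- dissociation constant (mol/kg).
#' @param kh_h2,kh_co2,kh_h2s Henry constants (mol/L/Pa).
#' @param d_o2,d_h2,d_co2,d_h2s aqueous diffusivities at 80 degC (cm2/s).
#' @param r_gas gas constant (Pa L/mol/K).
#' @param temp_c temperature (degC).
#' @param ph culture pH (held constant by base addition).
#' @param p_total headspace pressure (Pa).
#'
#' @return An object of class `physical_constants`: a named list of the above
#'   plus derived fields `temp_k` (K) and `gas_molar_density` (mmol of gas per
#'   L of headspace at `p_total` and `temp_k`).
#' @export
#' @examples
#' cc <- physical_constants()
#' cc$gas_molar_density  # ~34.5 mmol/L at 80 degC, 1 atm
physical_constants <- function(k1 = 1.37e-6, k2 = 2.2e-7,
                               kh_h2 = 7.1e-9, kh_co2 = 1.33e-7,
                               kh_h2s = 2.1e-7,
                               d_o2 = 0.46e-4, d_h2 = 1.4e-4,
                               d_co2 = 0.66e-4, d_h2s = 0.46e-4,
                               r_gas = 8.314e3, temp_c = 80, ph = 7,
                               p_total = 101325) {
  cc <- list(k1 = k1, k2 = k2,
             kh_h2 = kh_h2, kh_co2 = kh_co2, kh_h2s = kh_h2s,
             d_o2 = d_o2, d_h2 = d_h2, d_co2 = d_co2, d_h2s = d_h2s,
             r_gas = r_gas, temp_c = temp_c, ph = ph, p_total = p_total)
  for (nm in names(cc)) {
    if (!is.numeric(cc[[nm]]) || length(cc[[nm]]) != 1L || !is.finite(cc[[nm]]))
      stop("physical constant '", nm, "' must be a finite numeric scalar")
    if (nm != "temp_c" && cc[[nm]] <= 0)
      stop("physical constant '", nm, "' must be strictly positive")
  }
  if (ph < 0 || ph > 14) stop("'ph' must lie in [0, 14]")
  cc$temp_k <- temp_c + 273.15
  # mmol of ideal gas per litre of headspace
  cc$gas_molar_density <- 1000 * p_total / (r_gas * cc$temp_k)
  structure(cc, class = "physical_constants")
}

#' Per-carbon-mole molar mass of biomass
#'
#' Molar mass of one C-mole of cells from an elemental formula. The default
#' formula CH1.6O0.6N0.2S0.005 is the measured elemental composition of
#' *T. maritima*.
#'
#' @param formula named numeric vector of atoms per carbon (names among
#'   C, H, O, N, S).
#' @return molar mass in g per C-mol.
#' @export
#' @examples
#' biomass_molar_mass()  # ~26.2 g/C-mol
biomass_molar_mass <- function(formula = c(C = 1, H = 1.6, O = 0.6,
                                           N = 0.2, S = 0.005)) {
  masses <- c(C = 12.011, H = 1.008, O = 15.999, N = 14.007, S = 32.06)
  if (is.null(names(formula)) || !all(names(formula) %in% names(masses)))
    stop("'formula' must be named with elements among ", paste(names(masses), collapse = ", "))
  sum(masses[names(formula)] * formula)
}

#' Biomass yield on incorporated thiosulfate from elemental composition
#'
#' Thiosulfate used anabolically supplies two sulfur atoms per molecule, so
#' the biomass formed per mmol thiosulfate incorporated is
#' 2 * M_biomass / nS, with M_biomass the per-C-mole molar mass and nS the
#' sulfur index of the elemental formula.
#'
#' @inheritParams biomass_molar_mass
#' @return yield in g biomass per mmol thiosulfate.
#' @export
#' @examples
#' thio_incorporation_yield()  # 10.47 g/mmol
thio_incorporation_yield <- function(formula = c(C = 1, H = 1.6, O = 0.6,
                                                 N = 0.2, S = 0.005)) {
  if (!"S" %in% names(formula) || formula[["S"]] <= 0)
    stop("'formula' must contain a positive sulfur index")
  2 * biomass_molar_mass(formula) / formula[["S"]] / 1000
}

#' Kinetic, yield and inhibition parameters of the growth model
#'
#' Builds the full parameter set of the batch fermentation model. Defaults are
#' the experimentally determined values for *T. maritima* MSB8 grown on
#' glucose / yeast extract / thiosulfate at 80 degC, pH 7.
#'
#' Two identities are enforced at construction rather than left to the user:
#' the glucose fermentation stoichiometry fixes
#' `y_h2_glu_max = 2 * y_act_glu_max` and `y_co2_glu_max = y_act_glu_max`
#' (1 glucose -> a acetate + 2a H2 + a CO2 + lactate + biomass + EPS), and the
#' total biomass-on-thiosulfate yield combines its anabolic and dissimilatory
#' components in parallel, `1/y_x_thio_total = 1/y_x_thio_x + 1/y_x_thio_h2s`
#' (both routes consume thiosulfate in proportion to growth). A supplied
#' `y_x_thio_total` deviating from the reciprocal combination by more than 5%
#' triggers a warning with the computed discrepancy.
#'
#' Mixed literature units (g/mol for the glucose yield) are converted once
#' here; the stored `y_x_glu_mmol` (g/mmol) is what the ODE uses.
#'
#' @param mu_max maximum specific growth rate (1/h).
#' @param mu_d cell death rate (1/h).
#' @param m_glu maintenance coefficient (mmol glucose/g biomass/h).
#' @param y_x_glu biomass yield on glucose, maintenance-corrected (g/mol).
#' @param y_x_yeast biomass yield on yeast extract (g/g).
#' @param y_x_thio_x biomass per thiosulfate incorporated (g/mmol).
#' @param y_x_thio_h2s biomass per thiosulfate reduced to H2S (g/mmol).
#' @param y_x_thio_total total biomass-on-thiosulfate yield (g/mmol); default
#'   is the reciprocal combination of the two components.
#' @param ks_glu,ks_yeast,ks_thio apparent saturation constants (mmol/L, g/L,
#'   mmol/L).
#' @param h2_crit critical dissolved-H2 concentration at which growth and
#'   acetate production stop (mmol/L).
#' @param n_inhib inhibition exponent (dimensionless, > 0).
#' @param y_act_glu_max maximal acetate yield on glucose, at zero dissolved H2
#'   (mol/mol).
#' @param y_h2s_thio stoichiometric H2S per thiosulfate reduced (mol/mol).
#' @param y_h2_h2s stoichiometric H2 consumed per H2S formed (mol/mol).
#' @param eps1 glucose equivalent of yeast extract (mmol/g).
#' @param eps2 thiosulfate equivalent of yeast extract (mmol/g).
#' @param f_biomass_c,f_eps_c fractions of consumed-glucose carbon routed to
#'   biomass and to extracellular polysaccharides (dimensionless; sum < 1).
#'
#' @return An object of class `model_parameters` (named list) with the above
#'   plus derived fields `y_h2_glu_max`, `y_co2_glu_max`, `y_x_thio_total`,
#'   `y_x_glu_mmol` and `carbon_closure` (= 6 * (f_biomass_c + f_eps_c), mol
#'   glucose carbon per mol glucose retained in biomass + EPS).
#' @export
#' @examples
#' p <- model_parameters()
#' p$y_h2_glu_max   # 2.76 mol/mol
#' p$y_x_thio_total # ~3.6 g/mmol
model_parameters <- function(mu_max = 0.9, mu_d = 0.05, m_glu = 2.2,
                             y_x_glu = 20.9, y_x_yeast = 0.67,
                             y_x_thio_x = thio_incorporation_yield(),
                             y_x_thio_h2s = 5.52,
                             y_x_thio_total = NULL,
                             ks_glu = 5.7, ks_yeast = 0.30, ks_thio = 0.052,
                             h2_crit = 1.44, n_inhib = 1,
                             y_act_glu_max = 1.38,
                             y_h2s_thio = 2, y_h2_h2s = 2,
                             eps1 = 0.56, eps2 = 0.03,
                             f_biomass_c = 0.05, f_eps_c = 0.22) {
  p <- list(mu_max = mu_max, mu_d = mu_d, m_glu = m_glu,
            y_x_glu = y_x_glu, y_x_yeast = y_x_yeast,
            y_x_thio_x = y_x_thio_x, y_x_thio_h2s = y_x_thio_h2s,
            ks_glu = ks_glu, ks_yeast = ks_yeast, ks_thio = ks_thio,
            h2_crit = h2_crit, n_inhib = n_inhib,
            y_act_glu_max = y_act_glu_max,
            y_h2s_thio = y_h2s_thio, y_h2_h2s = y_h2_h2s,
            eps1 = eps1, eps2 = eps2,
            f_biomass_c = f_biomass_c, f_eps_c = f_eps_c)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
      stop("model parameter '", nm, "' must be a finite numeric scalar")
    if (p[[nm]] < 0) stop("model parameter '", nm, "' must be non-negative")
  }
  if (n_inhib <= 0) stop("'n_inhib' must be > 0")
  if (h2_crit <= 0) stop("'h2_crit' must be > 0")
  if (f_biomass_c + f_eps_c >= 1)
    stop("'f_biomass_c' + 'f_eps_c' must be < 1")

  reciprocal <- 1 / (1 / y_x_thio_x + 1 / y_x_thio_h2s)
  if (is.null(y_x_thio_total)) {
    y_x_thio_total <- reciprocal
  } else if (abs(y_x_thio_total / reciprocal - 1) > 0.05) {
    warning(sprintf(paste0(
      "supplied y_x_thio_total (%.4g) deviates from the reciprocal ",
      "combination of its components (%.4g) by %.1f%%"),
      y_x_thio_total, reciprocal,
      100 * abs(y_x_thio_total / reciprocal - 1)))
  }
  p$y_x_thio_total <- y_x_thio_total
  # stoichiometry of glucose fermentation: 2 H2 and 1 CO2 per acetate
  p$y_h2_glu_max <- 2 * y_act_glu_max
  p$y_co2_glu_max <- y_act_glu_max
  p$y_x_glu_mmol <- y_x_glu / 1000        # g biomass per mmol glucose
  p$carbon_closure <- 6 * (f_biomass_c + f_eps_c)
  structure(p, class = "model_parameters")
}

#' Modify a parameter set
#'
#' Rebuilds a [model_parameters()] object with some fields replaced, so the
#' derived stoichiometric identities stay consistent.
#'
#' @param p a [model_parameters()] object.
#' @param ... named replacements among the [model_parameters()] arguments.
#' @return a new `model_parameters` object.
#' @export
#' @examples
#' update_parameters(model_parameters(), n_inhib = 0.5)$n_inhib
update_parameters <- function(p, ...) {
  keep <- intersect(names(formals(model_parameters)), names(unclass(p)))
  args <- utils::modifyList(unclass(p)[keep], list(...))
  # the stored total thiosulfate yield is derived; re-derive it from the
  # (possibly updated) components unless the caller pins it explicitly
  if (!"y_x_thio_total" %in% names(list(...)))
    args$y_x_thio_total <- NULL
  unknown <- setdiff(names(list(...)), names(formals(model_parameters)))
  if (length(unknown))
    stop("unknown model parameter(s): ", paste(unknown, collapse = ", "))
  do.call(model_parameters, args)
}

#' Operating conditions of a batch run
#'
#' Initial concentrations, inoculum size, carrier-gas flow and reactor
#' geometry for one batch fermentation. Defaults are the reference validation
#' run: glucose 14 mmol/L, yeast extract 1 g/L, thiosulfate 0.12 mmol/L,
#' inoculum 31.6 mg/L, N2 sparging at 6 L/h (100 mL/min) in a 2-L reactor
#' with 1.5 L working volume.
#'
#' Inlet flow `q_n2` is the total inlet gas flow expressed as volumetric flow
#' at reactor temperature and headspace pressure; `y_h2_in` is the H2 mole
#' fraction of that inlet stream (0 for pure N2; used to reproduce
#' H2-enriched-sparging inhibition experiments).
#'
#' @param x0 inoculum biomass (g/L).
#' @param glu0 initial glucose (mmol/L).
#' @param yeast0 initial yeast extract (g/L).
#' @param thio0 initial thiosulfate (mmol/L).
#' @param q_n2 inlet gas flow (L/h at reactor T, P).
#' @param y_h2_in inlet H2 mole fraction in `[0, 1]`.
#' @param v_l liquid volume (L).
#' @param v_g headspace volume (L).
#' @param t_end simulation horizon (h).
#' @return An object of class `operating_conditions` (named list).
#' @export
#' @examples
#' oc <- operating_conditions(glu0 = 20, q_n2 = 0.3)
operating_conditions <- function(x0 = 0.0316, glu0 = 14, yeast0 = 1,
                                 thio0 = 0.12, q_n2 = 6, y_h2_in = 0,
                                 v_l = 1.5, v_g = 0.5, t_end = 30) {
  oc <- list(x0 = x0, glu0 = glu0, yeast0 = yeast0, thio0 = thio0,
             q_n2 = q_n2, y_h2_in = y_h2_in, v_l = v_l, v_g = v_g,
             t_end = t_end)
  for (nm in names(oc)) {
    if (!is.numeric(oc[[nm]]) || length(oc[[nm]]) != 1L || !is.finite(oc[[nm]]))
      stop("operating condition '", nm, "' must be a finite numeric scalar")
    if (oc[[nm]] < 0) stop("operating condition '", nm, "' must be non-negative")
  }
  if (v_l <= 0 || v_g <= 0) stop("'v_l' and 'v_g' must be > 0")
  if (y_h2_in > 1) stop("'y_h2_in' must lie in [0, 1]")
  if (t_end <= 0) stop("'t_end' must be > 0")
  structure(oc, class = "operating_conditions")
}

#' @export
print.physical_constants <- function(x, ...) {
  cat("Physical constants (", x$temp_c, " degC, pH ", x$ph, ", ",
      x$p_total, " Pa)\n", sep = "")
  cat(sprintf("  Henry (mol/L/Pa): H2 %.3g  CO2 %.3g  H2S %.3g\n",
              x$kh_h2, x$kh_co2, x$kh_h2s))
  cat(sprintf("  Dissociation (mol/kg): K1 %.3g  K2 %.3g\n", x$k1, x$k2))
  cat(sprintf("  Diffusivities (cm2/s): O2 %.3g  H2 %.3g  CO2 %.3g  H2S %.3g\n",
              x$d_o2, x$d_h2, x$d_co2, x$d_h2s))
  invisible(x)
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Growth/yield/inhibition parameters\n")
  cat(sprintf("  mu_max %.3g 1/h, mu_d %.3g 1/h, m_glu %.3g mmol/g/h\n",
              x$mu_max, x$mu_d, x$m_glu))
  cat(sprintf("  Yields: X/Glu %.3g g/mol, X/Yeast %.3g g/g, X/Thio %.3g g/mmol\n",
              x$y_x_glu, x$y_x_yeast, x$y_x_thio_total))
  cat(sprintf("  Ks: glu %.3g mmol/L, yeast %.3g g/L, thio %.3g mmol/L\n",
              x$ks_glu, x$ks_yeast, x$ks_thio))
  cat(sprintf("  Inhibition: H2crit %.3g mmol/L, N %.3g; Yact/glu max %.3g mol/mol\n",
              x$h2_crit, x$n_inhib, x$y_act_glu_max))
  invisible(x)
}

#' @export
print.operating_conditions <- function(x, ...) {
  cat(sprintf("Batch conditions: X0 %.4g g/L, Glu %.3g mmol/L, Yeast %.3g g/L, Thio %.3g mmol/L\n",
              x$x0, x$glu0, x$yeast0, x$thio0))
  cat(sprintf("  Q %.3g L/h (y_H2_in %.3g), Vl %.3g L, Vg %.3g L, horizon %.3g h\n",
              x$q_n2, x$y_h2_in, x$v_l, x$v_g, x$t_end))
  invisible(x)
}
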