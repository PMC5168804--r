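## Concentration windows over which the biomass yields were measured; the
## model is quantitatively reliable when the limiting substrate lies inside
## its window and overestimates productions (by roughly 30%) outside.
.validity_windows <- list(glucose = c(2.5, 20),      # mmol/L
                          yeast = c(0.2, 0.5),       # g/L
                          thiosulfate = c(0.01, 0.06)) # mmol/L

#' Limiting-factor classification and validity verdict
#'
#' Computes the attainable-biomass potential of each substrate (yield times
#' initial availability including yeast-extract equivalents, in mg/L) and
#' identifies the growth-limiting factor as the smallest. The run is inside
#' the model's validity domain when the limiting substrate's initial
#' concentration lies within the window over which its yield was measured.
#' Ties are broken in the order glucose, yeast, thiosulfate and flagged.
#'
#' @param oc an [operating_conditions()] object.
#' @param p a [model_parameters()] object.
#' @param windows validity windows; override of the built-in defaults.
#' @return list of class `validity_verdict`: `limiting_factor` ("glucose",
#'   "yeast" or "thiosulfate"), `potentials_mg` (named, mg/L),
#'   `in_validity_domain`, `tie` (logical) and `expected_bias_note` (non-empty
#'   when out of domain).
#' @export
#' @examples
#' limiting_factor(operating_conditions(), model_parameters())
limiting_factor <- function(oc, p, windows = .validity_windows) {
  pot <- c(
    glucose = p$y_x_glu_mmol * (oc$glu0 + p$eps1 * oc$yeast0) * 1000,
    yeast = p$y_x_yeast * oc$yeast0 * 1000,
    thiosulfate = p$y_x_thio_total * (oc$thio0 + p$eps2 * oc$yeast0) * 1000)
  order_pref <- c("glucose", "yeast", "thiosulfate")
  minimal <- names(pot)[pot <= min(pot) * (1 + 1e-12)]
  lim <- order_pref[order_pref %in% minimal][1]
  conc <- switch(lim, glucose = oc$glu0, yeast = oc$yeast0,
                 thiosulfate = oc$thio0)
  w <- windows[[lim]]
  in_domain <- conc >= w[1] && conc <= w[2]
  note <- if (!in_domain)
    sprintf(paste0("limiting substrate %s at %.3g is outside its calibrated ",
                   "window [%.3g, %.3g]; the model typically overestimates ",
                   "productions (about 30%%) out of domain"),
            lim, conc, w[1], w[2]) else ""
  structure(list(limiting_factor = lim, potentials_mg = pot,
                 in_validity_domain = in_domain,
                 tie = length(minimal) > 1,
                 expected_bias_note = note),
            class = "validity_verdict")
}

#' @export
print.validity_verdict <- function(x, ...) {
  cat(sprintf("Limiting factor: %s (potentials mg/L: glucose %.0f, yeast %.0f, thiosulfate %.0f)\n",
              x$limiting_factor, x$potentials_mg[["glucose"]],
              x$potentials_mg[["yeast"]], x$potentials_mg[["thiosulfate"]]))
  cat("  In validity domain:", x$in_validity_domain,
      if (x$tie) " [tie]" else "", "\n")
  if (nzchar(x$expected_bias_note)) cat("  ", x$expected_bias_note, "\n")
  invisible(x)
}

#' Compare simulated and observed batch endpoints
#'
#' Relative deviation `(model - observed)/observed` for the end-point totals
#' of acetate, lactate, H2 and CO2 and for the maximum biomass. When an
#' observed endpoint is zero, the absolute difference is reported instead and
#' flagged.
#'
#' @param model a `batch_sim` from [run_batch()].
#' @param observed a `batch_dataset` from [generate_batch()] or a list with
#'   an `observations` data frame holding `time`, `biomass`, `acetate`,
#'   `lactate`, `cum_h2`.
#' @return data frame with columns `endpoint`, `model`, `observed`,
#'   `deviation`, `absolute` (TRUE where the deviation is an absolute
#'   difference); attribute `mean_abs_deviation` summarises the relative
#'   rows.
#' @export
compare_runs <- function(model, observed) {
  obs <- observed$observations
  need <- c("biomass", "acetate", "lactate", "cum_h2")
  if (is.null(obs) || !all(need %in% names(obs)))
    stop("'observed' must carry observations with columns ",
         paste(need, collapse = ", "))
  v_l <- model$conditions$v_l
  n <- nrow(obs)
  tr <- model$trajectory
  nt <- nrow(tr)
  # H2 endpoint on the observable scale: emitted plus headspace inventory
  ep_model <- c(max_biomass = model$metrics$max_biomass,
                acetate = model$metrics$total_act,
                lactate = model$metrics$total_lact,
                h2 = tr$cumH2out[nt] + tr$H2g[nt] * model$conditions$v_g)
  ep_obs <- c(max_biomass = max(obs$biomass),
              acetate = obs$acetate[n] * v_l,
              lactate = obs$lactate[n] * v_l,
              h2 = obs$cum_h2[n])
  if ("offgas_co2_pct" %in% names(obs) || "cum_co2" %in% names(obs)) {
    if ("cum_co2" %in% names(obs)) {
      ep_model <- c(ep_model, co2 = model$metrics$total_co2)
      ep_obs <- c(ep_obs, co2 = obs$cum_co2[n])
    }
  }
  absolute <- ep_obs == 0
  deviation <- ifelse(absolute, ep_model - ep_obs,
                      (ep_model - ep_obs) / ep_obs)
  out <- data.frame(endpoint = names(ep_model), model = unname(ep_model),
                    observed = unname(ep_obs),
                    deviation = unname(deviation),
                    absolute = unname(absolute))
  attr(out, "mean_abs_deviation") <-
    mean(abs(out$deviation[!out$absolute]))
  out
}
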