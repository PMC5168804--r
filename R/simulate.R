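#' Integrate one batch fermentation
#'
#' Integrates the full ODE system from [initial_state()] over `[0, t_end]`
#' with a stiff-capable solver and computes the performance metrics used
#' throughout: maximum biomass and its time, maximum volumetric and specific
#' H2 productivity, overall H2 yield on consumed glucose-equivalents, maximal
#' dissolved-H2 inhibition ratio, and product totals.
#'
#' Transfer coefficients are either supplied per gas or derived from the
#' inlet flow through the O2 flow correlation and diffusivity scaling
#' ([kla_for_flow()]). Volumetric H2 productivity is the gross volumetric H2
#' production rate (mmol per L of liquid per h); the specific productivity
#' divides by the instantaneous biomass. The overall yield divides cumulative
#' gross H2 production by consumed glucose-equivalents; the net (gross minus
#' H2 re-consumed by thiosulfate reduction) is also reported.
#'
#' @param p a [model_parameters()] object.
#' @param cc a [physical_constants()] object.
#' @param oc an [operating_conditions()] object.
#' @param kla either `NULL` (derive from `oc$q_n2` via `corr`) or a named
#'   vector `c(h2=, co2=, h2s=)` in 1/h.
#' @param corr [kla_correlation()] used when `kla` is `NULL`.
#' @param k_ab acid-base interconversion rate constant (1/h).
#' @param rtol,atol solver relative/absolute tolerances.
#' @param dt output grid spacing (h); metrics are read off this grid, so keep
#'   it fine relative to the growth time scale.
#' @param allow_low_flow low inlet flows (< 0.3 L/h) put the reactor in a
#'   diffusion-dominated regime the transfer model does not cover; they are
#'   refused unless this is `TRUE`.
#' @return object of class `batch_sim`: list with `trajectory` (data frame of
#'   time, all states, and derived columns `mu`, `prod_h2_vol`,
#'   `prod_h2_spec`, `inhibition_ratio`, `offgas_h2_frac`,
#'   `offgas_co2_frac`), `metrics` (named list), and the inputs.
#' @export
#' @examples
#' sim <- run_batch(model_parameters(), physical_constants(),
#'                  operating_conditions(t_end = 15))
#' sim$metrics$max_biomass * 1000  # mg/L
run_batch <- function(p, cc, oc, kla = NULL, corr = kla_correlation(),
                      k_ab = 1000, rtol = 1e-8, atol = 1e-10, dt = 0.02,
                      allow_low_flow = FALSE) {
  if (oc$q_n2 < 0.3 && !allow_low_flow)
    stop("inlet flow below 0.3 L/h (5 mL/min): diffusion-dominated regime ",
         "outside the transfer model; set allow_low_flow = TRUE to force")
  if (is.null(kla)) kla <- kla_for_flow(max(oc$q_n2, 1e-6), cc, corr)
  if (!all(c("h2", "co2", "h2s") %in% names(kla)))
    stop("'kla' must have entries named h2, co2, h2s")

  y0 <- initial_state(p, cc, oc)
  times <- seq(0, oc$t_end, by = dt)
  sol <- deSolve::ode(y = y0, times = times,
                      func = function(t, y, parms)
                        fermentation_rhs(t, y, p, cc, oc, kla, k_ab),
                      parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol, maxsteps = 50000)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE integration failed at t = ", max(sol[, "time"]),
         " h; last state retained in the error condition")
  traj <- as.data.frame(sol)

  # derived per-time diagnostics (algebraic in the state, not differenced)
  a <- acetate_yield(pmax(traj$H2l, 0), p)
  gate <- pmax(traj$S1, 0) / (pmax(traj$S1, 0) + .maintenance_gate_k)
  q_glu <- traj$mu / p$y_x_glu_mmol + p$m_glu * gate
  traj$prod_h2_vol <- 2 * a * q_glu * pmax(traj$X, 0)
  traj$prod_h2_spec <- 2 * a * q_glu
  traj$inhibition_ratio <- pmax(traj$H2l, 0) / p$h2_crit
  gas_total <- cc$gas_molar_density
  traj$offgas_h2_frac <- pmax(traj$H2g, 0) / gas_total
  traj$offgas_co2_frac <- pmax(traj$CO2g, 0) / gas_total

  n <- nrow(traj)
  glu_consumed <- traj$cumGluCons[n]
  yield <- if (glu_consumed > 0) traj$cumH2prod[n] / glu_consumed else NA_real_
  yield_net <- if (glu_consumed > 0)
    (traj$cumH2prod[n] - traj$cumH2cons[n]) / glu_consumed else NA_real_
  i_xmax <- which.max(traj$X)
  metrics <- list(
    max_biomass = traj$X[i_xmax],                      # g/L
    t_max_biomass = traj$time[i_xmax],                 # h
    max_prod_h2_vol = max(traj$prod_h2_vol),           # mmol/L/h
    max_prod_h2_spec = max(traj$prod_h2_spec),         # mmol/g/h
    yield_h2_glu = yield,                              # mol/mol (gross)
    yield_h2_glu_net = yield_net,                      # mol/mol (net)
    max_inhibition_ratio = max(traj$inhibition_ratio), # [0, 1]
    glu_consumed = glu_consumed,                       # mmol/L
    total_act = traj$Act[n] * oc$v_l,                  # mmol
    total_lact = traj$Lact[n] * oc$v_l,
    total_h2 = traj$cumH2out[n] + traj$H2g[n] * oc$v_g +
      traj$H2l[n] * oc$v_l,
    total_co2 = traj$cumCO2out[n] + traj$CO2g[n] * oc$v_g +
      (traj$CO2l[n] + traj$HCO3[n]) * oc$v_l,
    total_h2s = traj$cumH2Sout[n] + traj$H2Sg[n] * oc$v_g +
      (traj$H2Sl[n] + traj$HS[n]) * oc$v_l
  )
  structure(list(trajectory = traj, metrics = metrics,
                 parameters = p, constants = cc, conditions = oc,
                 kla = kla, k_ab = k_ab,
                 solver = list(rtol = rtol, atol = atol, dt = dt)),
            class = "batch_sim")
}

#' @export
print.batch_sim <- function(x, ...) {
  m <- x$metrics
  cat("Batch fermentation simulation (", x$conditions$t_end, " h)\n", sep = "")
  cat(sprintf("  Xmax %.1f mg/L at %.2f h; H2 productivity max %.2f mmol/L/h (%.1f mmol/g/h)\n",
              1000 * m$max_biomass, m$t_max_biomass,
              m$max_prod_h2_vol, m$max_prod_h2_spec))
  cat(sprintf("  H2 yield %.2f mol/mol glucose (net %.2f); peak [H2]/[H2crit] %.1f%%\n",
              m$yield_h2_glu, m$yield_h2_glu_net,
              100 * m$max_inhibition_ratio))
  invisible(x)
}

#' Condition grid for the stripping-rate prediction sweep
#'
#' Builds the prediction grid crossing inlet N2 flows 5, 10, 20 and 100
#' mL/min (0.3-6 L/h) with the three in-domain substrate series: yeast
#' extract 0.1/0.25/0.5 g/L (glucose 50 mmol/L, thiosulfate 0.12 mmol/L),
#' thiosulfate 0/0.03/0.06 mmol/L (glucose 50 mmol/L, yeast 1 g/L), and
#' glucose 0/5/10/20 mmol/L (thiosulfate 0.12 mmol/L, yeast 1 g/L). In every
#' series the varied substrate is the growth-limiting factor. Inoculum
#' 31.6 mg/L throughout.
#'
#' @param q_n2 inlet flows (L/h) crossed with each series.
#' @return data frame with columns `series`, `glu0`, `yeast0`, `thio0`,
#'   `q_n2`, `x0`.
#' @export
prediction_grid <- function(q_n2 = c(0.3, 0.6, 1.2, 6)) {
  series <- rbind(
    data.frame(series = "yeast", glu0 = 50, yeast0 = c(0.1, 0.25, 0.5),
               thio0 = 0.12),
    data.frame(series = "thiosulfate", glu0 = 50, yeast0 = 1,
               thio0 = c(0, 0.03, 0.06)),
    data.frame(series = "glucose", glu0 = c(0, 5, 10, 20), yeast0 = 1,
               thio0 = 0.12))
  grid <- merge(series, data.frame(q_n2 = q_n2))
  grid$x0 <- 0.0316
  grid[order(grid$series, grid$q_n2, grid$glu0, grid$yeast0, grid$thio0), ,
       drop = FALSE]
}

#' Run a condition sweep
#'
#' Simulates one batch per grid row and collects the metrics, the
#' limiting-factor verdict and any per-row failure (flagged, not fatal).
#'
#' @param grid data frame with any of the columns `glu0`, `yeast0`, `thio0`,
#'   `q_n2`, `x0`, `y_h2_in`, `t_end` overriding `base`; e.g.
#'   [prediction_grid()].
#' @param p,cc parameter and constant objects.
#' @param base an [operating_conditions()] object supplying unvaried fields.
#' @param ... passed to [run_batch()].
#' @return data frame: the grid columns plus `limiting_factor`,
#'   `max_biomass_mg` (mg/L), `max_prod_h2_vol`, `max_prod_h2_spec`,
#'   `yield_h2_glu`, `max_inhibition_pct` (%), and `failed` (logical with the
#'   message in attribute `failures`).
#' @export
#' @examples
#' grid <- prediction_grid(q_n2 = 6)[1:2, ]
#' run_sweep(grid, model_parameters(), physical_constants())
run_sweep <- function(grid, p, cc, base = operating_conditions(), ...) {
  if (nrow(grid) == 0) stop("'grid' is empty")
  override <- intersect(names(grid),
                        c("glu0", "yeast0", "thio0", "q_n2", "x0",
                          "y_h2_in", "t_end"))
  out <- grid
  out$limiting_factor <- NA_character_
  out$max_biomass_mg <- NA_real_
  out$max_prod_h2_vol <- NA_real_
  out$max_prod_h2_spec <- NA_real_
  out$yield_h2_glu <- NA_real_
  out$max_inhibition_pct <- NA_real_
  out$failed <- FALSE
  failures <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    oc_args <- unclass(base)
    for (nm in override) oc_args[[nm]] <- grid[[nm]][i]
    oc <- do.call(operating_conditions, oc_args)
    res <- tryCatch(run_batch(p, cc, oc, ...), error = function(e) e)
    if (inherits(res, "error")) {
      out$failed[i] <- TRUE
      failures[i] <- conditionMessage(res)
      next
    }
    out$limiting_factor[i] <- limiting_factor(oc, p)$limiting_factor
    out$max_biomass_mg[i] <- 1000 * res$metrics$max_biomass
    out$max_prod_h2_vol[i] <- res$metrics$max_prod_h2_vol
    out$max_prod_h2_spec[i] <- res$metrics$max_prod_h2_spec
    out$yield_h2_glu[i] <- res$metrics$yield_h2_glu
    out$max_inhibition_pct[i] <- 100 * res$metrics$max_inhibition_ratio
  }
  attr(out, "failures") <- failures
  rownames(out) <- NULL
  out
}
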