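#' Linear biomass-yield regression on a limiting substrate
#'
#' Ordinary least squares of maximum biomass (mg/L) against initial
#' concentration of the limiting substrate. The slope is the total biomass
#' yield (growth + maintenance confounded); the intercept, biomass formed at
#' zero added substrate, is retained for the yeast-extract equivalence
#' extrapolation ([equivalence_from_intercept()]). Points outside the
#' substrate's limiting window are accepted but flag the fit, since there the
#' response saturates and the line underestimates the yield.
#'
#' @param conc substrate concentrations (mmol/L for glucose and thiosulfate,
#'   g/L for yeast extract), at least 3 distinct values.
#' @param xmax_mg observed maximum biomass (mg/L).
#' @param substrate `"glucose"`, `"yeast"` or `"thiosulfate"`.
#' @param limiting_range optional `c(min, max)` limiting window used for the
#'   range flag; defaults to the built-in validity windows (upper end only —
#'   the regression itself legitimately extends to zero substrate).
#' @return object of class `yield_regression`: `slope` and `intercept` in
#'   regression units (mg/L per concentration unit), `yield` converted to the
#'   substrate's customary unit (g/mol glucose, g/g yeast, g/mmol
#'   thiosulfate), `r2`, `se_slope`, `substrate`, `out_of_range` flag.
#' @export
#' @examples
#' conc <- c(2.5, 5, 10, 14, 20)
#' fit_yield(conc, 20.4 * conc + 11.4, "glucose")$yield  # 20.4 g/mol
fit_yield <- function(conc, xmax_mg,
                      substrate = c("glucose", "yeast", "thiosulfate"),
                      limiting_range = NULL) {
  substrate <- match.arg(substrate)
  if (length(conc) != length(xmax_mg)) stop("lengths of inputs differ")
  if (length(unique(conc)) < 3)
    stop("need at least 3 distinct substrate concentrations")
  if (is.null(limiting_range))
    limiting_range <- c(0, .validity_windows[[substrate]][2])
  out_of_range <- any(conc < limiting_range[1] | conc > limiting_range[2])
  if (out_of_range)
    warning("some points lie outside the limiting range for ", substrate,
            "; the linear yield regression may be biased by saturation")
  fit <- stats::lm(xmax_mg ~ conc)
  slope <- stats::coef(fit)[["conc"]]
  if (slope <= 0)
    warning("non-positive fitted slope: no biomass response to ", substrate)
  yield <- switch(substrate,
                  glucose = slope,          # mg/L per mmol/L = g/mol
                  yeast = slope / 1000,     # mg/L per g/L -> g/g
                  thiosulfate = slope / 1000) # g/mol -> g/mmol
  sm <- suppressWarnings(summary(fit))  # exact lines trip lm's R2 warning
  structure(list(slope = slope,
                 intercept = stats::coef(fit)[[1]],
                 yield = yield, r2 = sm$r.squared,
                 se_slope = sm$coefficients["conc", "Std. Error"],
                 substrate = substrate, out_of_range = out_of_range),
            class = "yield_regression")
}

#' @export
print.yield_regression <- function(x, ...) {
  cat(sprintf("Yield regression on %s: Xmax = %.4g * conc + %.4g (R2 %.4f)%s\n",
              x$substrate, x$slope, x$intercept, x$r2,
              if (x$out_of_range) " [points beyond limiting range]" else ""))
  unit <- switch(x$substrate, glucose = "g/mol", yeast = "g/g",
                 thiosulfate = "g/mmol")
  cat(sprintf("  total biomass yield: %.4g %s\n", x$yield, unit))
  invisible(x)
}

#' Yeast-extract substrate equivalence from a regression intercept
#'
#' The intercept of a yield regression is the biomass formed with no added
#' substrate, attributable to the equivalent content of that substrate in the
#' yeast extract present. Extrapolating the line to zero biomass gives the
#' equivalent concentration `intercept/slope`, and dividing by the
#' yeast-extract concentration of the campaign gives the equivalence per gram.
#'
#' @param reg a [fit_yield()] result with positive slope.
#' @param yeast_conc yeast-extract concentration of the campaign (g/L), > 0.
#' @return substrate equivalent per g yeast extract (mmol/g for
#'   glucose/thiosulfate regressions).
#' @export
#' @examples
#' reg <- fit_yield(c(2.5, 5, 10, 20), 20.4 * c(2.5, 5, 10, 20) + 11.4)
#' equivalence_from_intercept(reg, 1)  # 0.56 mmol/g
equivalence_from_intercept <- function(reg, yeast_conc) {
  if (reg$slope <= 0) stop("regression slope must be positive")
  if (yeast_conc <= 0) stop("'yeast_conc' must be > 0")
  (reg$intercept / reg$slope) / yeast_conc
}

#' Apparent half-saturation constant from growth-rate observations
#'
#' Nonlinear least squares of the single-substrate Monod law
#' `mu = mu_max * S / (S + Ks)`. Batch-derived estimates conflate transport
#' and history effects and are apparent constants (Ks,app), typically larger
#' than intrinsic ones. `mu_max` is either fixed (known from excess-substrate
#' runs) or co-estimated.
#'
#' @param s substrate concentrations, at least 4 points spanning the
#'   half-saturation region.
#' @param mu observed specific growth rates (1/h).
#' @param mu_max maximum specific growth rate (1/h).
#' @param co_estimate_mu_max if `TRUE`, `mu_max` is refined jointly with Ks.
#' @return list of class `ks_fit`: `ks`, `se`, 95% `ci`, `mu_max`,
#'   `residual_sd`.
#' @export
#' @examples
#' s <- c(1, 3, 6, 12, 30, 60)
#' fit_apparent_ks(s, 0.9 * s / (s + 5.7), mu_max = 0.9)$ks  # 5.7
fit_apparent_ks <- function(s, mu, mu_max, co_estimate_mu_max = FALSE) {
  if (length(s) != length(mu)) stop("lengths of 's' and 'mu' differ")
  if (length(s) < 4) stop("need at least 4 observations")
  if (any(s < 0) || any(mu < 0)) stop("'s' and 'mu' must be non-negative")
  # identifiability needs curvature: points clearly below saturation
  if (all(mu > 0.9 * mu_max))
    stop("non-identifiable: all growth rates within 10% of mu_max, ",
         "no curvature in the Monod response")
  df <- data.frame(s = s, mu = mu)
  fit <- if (co_estimate_mu_max)
    minpack.lm::nlsLM(mu ~ mumax * s / (s + ks), data = df,
                      start = list(mumax = mu_max, ks = stats::median(s)),
                      lower = c(0, 0))
  else
    minpack.lm::nlsLM(mu ~ mu_max * s / (s + ks), data = df,
                      start = list(ks = stats::median(s)), lower = 0)
  sm <- summary(fit)
  ks <- sm$coefficients["ks", "Estimate"]
  se <- sm$coefficients["ks", "Std. Error"]
  if (!is.finite(se) || se > 5 * max(ks, 1e-12))
    stop("non-identifiable: Ks standard error exceeds the estimate ",
         "several-fold (flat response)")
  structure(list(ks = ks, se = se, ci = ks + c(-1.96, 1.96) * se,
                 mu_max = if (co_estimate_mu_max)
                   sm$coefficients["mumax", "Estimate"] else mu_max,
                 residual_sd = sm$sigma),
            class = "ks_fit")
}

#' @export
print.ks_fit <- function(x, ...) {
  cat(sprintf("Apparent Ks: %.4g (se %.2g, 95%% CI %.3g-%.3g), mu_max %.3g 1/h\n",
              x$ks, x$se, x$ci[1], x$ci[2], x$mu_max))
  invisible(x)
}

#' Critical dissolved-H2 concentration by linear extrapolation
#'
#' Fits straight lines to the acetate yield and to the relative growth rate
#' against the inlet H2 percentage, extrapolates each to zero response to
#' obtain a critical headspace H2 percentage, and converts it to a dissolved
#' concentration with Henry's law at the total headspace pressure
#' (`Kh2 * (pct/100) * P_total`). At zero inhibition (extrapolated 0%
#' intercept of the yield line) the acetate yield equals its maximum. When
#' the two responses disagree, the growth-rate-based value is the
#' recommended critical concentration.
#'
#' @param tbl data frame with columns `pct_h2` (inlet H2 %, must include 0),
#'   `y_act` (mol/mol) and `mu_ratio`; at least 3 percentages.
#' @param cc a [physical_constants()] object.
#' @return object of class `inhibition_fit`: per response (`y_act`,
#'   `mu_ratio`) the OLS `slope`, `intercept`, zero-crossing `critical_pct`
#'   and `critical_mmol` (mmol/L); plus `y_act_max` (yield-line intercept)
#'   and `h2_crit` (the growth-based dissolved critical concentration).
#' @export
estimate_h2crit <- function(tbl, cc) {
  need <- c("pct_h2", "y_act", "mu_ratio")
  if (!all(need %in% names(tbl)))
    stop("'tbl' must have columns ", paste(need, collapse = ", "))
  if (length(unique(tbl$pct_h2)) < 3)
    stop("need at least 3 distinct inlet percentages")
  if (!any(tbl$pct_h2 == 0))
    stop("the inlet-percentage grid must include 0 (uninhibited reference)")
  one <- function(y, label) {
    fit <- stats::lm(y ~ pct_h2, data = tbl)
    slope <- stats::coef(fit)[["pct_h2"]]
    intercept <- stats::coef(fit)[[1]]
    if (slope >= 0)
      stop("no inhibition trend in ", label,
           ": fitted slope against inlet H2 is non-negative")
    pct <- -intercept / slope
    list(slope = slope, intercept = intercept, critical_pct = pct,
         critical_mmol = 1000 * cc$kh_h2 * (pct / 100) * cc$p_total,
         r2 = suppressWarnings(summary(fit))$r.squared)
  }
  ya <- one(tbl$y_act, "acetate yield")
  mr <- one(tbl$mu_ratio, "relative growth rate")
  structure(list(y_act = ya, mu_ratio = mr,
                 y_act_max = ya$intercept,
                 h2_crit = mr$critical_mmol),
            class = "inhibition_fit")
}

#' @export
print.inhibition_fit <- function(x, ...) {
  cat("Critical dissolved-H2 extrapolation\n")
  cat(sprintf("  acetate yield: crossing %.3g%% -> %.3g mmol/L (Yact max %.3g mol/mol)\n",
              x$y_act$critical_pct, x$y_act$critical_mmol, x$y_act_max))
  cat(sprintf("  growth rate:   crossing %.3g%% -> %.3g mmol/L (recommended H2crit)\n",
              x$mu_ratio$critical_pct, x$h2_crit))
  invisible(x)
}

## Maximum volumetric H2 productivity as a campaign would measure it: the
## steepest rise of cumulative emitted H2 per liquid volume, estimated by a
## sliding local-linear slope (window of 5 samples) so that sampling noise on
## the cumulative signal does not inflate the maximum.
observed_max_productivity <- function(time, cum_h2, v_l, window = 5L) {
  n <- length(time)
  if (n < 3) stop("need at least 3 time points")
  window <- min(window, n)
  half <- (window - 1L) %/% 2L
  slopes <- vapply(seq_len(n), function(i) {
    idx <- max(1L, i - half):min(n, i + half)
    if (length(idx) < 2) return(NA_real_)
    stats::cov(time[idx], cum_h2[idx]) / stats::var(time[idx])
  }, numeric(1))
  max(slopes, na.rm = TRUE) / v_l
}

#' Select the inhibition exponent against observed maximal productivities
#'
#' For each candidate exponent N, simulates every experiment's conditions and
#' compares the model's maximal volumetric H2 productivity with the observed
#' one, both measured identically from the rise of cumulative emitted H2.
#' The candidate minimising the absolute mean signed error is selected.
#' A low N strengthens inhibition below the critical concentration (the
#' factor `1-(H2/H2crit)^N` falls faster), so candidates below the true value
#' underpredict productivity and those above overpredict it.
#'
#' @param candidates positive exponents to score.
#' @param experiments list of `batch_dataset` objects (observed or
#'   synthetic), each carrying `conditions` and observations with `time` and
#'   `cum_h2`.
#' @param p,cc parameter and constant objects (`n_inhib` in `p` is replaced
#'   per candidate).
#' @param ... passed to [run_batch()].
#' @return list of class `n_selection`: `n` (chosen exponent), `errors`
#'   (named mean signed errors, mmol/L/h, model minus observed) and
#'   `per_experiment` matrix.
#' @export
select_n <- function(candidates, experiments, p, cc, ...) {
  if (length(experiments) == 0) stop("'experiments' is empty")
  if (any(candidates <= 0)) stop("'candidates' must be > 0")
  per <- matrix(NA_real_, nrow = length(candidates),
                ncol = length(experiments),
                dimnames = list(as.character(candidates), NULL))
  for (j in seq_along(experiments)) {
    ex <- experiments[[j]]
    obs <- observed_max_productivity(ex$observations$time,
                                     ex$observations$cum_h2,
                                     ex$conditions$v_l)
    for (i in seq_along(candidates)) {
      p_i <- update_parameters(p, n_inhib = candidates[i])
      sim <- run_batch(p_i, cc, ex$conditions, ...)
      tr <- sim$trajectory
      cum <- stats::approx(tr$time, tr$cumH2out + tr$H2g * ex$conditions$v_g,
                           xout = ex$observations$time)$y
      mod <- observed_max_productivity(ex$observations$time, cum,
                                       ex$conditions$v_l)
      per[i, j] <- mod - obs
    }
  }
  errors <- rowMeans(per)
  structure(list(n = candidates[which.min(abs(errors))],
                 errors = errors, per_experiment = per),
            class = "n_selection")
}

#' @export
print.n_selection <- function(x, ...) {
  cat("Inhibition-exponent selection (mean model - observed max productivity, mmol/L/h)\n")
  for (nm in names(x$errors))
    cat(sprintf("  N = %-4s  %+0.3f%s\n", nm, x$errors[[nm]],
                if (as.numeric(nm) == x$n) "  <- selected" else ""))
  invisible(x)
}
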