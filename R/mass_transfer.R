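#' Flow-rate correlation for the O2 volumetric mass-transfer coefficient
#'
#' Power-law correlation `KlaO2 = A * Q^n` between the O2 volumetric
#' mass-transfer coefficient and the gas flow rate at fixed stirring.
#' The default `(A, n) = (18.11, 0.721)` (Q in L/h, Kla in 1/h) was measured
#' in the reference 2-L reactor at 350 rpm over 20-500 mL/min.
#'
#' @param coefficient pre-factor A (1/h per (L/h)^exponent).
#' @param exponent dimensionless power n.
#' @return object of class `kla_correlation`.
#' @export
kla_correlation <- function(coefficient = 18.11, exponent = 0.721) {
  if (coefficient <= 0 || exponent <= 0)
    stop("'coefficient' and 'exponent' must be > 0")
  structure(list(coefficient = coefficient, exponent = exponent,
                 flow_units = "L/h"),
            class = "kla_correlation")
}

#' Evaluate a Kla flow correlation
#'
#' @param corr a [kla_correlation()] object.
#' @param q gas flow rate (L/h); vectorised.
#' @return KlaO2 (1/h).
#' @export
#' @examples
#' predict_kla(kla_correlation(), 6)  # ~66 1/h at 100 mL/min
predict_kla <- function(corr, q) {
  if (any(q <= 0)) stop("'q' must be > 0")
  corr$coefficient * q^corr$exponent
}

#' Scale an O2 Kla to another sparingly soluble gas
#'
#' Film theory for sparingly soluble gases: transfer coefficients scale with
#' the square root of aqueous diffusivity, `KlaG = KlaO2 * sqrt(DG / DO2)`.
#'
#' @param klao2 O2 volumetric mass-transfer coefficient (1/h), > 0.
#' @param species one of `"h2"`, `"co2"`, `"h2s"`.
#' @param cc a [physical_constants()] object (diffusivities at 80 degC).
#' @return species Kla (1/h).
#' @export
#' @examples
#' cc <- physical_constants()
#' scale_kla(predict_kla(kla_correlation(), 6), "h2", cc)  # ~114 1/h
scale_kla <- function(klao2, species = c("h2", "co2", "h2s"), cc) {
  species <- match.arg(species)
  if (any(klao2 <= 0)) stop("'klao2' must be > 0")
  d <- switch(species, h2 = cc$d_h2, co2 = cc$d_co2, h2s = cc$d_h2s)
  klao2 * sqrt(d / cc$d_o2)
}

#' Per-gas transfer coefficients at a given gas flow
#'
#' Convenience wrapper: evaluates the O2 flow correlation at `q` and scales to
#' H2, CO2 and H2S by diffusivity.
#'
#' @inheritParams predict_kla
#' @param cc a [physical_constants()] object.
#' @param corr a [kla_correlation()] object.
#' @return named numeric vector `c(h2 =, co2 =, h2s =)` in 1/h.
#' @export
kla_for_flow <- function(q, cc, corr = kla_correlation()) {
  klao2 <- predict_kla(corr, q)
  c(h2 = scale_kla(klao2, "h2", cc),
    co2 = scale_kla(klao2, "co2", cc),
    h2s = scale_kla(klao2, "h2s", cc))
}

#' Dynamic gassing-out estimate of KlaO2 from a dissolved-O2 curve
#'
#' Fits the first-order transfer response of a dynamic absorption or
#' desorption run. With `C` the dissolved O2 as fraction of saturation,
#' absorption follows `C(t) = 1 - (1 - C0) exp(-Kla t)` and desorption
#' `C(t) = C0 exp(-Kla t)`, so the driving-force deficit `|C* - C|` decays
#' log-linearly in time with slope `-Kla`. The rate is estimated by
#' nonlinear least squares on the original concentration scale (where probe
#' noise is homoscedastic; a log-scale regression would let the noisy
#' near-saturation tail dominate), initialised from the deficit-weighted
#' log-linear slope; on noiseless data the two coincide exactly. Points
#' outside (2%, 98%) of the driving-force range are discarded (probe
#' floor/ceiling).
#'
#' @param curve a data frame with columns `time` (h, strictly increasing) and
#'   `do` (fraction of saturation), or a [generate_do_curve()] result.
#' @param direction `"absorption"` or `"desorption"`; taken from the curve
#'   object when present.
#' @return list of class `kla_fit` with `klao2` (1/h), `se` (standard error),
#'   `r2` (on the concentration scale) and `n_used`.
#' @export
#' @examples
#' curve <- generate_do_curve(50, n = 30)
#' fit_kla_from_do(curve)$klao2  # 50
fit_kla_from_do <- function(curve, direction = NULL) {
  if (is.null(direction)) direction <- attr(curve, "direction")
  if (is.null(direction)) direction <- "absorption"
  direction <- match.arg(direction, c("absorption", "desorption"))
  if (!all(c("time", "do") %in% names(curve)))
    stop("'curve' must have columns 'time' and 'do'")
  if (any(diff(curve$time) <= 0)) stop("'time' must be strictly increasing")
  deficit <- if (direction == "absorption") 1 - curve$do else curve$do
  keep <- deficit > 0.02 & deficit < 0.98
  if (sum(keep) < 5)
    stop("need at least 5 points strictly between 2% and 98% of the ",
         "driving-force range")
  tt <- curve$time[keep]
  dd <- deficit[keep]
  # deficit-weighted log-linear slope initialises the nonlinear fit
  init <- stats::lm(log(dd) ~ tt, weights = dd^2)
  slope <- stats::coef(init)[["tt"]]
  if (slope >= 0)
    stop("curve does not approach saturation: decay rate is non-negative ",
         "(non-monotone curve or wrong 'direction'?)")
  df <- data.frame(tt = tt, dd = dd)
  fit <- minpack.lm::nlsLM(dd ~ d0 * exp(-k * tt), data = df,
                           start = list(d0 = max(dd), k = -slope),
                           lower = c(0, 0))
  sm <- summary(fit)
  k <- sm$coefficients["k", "Estimate"]
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((dd - mean(dd))^2)
  if (r2 < 0.9)
    stop(sprintf(paste0("poor first-order fit (R2 = %.3f): curve is not a ",
                        "clean transfer response"), r2))
  structure(list(klao2 = k, se = sm$coefficients["k", "Std. Error"],
                 r2 = r2, n_used = sum(keep)),
            class = "kla_fit")
}

#' Fit the Kla flow correlation from (flow, Kla) pairs
#'
#' Least-squares fit of `log(Kla) = log(A) + n log(Q)` over measured pairs.
#'
#' @param flow gas flow rates (L/h), at least 3 distinct values in (0, 30].
#' @param klao2 measured KlaO2 values (1/h), same length.
#' @return a [kla_correlation()] object with attributes `r2` and `se_exponent`.
#' @export
#' @examples
#' q <- c(1.2, 6, 18)
#' fit_kla_flow_correlation(q, 18.11 * q^0.721)
fit_kla_flow_correlation <- function(flow, klao2) {
  if (length(flow) != length(klao2)) stop("'flow' and 'klao2' lengths differ")
  if (any(flow <= 0) || any(flow > 30))
    stop("'flow' must lie in (0, 30] L/h")
  if (any(klao2 <= 0)) stop("'klao2' must be > 0")
  if (length(unique(flow)) < 3)
    stop("need at least 3 distinct flow rates to identify the power law")
  fit <- stats::lm(log(klao2) ~ log(flow))
  out <- kla_correlation(coefficient = exp(stats::coef(fit)[[1]]),
                         exponent = stats::coef(fit)[[2]])
  sm <- suppressWarnings(summary(fit))  # exact fits trip lm's R2 warning
  attr(out, "r2") <- sm$r.squared
  attr(out, "se_exponent") <- sm$coefficients[2, "Std. Error"]
  out
}

#' @export
print.kla_correlation <- function(x, ...) {
  cat(sprintf("Kla flow correlation: KlaO2 = %.4g * Q^%.4g  (Q in %s, Kla in 1/h)\n",
              x$coefficient, x$exponent, x$flow_units))
  invisible(x)
}

#' @export
print.kla_fit <- function(x, ...) {
  cat(sprintf("Gassing-out fit: KlaO2 = %.4g 1/h (se %.2g, R2 %.4f, n = %d)\n",
              x$klao2, x$se, x$r2, x$n_used))
  invisible(x)
}
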