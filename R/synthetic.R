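## Evaluate an expression under a fixed RNG seed, restoring the caller's RNG
## state afterwards, so generators are pure functions of (config, seed).
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Noise specification for synthetic observations
#'
#' Measurement-noise model applied by the generators: multiplicative Gaussian
#' noise on concentration-like observables (biomass, solutes, cumulative H2)
#' and additive Gaussian noise on off-gas mole fractions, both truncated at
#' zero. Defaults emulate the scatter of replicate batch fermentations
#' (about 5% on concentrations, 1 percentage point on off-gas).
#'
#' @param conc_cv multiplicative noise coefficient of variation on
#'   concentration observables (fraction; 0 disables).
#' @param gas_sd additive noise on off-gas mole fractions (fraction units).
#' @param cum_cv multiplicative noise on the cumulative emitted-gas signal;
#'   online off-gas integration is more precise than per-sample solute
#'   assays, hence the smaller default.
#' @param times sampling times (h), strictly increasing.
#' @param seed integer RNG seed; a fixed seed gives bit-reproducible output.
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(conc_cv = 0.05, gas_sd = 0.01, cum_cv = 0.01,
                       times = seq(0, 15, by = 0.5), seed = 1L) {
  if (conc_cv < 0 || gas_sd < 0 || cum_cv < 0)
    stop("noise scales must be non-negative")
  if (length(times) < 2 || any(diff(times) <= 0))
    stop("'times' must be strictly increasing with at least 2 points")
  structure(list(conc_cv = conc_cv, gas_sd = gas_sd, cum_cv = cum_cv,
                 times = times, seed = seed), class = "noise_spec")
}

perturb_mult <- function(x, cv) {
  if (cv == 0) return(x)
  pmax(0, x * (1 + stats::rnorm(length(x), 0, cv)))
}

perturb_add <- function(x, sd) {
  if (sd == 0) return(x)
  pmax(0, x + stats::rnorm(length(x), 0, sd))
}

#' Generate a noisy synthetic batch fermentation dataset
#'
#' Simulates a batch with [run_batch()], samples the observables a wet-lab
#' campaign would record (biomass, glucose-equivalent pool, acetate, lactate,
#' off-gas H2 and CO2 percentages, cumulative H2 emitted) on the noise
#' specification's time grid and applies its noise model. The generating
#' parameters are stored alongside for recovery scoring.
#'
#' @param p,cc,oc parameter/constant/condition objects.
#' @param noise a [noise_spec()].
#' @param ... passed to [run_batch()].
#' @return object of class `batch_dataset`: list with `observations` (data
#'   frame: `time`, `biomass` g/L, `glucose` mmol/L glucose-equivalents,
#'   `acetate`, `lactate` mmol/L, `offgas_h2_pct`, `offgas_co2_pct`,
#'   `cum_h2` mmol emitted + headspace), `conditions`, `truth` (the
#'   generating [model_parameters()]) and `noise`.
#' @export
#' @examples
#' ds <- generate_batch(model_parameters(), physical_constants(),
#'                      operating_conditions(t_end = 12),
#'                      noise_spec(times = seq(0, 12, 1), seed = 7))
#' head(ds$observations)
generate_batch <- function(p, cc, oc, noise = noise_spec(), ...) {
  if (max(noise$times) > oc$t_end)
    stop("noise sampling times extend beyond the simulation horizon")
  sim <- run_batch(p, cc, oc, ...)
  tr <- sim$trajectory
  at <- function(col) stats::approx(tr$time, tr[[col]], xout = noise$times)$y
  obs <- data.frame(
    time = noise$times,
    biomass = at("X"),
    glucose = at("S1"),
    acetate = at("Act"),
    lactate = at("Lact"),
    offgas_h2_pct = 100 * at("offgas_h2_frac"),
    offgas_co2_pct = 100 * at("offgas_co2_frac"),
    cum_h2 = at("cumH2out") + at("H2g") * oc$v_g)
  obs <- with_seed_(noise$seed, {
    for (col in c("biomass", "glucose", "acetate", "lactate"))
      obs[[col]] <- perturb_mult(obs[[col]], noise$conc_cv)
    obs$cum_h2 <- perturb_mult(obs$cum_h2, noise$cum_cv)
    for (col in c("offgas_h2_pct", "offgas_co2_pct"))
      obs[[col]] <- perturb_add(obs[[col]], 100 * noise$gas_sd)
    obs
  })
  structure(list(observations = obs, conditions = oc, truth = p,
                 noise = noise, sim = sim),
            class = "batch_dataset")
}

#' @export
print.batch_dataset <- function(x, ...) {
  cat(sprintf("Synthetic batch dataset: %d time points over %.3g h (seed %s, cv %.3g)\n",
              nrow(x$observations), max(x$observations$time),
              format(x$noise$seed), x$noise$conc_cv))
  invisible(x)
}

#' Generate a maximum-biomass versus substrate-concentration table
#'
#' Emulates the yield-determination campaigns: one batch per substrate
#' concentration, all other substrates held at the historical complements
#' (glucose series: yeast 1 g/L, thiosulfate 0.12 mmol/L; yeast series:
#' glucose 60 mmol/L, thiosulfate 0.12 mmol/L; thiosulfate series: glucose
#' 60 mmol/L, yeast 4 g/L), recording the maximum biomass reached. Within the
#' substrate-limited window the noiseless table is linear in the substrate
#' with slope equal to the total biomass yield.
#'
#' @param substrate `"glucose"`, `"yeast"` or `"thiosulfate"`.
#' @param grid substrate concentrations (mmol/L for glucose/thiosulfate, g/L
#'   for yeast); non-empty.
#' @param p,cc parameter and constant objects.
#' @param noise a [noise_spec()] (only `conc_cv` and `seed` are used).
#' @param q_n2 stripping rate for the simulated campaigns (L/h).
#' @param t_end horizon per batch (h).
#' @param ... passed to [run_batch()].
#' @return data frame with columns `conc` and `xmax_mg`: net maximum biomass
#'   produced above the inoculum (mg/L), the quantity the historical
#'   regressions were fitted to.
#' @export
generate_yield_table <- function(substrate = c("glucose", "yeast",
                                               "thiosulfate"),
                                 grid, p, cc, noise = noise_spec(),
                                 q_n2 = 6, t_end = 40, ...) {
  substrate <- match.arg(substrate)
  if (length(grid) == 0) stop("'grid' is empty")
  if (any(grid < 0)) stop("'grid' concentrations must be non-negative")
  xmax <- vapply(grid, function(conc) {
    oc <- switch(substrate,
      glucose = operating_conditions(glu0 = conc, yeast0 = 1, thio0 = 0.12,
                                     q_n2 = q_n2, t_end = t_end),
      yeast = operating_conditions(glu0 = 60, yeast0 = conc, thio0 = 0.12,
                                   q_n2 = q_n2, t_end = t_end),
      thiosulfate = operating_conditions(glu0 = 60, yeast0 = 4, thio0 = conc,
                                         q_n2 = q_n2, t_end = t_end))
    1000 * (run_batch(p, cc, oc, ...)$metrics$max_biomass - oc$x0)
  }, numeric(1))
  xmax <- with_seed_(noise$seed, perturb_mult(xmax, noise$conc_cv))
  data.frame(conc = grid, xmax_mg = xmax)
}

#' Generate an inhibition table from H2-enriched sparging runs
#'
#' Emulates the critical-H2 determination campaign: batches sparged with
#' N2/H2 mixtures of increasing H2 content (historically glucose 60 mmol/L,
#' yeast extract 4 g/L, thiosulfate 0.12 mmol/L, 100 mL/min), recording per
#' inlet percentage the realized acetate yield on consumed glucose and the
#' realized maximal specific growth rate relative to the 0% reference.
#'
#' Both quantities are measured over the early exponential phase (biomass
#' below `x_window` g/L), where dissolved H2 is dominated by the imposed
#' headspace composition rather than by the culture's own production — the
#' regime the linear-extrapolation procedure assumes.
#'
#' @param percent_grid inlet H2 percentages, each in `[0, 100]`.
#' @param p,cc parameter and constant objects.
#' @param noise a [noise_spec()] (only `conc_cv` and `seed` are used).
#' @param oc base conditions; `y_h2_in` is overridden per grid point.
#' @param x_window biomass (g/L) ending the observation window.
#' @param ... passed to [run_batch()].
#' @return data frame with columns `pct_h2`, `y_act` (mol/mol) and
#'   `mu_ratio` (realized mu / realized mu at 0%).
#' @export
generate_inhibition_table <- function(percent_grid, p, cc,
                                      noise = noise_spec(),
                                      oc = operating_conditions(
                                        glu0 = 60, yeast0 = 4, thio0 = 0.12,
                                        q_n2 = 6, t_end = 20),
                                      x_window = 0.1, ...) {
  if (any(percent_grid < 0 | percent_grid > 100))
    stop("inlet H2 percentages must lie in [0, 100]")
  one <- function(pct) {
    oc_i <- do.call(operating_conditions,
                    utils::modifyList(unclass(oc), list(y_h2_in = pct / 100)))
    tr <- run_batch(p, cc, oc_i, ...)$trajectory
    win <- tr$X <= max(x_window, 2 * oc$x0)
    if (!any(win)) win <- seq_len(min(10, nrow(tr)))
    i <- max(which(win))
    c(y_act = (tr$Act[i] - tr$Act[1]) / (tr$S1[1] - tr$S1[i]),
      mu = max(tr$mu[win]))
  }
  res <- vapply(percent_grid, one, numeric(2))
  mu0 <- if (any(percent_grid == 0)) res["mu", match(0, percent_grid)]
         else one(0)[["mu"]]
  out <- data.frame(pct_h2 = percent_grid,
                    y_act = res["y_act", ],
                    mu_ratio = res["mu", ] / mu0)
  with_seed_(noise$seed, {
    out$y_act <- perturb_mult(out$y_act, noise$conc_cv)
    out$mu_ratio <- perturb_mult(out$mu_ratio, noise$conc_cv)
    out
  })
}

#' Generate a dynamic gassing-out dissolved-O2 curve
#'
#' First-order absorption (`C(t) = 1 - (1 - C0) exp(-Kla t)`) or desorption
#' (`C(t) = C0 exp(-Kla t)`) curve in fraction-of-saturation units, with
#' additive Gaussian probe noise, for exercising [fit_kla_from_do()].
#'
#' @param klao2 true transfer coefficient (1/h), > 0.
#' @param direction `"absorption"` or `"desorption"`.
#' @param n number of samples.
#' @param t_max duration (h); default spans five time constants.
#' @param c0 initial saturation fraction (0 for absorption, 1 for
#'   desorption by default).
#' @param noise_sd additive noise on the saturation fraction.
#' @param seed RNG seed.
#' @return data frame (`time`, `do`) with attribute `direction`.
#' @export
#' @examples
#' fit_kla_from_do(generate_do_curve(50))$klao2
generate_do_curve <- function(klao2, direction = c("absorption", "desorption"),
                              n = 40, t_max = 5 / klao2, c0 = NULL,
                              noise_sd = 0, seed = NULL) {
  direction <- match.arg(direction)
  if (klao2 <= 0) stop("'klao2' must be > 0")
  if (is.null(c0)) c0 <- if (direction == "absorption") 0 else 1
  tt <- seq(0, t_max, length.out = n)
  do <- if (direction == "absorption") 1 - (1 - c0) * exp(-klao2 * tt)
        else c0 * exp(-klao2 * tt)
  do <- with_seed_(seed, pmin(1.05, perturb_add(do, noise_sd)))
  structure(data.frame(time = tt, do = do), direction = direction)
}
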