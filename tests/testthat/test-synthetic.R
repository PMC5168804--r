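test_that("generators are pure functions of configuration and seed", {
  oc <- operating_conditions(t_end = 6)
  ns <- noise_spec(times = seq(0, 6, 0.5), seed = 7)
  a <- generate_batch(tm_p, tm_cc, oc, ns, dt = 0.05)
  b <- generate_batch(tm_p, tm_cc, oc, ns, dt = 0.05)
  expect_identical(a$observations, b$observations)
  c2 <- generate_batch(tm_p, tm_cc, oc,
                       noise_spec(times = seq(0, 6, 0.5), seed = 8),
                       dt = 0.05)
  expect_false(identical(a$observations, c2$observations))
  # the caller's RNG stream is untouched
  set.seed(1); before <- stats::runif(1)
  set.seed(1); invisible(generate_batch(tm_p, tm_cc, oc, ns, dt = 0.05))
  expect_identical(stats::runif(1), before)
})

test_that("noiseless datasets equal the simulation sampled on the grid", {
  oc <- operating_conditions(t_end = 6)
  ds <- generate_batch(tm_p, tm_cc, oc, noiseless(seq(0, 6, 0.25)),
                       dt = 0.05)
  tr <- ds$sim$trajectory
  idx <- match(seq(0, 6, 0.25), round(tr$time, 10))
  expect_equal(ds$observations$biomass, tr$X[idx], tolerance = 1e-12)
  expect_equal(ds$observations$acetate, tr$Act[idx], tolerance = 1e-12)
  expect_equal(ds$observations$cum_h2,
               tr$cumH2out[idx] + tr$H2g[idx] * oc$v_g, tolerance = 1e-12)
  expect_true(all(ds$observations$offgas_h2_pct >= 0))
  expect_error(generate_batch(tm_p, tm_cc, oc,
                              noise_spec(times = seq(0, 20, 1))),
               "horizon")
})

test_that("noise is unbiased and truncated at zero", {
  oc <- operating_conditions(t_end = 6)
  base <- generate_batch(tm_p, tm_cc, oc, noiseless(seq(0, 6, 1)),
                         dt = 0.05)
  xs <- vapply(1:30, function(s) {
    ds <- generate_batch(tm_p, tm_cc, oc,
                         noise_spec(times = seq(0, 6, 1), seed = s),
                         dt = 0.05)
    expect_true(all(unlist(ds$observations) >= 0))
    max(ds$observations$biomass)
  }, numeric(1))
  truth <- max(base$observations$biomass)
  se <- stats::sd(xs) / sqrt(length(xs))
  expect_lt(abs(mean(xs) - truth), 3 * se + 1e-12)
})

test_that("yield tables are linear in the limiting window with the loss-free slope", {
  # without maintenance and death every consumed glucose carbon routed to
  # biomass appears in Xmax, so the slope is the growth yield itself
  p0 <- update_parameters(tm_p, m_glu = 0, mu_d = 0)
  tb <- generate_yield_table("glucose", c(5, 10, 20), p0, tm_cc,
                             noise = noiseless(), t_end = 30, dt = 0.05)
  fit <- fit_yield(tb$conc, tb$xmax_mg, "glucose")
  expect_equal(fit$slope, p0$y_x_glu, tolerance = 0.02)
  # the composed pipeline recovers the yeast-extract glucose equivalence
  expect_equal(equivalence_from_intercept(fit, 1), p0$eps1, tolerance = 0.05)
  # with maintenance and death active the realised slope falls below the
  # growth yield: batch totals confound growth and maintenance consumption
  tb_full <- generate_yield_table("glucose", c(5, 10, 20), tm_p, tm_cc,
                                  noise = noiseless(), t_end = 30, dt = 0.05)
  fit_full <- fit_yield(tb_full$conc, tb_full$xmax_mg, "glucose")
  expect_lt(fit_full$slope, tm_p$y_x_glu)
  expect_gt(fit_full$slope, 0.5 * tm_p$y_x_glu)
  # beyond the limiting window the response saturates below the line
  sat <- generate_yield_table("glucose", 60, tm_p, tm_cc,
                              noise = noiseless(), t_end = 30, dt = 0.05)
  expect_lt(sat$xmax_mg,
            fit_full$slope * 60 + fit_full$intercept)
  expect_error(generate_yield_table("glucose", numeric(0), tm_p, tm_cc),
               "empty")
})

test_that("dissolved-O2 curves obey first-order kinetics and round-trip", {
  # half-life identity
  curve <- generate_do_curve(50, n = 2, t_max = log(2) / 50)
  expect_equal(curve$do[2], 0.5, tolerance = 1e-12)
  # desorption mirrors absorption
  ka <- fit_kla_from_do(generate_do_curve(35, "absorption", n = 25))$klao2
  kd <- fit_kla_from_do(generate_do_curve(35, "desorption", n = 25))$klao2
  expect_equal(ka, kd, tolerance = 1e-9)
  expect_error(generate_do_curve(-5), "> 0")
  # seeded noise is reproducible
  c1 <- generate_do_curve(50, n = 20, noise_sd = 0.02, seed = 3)
  c2 <- generate_do_curve(50, n = 20, noise_sd = 0.02, seed = 3)
  expect_identical(c1, c2)
})
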