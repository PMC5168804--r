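test_that("yield regressions reproduce the historical lines exactly", {
  conc <- c(2.5, 5, 10, 14, 20)
  fit <- fit_yield(conc, 20.4 * conc + 11.4, "glucose")
  expect_equal(fit$slope, 20.4, tolerance = 1e-9)
  expect_equal(fit$intercept, 11.4, tolerance = 1e-9)
  expect_equal(fit$yield, 20.4, tolerance = 1e-9)   # g/mol
  yc <- c(0.2, 0.3, 0.4, 0.5)
  fy <- fit_yield(yc, 673 * yc + 36.1, "yeast")
  expect_equal(fy$yield, 0.673, tolerance = 1e-9)   # g/g after conversion
  expect_error(fit_yield(c(5, 5), c(100, 101), "glucose"), "distinct")
  expect_warning(fit_yield(c(5, 10, 30), 20.4 * c(5, 10, 30) + 11.4,
                           "glucose"),
                 "limiting range")
})

test_that("equivalence extrapolation gives the glucose content of yeast extract", {
  conc <- c(2.5, 5, 10, 20)
  reg <- fit_yield(conc, 20.4 * conc + 11.4, "glucose")
  expect_equal(equivalence_from_intercept(reg, 1), 11.4 / 20.4,
               tolerance = 1e-9)
  expect_equal(equivalence_from_intercept(reg, 1), 0.56, tolerance = 0.005)
  reg0 <- fit_yield(conc, 20.4 * conc, "glucose")
  expect_equal(equivalence_from_intercept(reg0, 1), 0, tolerance = 1e-9)
  # ratio invariance: doubling slope and intercept changes nothing
  reg2 <- fit_yield(conc, 2 * (20.4 * conc + 11.4), "glucose")
  expect_equal(equivalence_from_intercept(reg2, 1),
               equivalence_from_intercept(reg, 1), tolerance = 1e-9)
  expect_error(equivalence_from_intercept(list(slope = -1, intercept = 3), 1),
               "positive")
})

test_that("apparent-Ks fits recover the Monod constant", {
  s <- c(0.5, 1, 2, 3, 5, 8, 12, 20, 30, 45, 60, 80)
  expect_equal(fit_apparent_ks(s, 0.9 * s / (s + 5.7), 0.9)$ks, 5.7,
               tolerance = 1e-6)
  co <- fit_apparent_ks(s, 0.9 * s / (s + 5.7), 0.8,
                        co_estimate_mu_max = TRUE)
  expect_equal(co$ks, 5.7, tolerance = 1e-4)
  expect_equal(co$mu_max, 0.9, tolerance = 1e-4)
  # saturated-everywhere data carry no information about Ks
  s_hi <- c(400, 500, 600, 800)
  expect_error(fit_apparent_ks(s_hi, 0.9 * s_hi / (s_hi + 5.7), 0.9),
               "non-identifiable")
  # recovery study: 5% noise, 12 concentrations, 200 draws
  set.seed(99)
  est <- vapply(1:200, function(i) {
    mu <- pmax(0, (0.9 * s / (s + 5.7)) * (1 + stats::rnorm(12, 0, 0.05)))
    fit_apparent_ks(s, mu, 0.9)$ks
  }, numeric(1))
  expect_lt(stats::median(abs(est / 5.7 - 1)), 0.10)
})

test_that("critical-H2 extrapolation inverts the inhibition law", {
  # synthetic campaign from the inhibition law itself: dissolved H2 at the
  # inlet equilibrium, responses linear in the inlet percentage for N = 1
  pct <- c(0, 25, 50, 75, 100)
  eq <- 1000 * tm_cc$kh_h2 * (pct / 100) * tm_cc$p_total
  tbl <- data.frame(pct_h2 = pct,
                    y_act = acetate_yield(eq, tm_p),
                    mu_ratio = inhibition_factor(eq, tm_p))
  fit <- estimate_h2crit(tbl, tm_cc)
  # crossing where the equilibrium reaches H2crit: 1.44/0.719 ~ 200%
  expect_equal(fit$mu_ratio$critical_pct,
               100 * 1.44 / (1000 * tm_cc$kh_h2 * tm_cc$p_total),
               tolerance = 1e-6)
  expect_equal(fit$h2_crit, 1.44, tolerance = 1e-6)
  expect_equal(fit$y_act_max, 1.38, tolerance = 1e-6)
  # a response crossing exactly at 100% maps to Kh2 * P
  tbl2 <- data.frame(pct_h2 = pct, y_act = 1.38 * (1 - pct / 100),
                     mu_ratio = 1 - pct / 100)
  fit2 <- estimate_h2crit(tbl2, tm_cc)
  expect_equal(fit2$h2_crit, 1000 * 7.1e-9 * 101325, tolerance = 1e-9)
  # degenerate inputs
  flat <- data.frame(pct_h2 = pct, y_act = rep(1, 5), mu_ratio = rep(1, 5))
  expect_error(estimate_h2crit(flat, tm_cc), "no inhibition trend")
  expect_error(estimate_h2crit(tbl[tbl$pct_h2 > 0, ], tm_cc), "include 0")
  expect_error(estimate_h2crit(tbl[1:2, ], tm_cc), "3 distinct")
})

test_that("simulated inhibition campaign reproduces the extrapolation inputs", {
  tbl <- generate_inhibition_table(c(0, 50, 100), tm_p, tm_cc,
                                   noise = noiseless(),
                                   oc = operating_conditions(
                                     glu0 = 60, yeast0 = 4, thio0 = 0.12,
                                     q_n2 = 6, t_end = 10),
                                   dt = 0.05)
  # growth response at the imposed equilibria: exactly the inhibition factor
  eq100 <- 1000 * tm_cc$kh_h2 * tm_cc$p_total
  expect_equal(tbl$mu_ratio[3], inhibition_factor(eq100, tm_p),
               tolerance = 1e-3)
  # acetate yield at 0% inlet is near its uninhibited maximum (small
  # self-produced H2 during the early window depresses it slightly)
  expect_equal(tbl$y_act[1], 1.38, tolerance = 0.06)
  # roughly 50% drop from 0 to 100% inlet H2
  expect_equal(tbl$y_act[3] / tbl$y_act[1], 0.5, tolerance = 0.08)
  fit <- estimate_h2crit(tbl, tm_cc)
  expect_equal(fit$h2_crit, tm_p$h2_crit, tolerance = 0.02)
  expect_error(generate_inhibition_table(c(0, 150), tm_p, tm_cc),
               "0, 100")
})

test_that("inhibition-exponent selection is consistent on synthetic data", {
  mk <- function(glu, q, seed) generate_batch(
    tm_p, tm_cc, operating_conditions(glu0 = glu, q_n2 = q, t_end = 20),
    noise_spec(conc_cv = 0.05, times = seq(0, 20, 0.5), seed = seed),
    dt = 0.05)
  exps <- list(mk(14, 0.3, 11), mk(20, 0.3, 12), mk(14, 0.6, 13))
  sel <- select_n(c(0.5, 1, 1.5), exps, tm_p, tm_cc, dt = 0.05)
  expect_equal(sel$n, 1)
  # under-strength exponent over-inhibits (negative error), over-strength
  # under-inhibits: the signed-error pattern brackets the truth
  expect_lt(sel$errors[["0.5"]], 0)
  expect_gt(sel$errors[["1.5"]], sel$errors[["1"]])
  expect_lt(abs(sel$errors[["1"]]), abs(sel$errors[["0.5"]]))
  # noiseless single experiment at the true exponent scores zero
  ex0 <- generate_batch(tm_p, tm_cc,
                        operating_conditions(glu0 = 14, t_end = 14),
                        noiseless(times = seq(0, 14, 0.5)), dt = 0.05)
  s0 <- select_n(1, list(ex0), tm_p, tm_cc, dt = 0.05)
  expect_equal(unname(s0$errors), 0, tolerance = 1e-8)
  expect_error(select_n(1, list(), tm_p, tm_cc), "empty")
  expect_error(select_n(-1, list(ex0), tm_p, tm_cc), "> 0")
})
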