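test_that("peak metrics handle constant and analytic pulses", {
  tt <- seq(0, 48, 0.05)
  const <- as_toy_trajectory(tt, rep(2, length(tt)))
  pm <- peak_metrics(const)
  expect_equal(pm$peak_value, 2)
  expect_equal(pm$decline_ratio, 1)

  # A * (t/5) * exp(1 - t/5) has its calculus maximum A at t = 5
  pulse <- as_toy_trajectory(tt, 3 * (tt / 5) * exp(1 - tt / 5))
  pm2 <- peak_metrics(pulse)
  expect_equal(pm2$peak_time, 5, tolerance = 0.011)
  expect_equal(pm2$peak_value, 3, tolerance = 1e-4)
  expect_gte(pm2$peak_value, pm2$value_at_5h)
  expect_gte(pm2$peak_value, pm2$value_at_24h)

  expect_error(peak_metrics(const, species = "nosuch"), "nosuch")
})

test_that("knockouts reproduce the mutant hierarchy", {
  m <- default_model()
  peak_of <- function(mm) peak_metrics(run_aba_protocol(mm, 100))$peak_value

  expect_error(knockout(m, "DREB2A"))
  p_wt <- peak_metrics(wt_trajectory())$peak_value
  p_pp2c <- peak_of(knockout(m, "PP2C"))
  p_pyr <- peak_of(knockout(m, "PYR"))
  expect_equal(peak_of(knockout(m, "SnRK2")), 0)
  expect_equal(peak_of(knockout(m, "ABF")), 0)
  expect_gt(p_pp2c, p_wt)
  expect_gt(p_wt, p_pyr)
  expect_gt(p_pyr, 0)
})

test_that("only the PP2C feedback loop shapes the transient", {
  m <- default_model()
  wt <- wt_trajectory()

  abl_pp2c <- run_aba_protocol(feedback_ablation(m, "PP2C"), 100)
  ts <- transient_score(abl_pp2c)
  expect_false(ts$is_transient) # sustained, logarithmic-like accumulation
  expect_gt(ts$decline_ratio, 0.8)
  expect_gt(fold_change(abl_pp2c, wt), 10)

  for (g in c("ABF", "DREB2A")) {
    abl <- run_aba_protocol(feedback_ablation(m, g), 100)
    expect_true(transient_score(abl)$is_transient)
  }
  expect_error(feedback_ablation(m, "PYR"))
})

test_that("fold change is a ratio of peaks", {
  tt <- seq(0, 30, 0.5)
  a <- as_toy_trajectory(tt, sin(tt / 10) + 1.5)
  b <- as_toy_trajectory(tt, 3 * (sin(tt / 10) + 1.5))
  expect_equal(fold_change(a, a), 1)
  expect_equal(fold_change(b, a), 3)
  zero <- as_toy_trajectory(tt, rep(0, length(tt)))
  expect_error(fold_change(a, zero), "zero")
})

test_that("DRE affinity shifts expression level but not transient shape", {
  m <- default_model()
  weak_dre <- set_parameters(m, c(
    kr11 = param_value(m$parameters, "kr11") * 100,
    kr13 = param_value(m$parameters, "kr13") * 100))
  traj <- run_aba_protocol(weak_dre, 100)
  expect_lt(peak_metrics(traj)$peak_value,
            peak_metrics(wt_trajectory())$peak_value)
  expect_true(transient_score(traj)$is_transient)
})

test_that("sensitivity indices behave like local log-gradients", {
  m <- default_model()
  expect_error(local_sensitivity(m, perturbation = 0), "positive")

  # kf45 is declared but drives no reaction: a disconnected parameter
  sens <- local_sensitivity(m, parameter_names = c("kr10", "kf45"),
                            window = 12)
  expect_equal(sens$sensitivity[sens$parameter == "kf45"], 0)
  expect_gt(sens$sensitivity[sens$parameter == "kr10"], 1)
  expect_setequal(sens$rank, 1:2)

  # finite-difference convergence: halving the perturbation moves the index
  # by well under 5%
  for (p in c("kr10", "kr16")) {
    s1 <- local_sensitivity(m, p, perturbation = 0.01, window = 12)
    s2 <- local_sensitivity(m, p, perturbation = 0.005, window = 12)
    expect_equal(s1$sensitivity, s2$sensitivity, tolerance = 0.05)
  }
})
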