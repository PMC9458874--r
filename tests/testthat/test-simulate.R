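test_that("an isolated reversible binding reaches its closed-form equilibrium", {
  kf <- 3.6e6; kr <- 7200
  toy <- toy_binding_model(kf = kf, kr = kr, a0 = 0.1, b0 = 0.1)
  traj <- simulate_model(toy, t_grid = c(0, 10))
  c_eq <- toy_binding_equilibrium(kf, kr, 0.1, 0.1)
  final <- unlist(traj[nrow(traj), -1])
  expect_equal(final[["C"]], c_eq, tolerance = 1e-6)
  expect_equal(final[["A"]], 0.1 - c_eq, tolerance = 1e-6)
  # detailed balance: [C]/([A][B]) = kf/kr
  expect_equal(final[["C"]] / (final[["A"]] * final[["B"]]), kf / kr,
               tolerance = 1e-5)
})

test_that("first-order decay follows the exponential closed form", {
  toy <- toy_binding_model(a0 = 0, b0 = 0, d0 = 1, kdecay = 0.05)
  t_half <- log(2) / 0.05 # 13.86 h
  traj <- simulate_model(toy, t_grid = c(0, t_half, 2 * t_half))
  expect_equal(traj$D, c(1, 0.5, 0.25), tolerance = 1e-6)
})

test_that("clamped species stay constant", {
  m <- default_model()
  s <- initial_state(m)
  s["ABA"] <- 42
  traj <- simulate_model(m, s, t_grid = seq(0, 5, 1))
  expect_equal(traj$ABA, rep(42, 6))
  # per-run clamp of an arbitrary species
  traj2 <- simulate_model(m, s, t_grid = seq(0, 5, 1),
                          clamps = c(PYR = 0.25))
  expect_equal(traj2$PYR, rep(0.25, 6))
})

test_that("gene loci are conserved along the protocol trajectory", {
  traj <- wt_trajectory()
  locus <- molecules_to_concentration(2, 50)
  rd_total <- traj$RD29Aprom_free + traj$RD29Aprom_ABRE +
    traj$RD29Aprom_DRE + traj$RD29Aprom_both
  expect_equal(rd_total, rep(locus, nrow(traj)), tolerance = 1e-6)
  for (g in c("PP2C", "ABF", "DREB2A")) {
    tot <- traj[[paste0("ABRE_", g, "_free")]] +
      traj[[paste0("ABRE_", g, "_bound")]]
    expect_equal(tot, rep(locus, nrow(traj)), tolerance = 1e-6)
  }
  expect_true(all(as.matrix(traj[, -1]) >= 0))
  expect_true(all(diff(traj$time_h) > 0))
})

test_that("equilibration reaches the 0.1 uM constitutive design point", {
  eq <- feedback_off_equilibrium()
  expect_equal(eq[["PYR"]], 0.0996, tolerance = 0.005)
  expect_lt(attr(eq, "qss_residual"), 0.1)
  # duration 0 returns the initial state unchanged
  m <- default_model()
  eq0 <- equilibrate(m, duration = 0)
  s0 <- initial_state(m); s0["ABA"] <- 0
  expect_equal(unname(eq0[names(s0)]), unname(s0))
})

test_that("DREB2A equilibrates below the feedback-off baseline", {
  # proteasome-mediated proteolysis is active even without ABA
  eq <- feedback_off_equilibrium()
  expect_lt(eq[["DREB2A"]], 0.05)
  expect_lt(eq[["DREB2A"]], eq[["PYR"]])
})

test_that("the protocol returns a post-step clock and responds to dose", {
  traj <- wt_trajectory()
  expect_equal(traj$time_h[1], 0)
  expect_equal(attr(traj, "dose"), 100)

  # dose 0 leaves RD29A at its pre-step quasi-steady level
  m <- default_model()
  flat <- run_aba_protocol(m, dose = 0, post_duration = 24,
                           t_grid = seq(0, 24, 1))
  y <- flat$mRNA_RD29A
  expect_lt(max(abs(y - y[1])) / y[1], 0.05)

  # no transcription channel, no RD29A at all
  m0 <- set_parameters(m, c(kf27 = 0))
  none <- run_aba_protocol(m0, dose = 100, post_duration = 24,
                           t_grid = seq(0, 24, 1))
  expect_equal(none$mRNA_RD29A, rep(0, 25))

  expect_error(run_aba_protocol(m, dose = -1), "non-negative")
})

test_that("solver tolerances and equilibration length are converged", {
  m <- default_model()
  peak_ref <- peak_metrics(wt_trajectory())$peak_value
  tight <- run_aba_protocol(m, 100, post_duration = 24,
                            t_grid = seq(0, 24, 0.05),
                            rtol = 5e-9, atol = 5e-13)
  expect_equal(peak_metrics(tight)$peak_value, peak_ref, tolerance = 1e-3)

  long_pre <- run_aba_protocol(m, 100, post_duration = 24,
                               pre_duration = 600,
                               t_grid = seq(0, 24, 0.05))
  expect_equal(peak_metrics(long_pre)$peak_value, peak_ref,
               tolerance = 0.01)
})

test_that("trajectories round-trip through CSV with metadata", {
  traj <- run_aba_protocol(default_model(), dose = 10, post_duration = 2,
                           t_grid = seq(0, 2, 0.5))
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(c(path, paste0(path, ".meta.json"))))
  write_trajectory(traj, path)
  back <- read_trajectory(path)
  expect_equal(as.data.frame(back), as.data.frame(traj), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(back, "dose"), 10)
})
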