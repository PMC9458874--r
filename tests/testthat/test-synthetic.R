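test_that("the noise-free mean curve has the designed shape", {
  # zero dose: flat baseline
  d0 <- generate_luminescence(0, noise_cv = 0, n_reps = 1)
  expect_equal(d0$rlu, rep(10, nrow(d0)))

  # saturating dose: unimodal pulse with mode at 5 h
  d200 <- generate_luminescence(200, noise_cv = 0, n_reps = 1)
  expect_equal(d200$time_h[which.max(d200$rlu)], 5)
  before <- d200$rlu[d200$time_h <= 5]
  after <- d200$rlu[d200$time_h >= 5]
  expect_true(all(diff(before) >= 0))
  expect_true(all(diff(after) <= 0))
  expect_true(all(d200$rlu > 0))

  # dose monotonicity of the amplitude
  amps <- vapply(c(0, 10, 50, 100, 200), function(d) {
    max(generate_luminescence(d, noise_cv = 0, n_reps = 1)$rlu)
  }, numeric(1))
  expect_true(all(diff(amps) > 0))
})

test_that("generation is reproducible and validates input", {
  a <- generate_luminescence(100, seed = 5)
  b <- generate_luminescence(100, seed = 5)
  expect_equal(a, b)
  expect_error(generate_luminescence(100, noise_cv = -0.1), "non-negative")
  expect_error(generate_luminescence(-5), "non-negative")
  expect_error(generate_luminescence(100, n_reps = 0), "n_reps")
})

test_that("replicate means converge to the generator mean", {
  n <- 400
  noisy <- generate_luminescence(100, n_reps = n, noise_cv = 0.2, seed = 3)
  clean <- generate_luminescence(100, n_reps = 1, noise_cv = 0)
  means <- noisy |>
    dplyr::group_by(time_h) |>
    dplyr::summarise(rlu = mean(rlu), .groups = "drop")
  # multiplicative noise has mean one, so the Monte-Carlo error of the
  # replicate mean is within 3 * cv / sqrt(n) of zero
  rel_err <- abs(means$rlu - clean$rlu) / clean$rlu
  expect_true(all(rel_err < 3 * 0.2 / sqrt(n)))
})

test_that("the dose series reads out saturating luminescence at 5 h", {
  ds <- generate_dose_series(c(0, 200), noise_cv = 0)
  expect_gt(ds$mean_rlu[ds$dose_uM == 200], ds$mean_rlu[ds$dose_uM == 0])

  # SEM is consistent with log-normal replicate noise: sd ~ cv * mean
  n <- 200
  one <- generate_dose_series(100, seed = 9, n_reps = n, noise_cv = 0.1)
  expected_sem <- 0.1 * one$mean_rlu / sqrt(n)
  expect_equal(one$sem_rlu, expected_sem, tolerance = 0.2)

  expect_error(generate_dose_series(numeric(0)), "non-empty")
  expect_error(generate_dose_series(100, sample_time = 99), "grid")
})

test_that("from-model datasets track the simulated RD29A trace", {
  m <- default_model()
  dm <- generate_luminescence(100, model = m, noise_cv = 0, n_reps = 1,
                              times = seq(0, 24, 1), baseline = 0)
  traj <- run_aba_protocol(m, 100, post_duration = 24,
                           t_grid = seq(0, 24, 1))
  y <- traj$mRNA_RD29A
  expect_equal(dm$rlu, 1000 * y / max(y), tolerance = 1e-8)
  expect_equal(attr(dm, "truth")$source, "from_model")
})

test_that("luminescence datasets round-trip through CSV", {
  d <- generate_luminescence(50, seed = 21)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(c(path, paste0(path, ".meta.json"))))
  write_luminescence(d, path)
  back <- read_luminescence(path)
  expect_equal(as.data.frame(back), as.data.frame(d), tolerance = 1e-12)
  expect_equal(attr(back, "truth")$noise_cv, 0.1)
})
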