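test_that("the default network has the expected structure", {
  m <- default_model()
  expect_s3_class(m, "aba_model")
  expect_gte(nrow(m$species), 30)

  # exactly three genes carry an ABRE feedback channel
  fb <- grep("^fb_transcription_", m$reactions$id, value = TRUE)
  expect_setequal(sub("fb_transcription_", "", fb),
                  c("PP2C", "ABF", "DREB2A"))

  # every promoter-state family sums to the two-copy locus concentration
  locus <- molecules_to_concentration(2, 50)
  s0 <- initial_state(m)
  expect_equal(sum(s0[c("RD29Aprom_free", "RD29Aprom_ABRE", "RD29Aprom_DRE",
                        "RD29Aprom_both")]), locus)
  for (g in c("PP2C", "ABF", "DREB2A")) {
    expect_equal(sum(s0[paste0("ABRE_", g, c("_free", "_bound"))]), locus)
  }
  # all initial concentrations are zero except gene loci / promoter states
  nonzero <- names(s0)[s0 > 0]
  expect_true(all(grepl("^gene_|^ABRE_.*_free$|^RD29Aprom_free$", nonzero)))

  # every referenced parameter exists
  refs <- stats::na.omit(c(m$reactions$forward_param,
                           m$reactions$reverse_param))
  expect_true(all(refs %in% m$parameters$name))
})

test_that("building without a required parameter fails", {
  pt <- build_parameter_table()
  expect_error(build_model(pt[pt$name != "kf26", ]), "kf26")
})

test_that("mass-action derivatives follow the rate laws", {
  m <- default_model()
  zero <- stats::setNames(rep(0, nrow(m$species)), m$species$name)
  expect_equal(unname(mass_action_rhs(m, zero)), rep(0, length(zero)))

  # a lone constitutive gene locus drives d[mRNA]/dt = kf29 * [G]
  locus <- molecules_to_concentration(2, 50)
  s <- zero
  s["gene_PYR"] <- locus
  d <- mass_action_rhs(m, s)
  expect_equal(unname(d["mRNA_PYR"]),
               param_value(m$parameters, "kf29") * locus)
  expect_equal(unname(d["gene_PYR"]), 0)
  expect_equal(sum(abs(d)), abs(d[["mRNA_PYR"]]))

  # clamped ABA has zero derivative regardless of binding fluxes
  s2 <- zero
  s2["ABA"] <- 100
  s2["PYR"] <- 0.1
  d2 <- mass_action_rhs(m, s2)
  expect_equal(unname(d2["ABA"]), 0)
  expect_true(d2[["ABA_PYR"]] > 0)

  expect_error(mass_action_rhs(m, zero[-1]), "length")
  s3 <- zero; s3["PYR"] <- -1
  expect_error(mass_action_rhs(m, s3), "PYR")
})

test_that("the analytic Jacobian matches finite differences", {
  m <- default_model()
  set.seed(7)
  x <- stats::runif(nrow(m$species), 0, 0.1)
  J <- abasignal:::.jac_raw(m$compiled, x)
  h <- 1e-7
  for (j in sample(seq_along(x), 6)) {
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    fd <- (abasignal:::.rhs_raw(m$compiled, xp) -
             abasignal:::.rhs_raw(m$compiled, xm)) / (2 * h)
    expect_equal(J[, j], fd, tolerance = 1e-3)
  }
})

test_that("protein totals account for every containing species", {
  eq <- feedback_off_equilibrium()
  # production kf30 * mRNA_ss balances 0.05/h whole-complex degradation
  for (p in c("PYR", "PP2C", "SnRK2", "ABF")) {
    expect_equal(protein_total(eq, p), 0.0996, tolerance = 0.01)
  }
})
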