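test_that("quantile calibration solves the log-normal anchors in closed form", {
  d <- calibrate_normal_distributions(MK)
  expect_equal(nrow(d), 43)
  # median identity: exp(mu) is the geometric mean of the bounds when the
  # anchor quantiles are symmetric
  c0 <- d[d$key == "C0", ]
  expect_equal(exp(c0$mu), sqrt(9 * 50), tolerance = 1e-12)
  # anchored quantiles hit the cut-off bounds exactly
  expect_equal(stats::qlnorm(0.005, c0$mu, c0$sigma), 9, tolerance = 1e-10)
  expect_equal(stats::qlnorm(0.995, c0$mu, c0$sigma), 50, tolerance = 1e-10)
  # zero lower bounds are replaced by eps before taking logs
  sa <- d[d$key == "SA", ]
  expect_true(is.finite(sa$mu) && sa$sigma > 0)

  degenerate <- MK
  degenerate$table$low[degenerate$table$name == "C0"] <- 50
  expect_error(calibrate_normal_distributions(degenerate), "C0")
})

test_that("sampled marker quantiles reproduce the cut-off anchors", {
  set.seed(2024)
  d <- calibrate_normal_distributions(MK)
  for (key in c("C0", "PHE", "C16")) {
    row <- d[d$key == key, ]
    draws <- stats::rlnorm(1e5, row$mu, row$sigma)
    q <- stats::quantile(draws, c(0.005, 0.995), names = FALSE)
    bounds <- MK$table[MK$table$key == key, c("low", "high")]
    expect_lt(abs(q[1] - bounds$low) / bounds$low, 0.05)
    expect_lt(abs(q[2] - bounds$high) / bounds$high, 0.05)
  }
})

test_that("disease profiles satisfy their target group at the set sensitivity", {
  profs <- default_disease_profiles(RL, MK)
  expect_named(profs, nbs_confirmed_counts()$disorder)
  # full-sensitivity PCD cohort: every affected panel satisfies C0 < 8.5,
  # inside the span of the observed case levels
  cfg <- cohort_config(n = 1000, incidence = c(PCD = 1 - 1e-9),
                       fp_rate = 0, seed = 5)
  coh <- sample_cohort(cfg, profiles = profs, rules = RL, markers = MK)
  c0 <- coh$panels[coh$truth == "PCD", "C0"]
  expect_gt(length(c0), 900)
  expect_true(all(c0 < 8.5))
  expect_true(all(c0 >= 1.94))
  # HPA profile anchored at the highest observed phenylalanine
  cfg2 <- cohort_config(n = 1000, incidence = c(PAHD = 1 - 1e-9),
                        fp_rate = 0, seed = 6)
  coh2 <- sample_cohort(cfg2, profiles = profs, rules = RL, markers = MK)
  phe <- coh2$panels[coh2$truth == "PAHD", "PHE"]
  expect_true(all(phe > 120 & phe <= 745.62))

  expect_error(make_disease_profile(RL[["PCD"]], group_index = 9),
               "no group")
  expect_error(make_disease_profile(RL[["PCD"]], sensitivity = 0),
               "sensitivity")
})

test_that("half-sensitivity profiles flag about half of affected panels", {
  profs <- default_disease_profiles(RL, MK, sensitivity = 0.5)
  cfg <- cohort_config(n = 10000, incidence = c(SCADD = 1 - 1e-9),
                       fp_rate = 0, seed = 8)
  coh <- sample_cohort(cfg, profiles = profs, rules = RL, markers = MK)
  scr <- screen_cohort(coh, RL)
  frac <- mean(scr$flagged[coh$truth == "SCADD", "SCADD"])
  expect_lt(abs(frac - 0.5), 0.05)
})

test_that("ratio conditions of a targeted group are enforced after derivation", {
  # PCD's second group conjoins C0 < 9 with the esterified/citrulline ratio
  prof <- make_disease_profile(RL[["PCD"]], group_index = 2,
                               disorder = "PCD", markers = MK)
  cfg <- cohort_config(n = 500, incidence = c(PCD = 1 - 1e-9),
                       fp_rate = 0, seed = 9)
  coh <- sample_cohort(cfg, profiles = list(PCD = prof), rules = RL,
                       markers = MK)
  idx <- coh$truth == "PCD"
  ratio <- coh$panels[idx, "(C0 + C2 + C3 + C16 + C18:1 + C18)/CIT"]
  expect_true(all(coh$panels[idx, "C0"] < 9))
  expect_true(all(ratio <= 1.3))
})

test_that("cohorts are reproducible and respect the configured incidences", {
  cfg <- cohort_config(n = 20000, seed = 123)
  a <- sample_cohort(cfg, rules = RL, markers = MK)
  b <- sample_cohort(cfg, rules = RL, markers = MK)
  expect_identical(a$panels, b$panels)
  expect_identical(a$truth, b$truth)
  expect_identical(a$year, b$year)

  # affected count for one disorder stays within its 99% Poisson band
  cfg2 <- cohort_config(n = 1e5, incidence = c(PCD = 1 / 13675),
                        fp_rate = 0, seed = 10)
  coh <- sample_cohort(cfg2, rules = RL, markers = MK)
  lambda <- 1e5 / 13675
  band <- stats::qpois(c(0.005, 0.995), lambda)
  expect_gte(sum(coh$truth == "PCD"), band[1])
  expect_lte(sum(coh$truth == "PCD"), band[2])

  expect_error(
    sample_cohort(cohort_config(n = 10, incidence = c(NOPE = 0.1), seed = 1),
                  rules = RL, markers = MK),
    "NOPE")
})

test_that("suspected-positive volume rises monotonically with fp_rate", {
  fracs <- vapply(c(0, 0.01, 0.05), function(fp) {
    cfg <- cohort_config(n = 20000, incidence = c(PCD = 0), fp_rate = fp,
                         seed = 77)
    coh <- sample_cohort(cfg, rules = RL, markers = MK)
    mean(screen_cohort(coh, RL)$suspected)
  }, numeric(1))
  expect_true(all(diff(fracs) > 0))
  # an unaffected-only cohort with no error layer flags only through
  # reference-tail variation: a small fraction, and no affected newborns
  cfg0 <- cohort_config(n = 10000, incidence = c(PCD = 0), fp_rate = 0,
                        seed = 78)
  coh0 <- sample_cohort(cfg0, rules = RL, markers = MK)
  expect_true(all(coh0$truth == "none"))
  expect_lt(mean(screen_cohort(coh0, RL)$suspected), 0.03)
})
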