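test_that("exposure matrix tracks prevalences and is seed-deterministic", {
  tab <- load_fixture("mena_prostate")
  cfg <- cohort_config(tab, n = 1e5, seed = 7)
  cohort <- simulate_exposures(cfg)
  expect_equal(dim(cohort$exposures), c(1e5, 14))
  # every column mean within a 3-sigma binomial band of its prevalence
  for (j in seq_len(nrow(tab))) {
    p <- tab$prevalence[j]
    expect_lt(abs(mean(cohort$exposures[, j]) - p),
              max(3 * sqrt(p * (1 - p) / 1e5), 1e-12))
  }
  # identical seed, identical matrix
  again <- simulate_exposures(cohort_config(tab, n = 1e5, seed = 7))
  expect_identical(cohort$exposures, again$exposures)
  # zero prevalence yields an all-zero column
  tab0 <- risk_table(rbind(risk_factor("never", "behavioral", 0, 1.5, 1.2, 1.9)),
                     1e4, 2e-4)
  c0 <- simulate_exposures(cohort_config(tab0, n = 1000, seed = 1))
  expect_true(all(c0$exposures == 0))
})

test_that("intercept calibration is exact for unexposed cohorts and matches a bisection oracle", {
  # nobody exposed: closed form logit(target)
  tab0 <- risk_table(rbind(risk_factor("never", "behavioral", 0, 1.5, 1.2, 1.9)),
                     1e4, 2e-4)
  c0 <- simulate_exposures(cohort_config(tab0, n = 500, seed = 1))
  expect_identical(calibrate_intercept(c0), qlogis(2e-4))

  # one factor, half the cohort exposed, rr = 2: oracle solves
  # 0.5 s(c) + 0.5 s(c + log 2) = 2e-4 by bisection
  tab1 <- risk_table(rbind(risk_factor("x", "behavioral", 0.5, 2, 1.5, 2.7)),
                     1e4, 2e-4)
  c1 <- simulate_exposures(cohort_config(tab1, n = 2, seed = 1))
  c1$exposures[, 1] <- c(0, 1)
  oracle <- bisect(function(c) 0.5 * plogis(c) + 0.5 * plogis(c + log(2)) - 2e-4,
                   -30, 0)
  expect_equal(calibrate_intercept(c1), oracle, tolerance = 1e-9)
})

test_that("calibration drives the mean probability onto the target incidence", {
  tab <- load_fixture("mena_prostate")
  cohort <- simulate_cohort(cohort_config(tab, n = 1e5, seed = 7))
  expect_lt(abs(mean(cohort$probabilities) - 23.7e-5), 1e-10)
  expect_error(
    calibrate_intercept(local({
      x <- simulate_exposures(cohort_config(tab, n = 100, seed = 1))
      x$log_rr[1] <- -Inf
      x
    })),
    "non-finite"
  )
})

test_that("disease assignment is logistic, reproducible, and binomially plausible", {
  tab0 <- risk_table(rbind(risk_factor("never", "behavioral", 0, 1.5, 1.2, 1.9)),
                     1e4, 2e-4)
  cohort <- simulate_cohort(cohort_config(tab0, n = 1000, seed = 3))
  expect_true(all(cohort$probabilities == plogis(cohort$intercept)))

  tab <- load_fixture("mena_prostate")
  cfgb <- cohort_config(tab, n = 1e5, seed = 7, case_mode = "bernoulli")
  a <- simulate_cohort(cfgb)
  b <- simulate_cohort(cfgb)
  expect_identical(a$cases, b$cases)
  # case count within a wide binomial band around n * target incidence
  expect_gte(sum(a$cases), qbinom(1e-4, 1e5, 23.7e-5))
  expect_lte(sum(a$cases), qbinom(1 - 1e-4, 1e5, 23.7e-5))
})

test_that("counterfactual elimination recovers closed-form fractions", {
  tab <- load_fixture("mena_prostate")
  cfg <- cohort_config(tab, n = 2e5, seed = 7)
  res <- cohort_paf_all(cfg)
  # rare-disease equivalence at moderate n: within half a point of Levin
  closed <- levin_paf(tab$prevalence, tab$rr)
  expect_true(all(abs(res$factors$paf - closed) < 0.005))
  # monotone counterfactuals: sign of the cohort PAF follows direction
  expect_true(all(res$factors$paf[tab$direction == "harmful"] > 0))
  expect_true(all(res$factors$paf[tab$direction == "protective"] < 0))
  # the protective factor raises the environmental joint less than the sum
  expect_lt(res$joint$paf[res$joint$set == "all"], 1)
  # a null factor contributes exactly zero in expected mode
  null_tab <- generate_synthetic_table(3, seed = 4, log_rr_sd = 0)
  null_res <- cohort_paf(cohort_config(null_tab, n = 1e4, seed = 1), "factor_01")
  expect_identical(null_res$paf, 0)
  expect_error(cohort_paf(cfg, "no_such_factor"), "unknown factor")
})

test_that("single-factor cohort PAF agrees with its published value", {
  tab <- load_fixture("mena_prostate")
  res <- cohort_paf(cohort_config(tab, n = 1e5, seed = 2), "tobacco_smoking")
  expect_lt(abs(res$paf - 0.095), 0.003)  # within 0.3 percentage points
  expect_equal(res$method, "cohort")
})
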