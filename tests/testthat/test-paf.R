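test_that("Levin PAF matches hand-computed values", {
  # frozen decimals computed by hand from Pe*(RR-1)/(Pe*(RR-1)+1)
  expect_equal(levin_paf(0.25, 1.42), 0.09502262, tolerance = 1e-7)
  expect_equal(levin_paf(0.30, 1.70), 0.17355372, tolerance = 1e-7)
  expect_equal(levin_paf(0.28, 0.86), -0.04079933, tolerance = 1e-7)
  expect_equal(round_half_up(100 * levin_paf(0.28, 0.86), 1), -4.1)
  # null relative risk zeroes the fraction at any prevalence
  expect_equal(levin_paf(seq(0, 1, 0.1), 1.0), rep(0, 11))
  expect_error(levin_paf(1.2, 1.5), "pe")
  expect_error(levin_paf(0.5, -1), "rr")
})

test_that("Levin PAF is monotone in prevalence and relative risk", {
  pe_grid <- seq(0.01, 0.99, length.out = 50)
  expect_true(all(diff(levin_paf(pe_grid, 1.8)) > 0))
  expect_true(all(diff(levin_paf(pe_grid, 0.7)) < 0))
  rr_grid <- seq(0.2, 4, length.out = 50)
  expect_true(all(diff(levin_paf(0.3, rr_grid)) > 0))
  # and always below 1
  expect_true(all(levin_paf(pe_grid, 50) < 1))
})

test_that("joint PAF combines multiplicatively and sub-additively", {
  expect_equal(joint_paf(0.095), 0.095)
  expect_equal(joint_paf(c(0.5, 0.5)), 0.75)
  expect_equal(joint_paf(numeric(0)), 0)
  # six behavioral fractions of the fixture, combined by complement product
  tab <- load_fixture("mena_prostate")
  beh <- levin_paf(tab$prevalence[tab$category == "behavioral"],
                   tab$rr[tab$category == "behavioral"])
  expect_equal(joint_paf(beh), 0.261038, tolerance = 1e-5)
  expect_lte(joint_paf(beh), sum(beh))
  expect_gte(joint_paf(beh), max(beh))
  # protective factors shrink the joint fraction
  expect_lt(joint_paf(c(0.2, -0.05)), joint_paf(0.2))
  expect_error(joint_paf(c(0.5, 1)), "< 1")
})

test_that("impact fraction matches hand-computed scenarios and reduces to PAF", {
  expect_equal(pif(scenario_spec("nitrate", 0.30, 0.20), 1.70),
               0.05785124, tolerance = 1e-7)
  expect_equal(pif(0.25, rr = 1.42, p1 = 0.15), 0.03800905, tolerance = 1e-7)
  expect_equal(pif(scenario_spec("x", 0.4, 0.4), 1.3), 0)
  # full elimination recovers Levin exactly, across a parameter grid
  for (p0 in c(0.05, 0.3, 0.8)) for (rr in c(0.8, 1.0, 1.5, 2.4)) {
    expect_identical(pif(p0, rr = rr, p1 = 0), levin_paf(p0, rr))
  }
  expect_error(scenario_spec("x", 0.2, 0.3), "increase")
  expect_silent(scenario_spec("x", 0.2, 0.3, allow_increase = TRUE))
})

test_that("combined impact fraction matches the fixture scenario set", {
  expect_equal(combined_pif(0.123), 0.123)
  expect_equal(combined_pif(c(0, 0, 0)), 0)
  tab <- load_fixture("mena_prostate")
  four <- pif_table(tab)
  expect_equal(four$pif[four$factor_name == "combined"], 0.121580,
               tolerance = 1e-5)
  expect_equal(four$pif_percent,
               c(1.4, 1.7, 5.8, 3.8, 12.2))
})

test_that("paf_table reports every factor, splitting diesel strata", {
  tab <- load_fixture("mena_prostate")
  pt <- paf_table(tab)
  expect_equal(nrow(pt), 15)  # 14 factors, diesel twice
  expect_setequal(pt$factor_name[grepl("diesel", pt$factor_name)],
                  c("diesel_exhaust", "diesel_exhaust_alt"))
  expect_equal(pt$paf_percent[pt$factor_name == "physical_inactivity"], 6.7)
  expect_equal(pt$paf_percent[pt$factor_name == "thms"], 5.0)
  expect_equal(pt$paf_percent[pt$factor_name == "arsenic"], 3.1)
  expect_equal(pt$paf_percent[pt$factor_name == "lead"], 0.7)
  expect_equal(pt$paf_percent[pt$factor_name == "no2"], 2.3)
  expect_equal(pt$paf_percent[grepl("diesel", pt$factor_name)], c(0.5, 0.5))
  expect_true(all(pt$method == "closed_form"))
  # null table propagates to all-zero fractions
  null_pt <- paf_table(generate_synthetic_table(5, seed = 2, log_rr_sd = 0))
  expect_true(all(null_pt$paf == 0))
})

test_that("joint table restricts to a single diesel stratum on request", {
  tab <- load_fixture("mena_prostate")
  both <- joint_paf_table(tab)
  one <- joint_paf_table(tab, include_alt_strata = FALSE)
  expect_equal(both$joint_percent[both$set == "all"], 45.8)
  expect_equal(one$joint_percent[one$set == "all"], 45.5)
  expect_lt(one$joint_paf[one$set == "all"], both$joint_paf[both$set == "all"])
})

test_that("half-up rounding matches the report convention", {
  expect_equal(round_half_up(3.05, 1), 3.1)
  expect_equal(round_half_up(2.34375, 1), 2.3)
  expect_equal(round_half_up(-4.08, 1), -4.1)
  expect_equal(round_half_up(0.05, 1), 0.1)
  expect_equal(round_half_up(c(1.25, 1.35), 1), c(1.3, 1.4))
})
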