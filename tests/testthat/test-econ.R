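test_that("discounting follows the end-of-year convention", {
  expect_equal(discount(103, 1, 0.03), 100)
  expect_equal(discount(250, 0, 0.08), 250)
  expect_equal(discount(77, 10, 0), 77)
  # five-year annuity of 100 at 3%: closed form (1 - 1.03^-5)/0.03
  expect_equal(sum(discount(100, 1:5, 0.03)), 100 * (1 - 1.03^-5) / 0.03)
  expect_equal(round(sum(discount(100, 1:5, 0.03)), 2), 457.97)
  expect_error(discount(1, -1, 0.03), "year")
  expect_error(discount(1, 1, -0.1), "rate")
})

test_that("effectiveness spans the scenario grid and is affine in pi", {
  cf <- study_econ()
  e0 <- effectiveness(cf, 0)
  expect_equal(e0$errors_prevented_ai, 4)
  expect_equal(e0$incremental, 3)
  e5 <- effectiveness(cf, 0.5)
  expect_equal(e5$errors_prevented_ai, 19)
  expect_equal(e5$errors_prevented_trad, 1)
  expect_equal(e5$incremental, 18)
  expect_equal(effectiveness(cf, 1)$incremental, 33)
  # affine: midpoint value is the mean of the endpoints
  expect_equal(e5$incremental, (e0$incremental +
                                  effectiveness(cf, 1)$incremental) / 2)
})

test_that("the ICER formula reproduces the published value to the cent", {
  res <- icer(study_econ(), 0.5)
  expect_equal(round(res$icer, 2), 18641.89)
  expect_equal(res$icer, (461426.49 - 125872.46) / 18)
  # linearity and identity checks
  equal <- icer(econ_config(cost_ai = 1e5, cost_traditional = 1e5), 0.5)
  expect_equal(equal$icer, 0)
  doubled <- icer(econ_config(cost_ai = 2 * 461426.49,
                              cost_traditional = 2 * 125872.46), 0.5)
  expect_equal(doubled$icer, 2 * res$icer)
  # the ICER identity is re-derivable from the result's own fields
  expect_equal(res$icer,
               (res$total_cost_ai - res$total_cost_trad) /
                 (res$errors_prevented_ai - res$errors_prevented_trad))
})

test_that("a zero incremental effect signals dominance, not a division error", {
  cf <- econ_config(direct_errors_preventable = 1,
                    comparator_errors_prevented = 1)
  res <- icer(cf, 0)
  expect_true(is.na(res$icer))
  expect_match(res$dominance, "zero incremental effect")
})

test_that("NPV behaves as the discounted benefit-minus-cost difference", {
  zero_ben <- econ_config(benefit_per_error = c(treatment_cost = 0,
                                                legal_compensation = 0,
                                                reputation_revenue_loss = 0))
  res <- npv(zero_ben, 0.5)
  expect_equal(res$npv, -(461426.49 - 125872.46))
  expect_lt(res$npv, 0)
  # single-year horizon at zero rate: closed form B x effect - cost
  cf1 <- econ_config(horizon_years = 1, discount_rate = 0,
                     cost_ai = 500, cost_traditional = 100,
                     benefit_per_error = c(treatment_cost = 1000,
                                           legal_compensation = 0,
                                           reputation_revenue_loss = 0),
                     near_misses = 0)
  expect_equal(npv(cf1, 0)$npv, 1000 * 3 - 400)
  # affine in each benefit component (finite differences)
  base <- npv(study_econ(), 0.5)$npv
  for (comp in c("treatment_cost", "legal_compensation",
                 "reputation_revenue_loss")) {
    bump <- c(treatment_cost = 15000, legal_compensation = 80000,
              reputation_revenue_loss = 25000)
    bump[comp] <- bump[comp] + 1000
    d1 <- npv(econ_config(benefit_per_error = bump), 0.5)$npv - base
    bump[comp] <- bump[comp] + 1000
    d2 <- npv(econ_config(benefit_per_error = bump), 0.5)$npv - base
    expect_equal(d2, 2 * d1, tolerance = 1e-9)
    expect_gt(d1, 0)
  }
})

test_that("NPV is nonincreasing in the discount rate for positive future flows", {
  # per-year schedules so the rate actually bites on both sides
  mk <- function(r) econ_config(discount_rate = r,
                                cost_ai = rep(92285.30, 5),
                                cost_traditional = rep(25174.49, 5))
  npvs <- vapply(c(0, 0.01, 0.03, 0.07, 0.12),
                 function(r) npv(mk(r), 0.5)$npv, numeric(1))
  expect_true(all(diff(npvs) <= 0))
})

test_that("scenario NPVs are ordered in the progression probability", {
  m <- cba_model(study_econ())
  npvs <- vapply(m$scenarios, `[[`, numeric(1), "npv")
  expect_true(all(diff(npvs) > 0))
  pred <- predict(m, pi = c(0, 0.25, 0.5, 0.75, 1))
  expect_true(all(diff(pred$npv) > 0))
  expect_true(all(diff(pred$icer) < 0))  # more effect, same cost
})

test_that("benefit calibration hits a target NPV exactly and keeps ordering", {
  cf <- calibrate_benefit(study_econ(), target_npv = 2093468.31, pi = 0.5)
  expect_equal(npv(cf, 0.5)$npv, 2093468.31, tolerance = 1e-9)
  # component proportions are preserved by the rescaling
  expect_equal(unname(cf$benefit_per_error / sum(cf$benefit_per_error)),
               c(15, 80, 25) / 120)
  expect_lt(npv(cf, 0)$npv, npv(cf, 0.5)$npv)
  expect_lt(npv(cf, 0.5)$npv, npv(cf, 1)$npv)
  expect_error(calibrate_benefit(econ_config(direct_errors_preventable = 1,
                                             comparator_errors_prevented = 1),
                                 1e6, pi = 0), "incremental effect")
})

test_that("econ configs round-trip through YAML and JSON with validation", {
  cf <- econ_config(cost_ai = 400000, near_misses = 25L, mc_seed = 9L)
  y <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(cost_ai = 400000, near_misses = 25,
                        benefit_per_error = as.list(cf$benefit_per_error),
                        mc_seed = 9), y)
  cf_y <- read_econ_config(y)
  expect_equal(cf_y$cost_ai, 400000)
  expect_equal(cf_y$near_misses, 25L)
  expect_equal(cf_y$benefit_per_error, cf$benefit_per_error)
  j <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(discount_rate = 0.05), j, auto_unbox = TRUE)
  expect_equal(read_econ_config(j)$discount_rate, 0.05)
  writeLines('{"not_a_field": 1}', j)
  expect_error(read_econ_config(j), "not_a_field")
  expect_error(econ_config(discount_rate = -0.01), "discount_rate")
  expect_error(econ_config(scenario_pis = c(0, 1.5)), "scenario_pis")
})
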