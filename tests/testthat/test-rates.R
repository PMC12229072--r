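test_that("Clopper-Pearson intervals match the exact binomial test oracle", {
  grid <- expand.grid(x = c(0L, 1L, 5L, 9L, 30L, 50L, 100L),
                      n = c(100L, 9713L, 18762L))
  grid <- grid[grid$x <= grid$n, ]
  for (i in seq_len(nrow(grid))) {
    est <- proportion_ci_cp(grid$x[i], grid$n[i])
    oracle <- binom.test(grid$x[i], grid$n[i])$conf.int
    expect_equal(c(est$ci_low, est$ci_high), as.numeric(oracle),
                 tolerance = 1e-12)
  }
})

test_that("Wilson intervals match the score-test oracle", {
  grid <- expand.grid(x = c(1L, 7L, 28L, 50L), n = c(100L, 9713L, 18762L))
  grid <- grid[grid$x < grid$n, ]
  for (i in seq_len(nrow(grid))) {
    est <- proportion_ci_wilson(grid$x[i], grid$n[i])
    oracle <- prop.test(grid$x[i], grid$n[i], correct = FALSE)$conf.int
    expect_equal(c(est$ci_low, est$ci_high), as.numeric(oracle),
                 tolerance = 1e-9)
  }
})

test_that("the study's text rates reproduce under Clopper-Pearson at printed rounding", {
  post_err <- proportion_ci_cp(5, 18762)
  expect_equal(round(100 * post_err$rate, 3), 0.027)
  expect_equal(round(100 * post_err$ci_low, 3), 0.009)
  expect_equal(round(100 * post_err$ci_high, 3), 0.062)
  pre_nm <- proportion_ci_cp(9, 18767)
  expect_equal(round(100 * pre_nm$ci_low, 3), 0.022)
  expect_equal(round(100 * pre_nm$ci_high, 3), 0.091)
  pre_err <- proportion_ci_cp(1, 18767)
  expect_equal(round(100 * pre_err$rate, 4), 0.0053)
  expect_equal(round(100 * pre_err$ci_high, 3), 0.030)
  post_nm <- proportion_ci_cp(30, 18762)
  expect_equal(round(100 * post_nm$rate, 2), 0.16)
  expect_equal(round(100 * post_nm$ci_low, 2), 0.11)
  expect_equal(round(100 * post_nm$ci_high, 2), 0.23)
})

test_that("the per-checkpoint rates reproduce under the Wilson interval", {
  lat <- proportion_ci_wilson(7, 18762)
  expect_equal(round(100 * lat$ci_low, 3), 0.018)
  expect_equal(round(100 * lat$ci_high, 3), 0.077)
  iol <- proportion_ci_wilson(28, 9713)
  expect_equal(round(100 * iol$rate, 2), 0.29)
  expect_equal(round(100 * iol$ci_low, 2), 0.20)
  expect_equal(round(100 * iol$ci_high, 2), 0.42)
  # Clopper-Pearson would NOT reproduce the laterality lower bound
  expect_equal(round(100 * proportion_ci_cp(7, 18762)$ci_low, 3), 0.015)
})

test_that("interval boundary behaviour and containment invariants hold", {
  expect_identical(proportion_ci_cp(0, 100)$ci_low, 0)
  expect_identical(proportion_ci_cp(100, 100)$ci_high, 1)
  w <- proportion_ci_wilson(50, 100)
  expect_true(w$ci_low < 0.5 && w$ci_high > 0.5)
  expect_equal(w$ci_high - 0.5, 0.5 - w$ci_low, tolerance = 1e-12)
  for (x in c(0L, 1L, 7L, 30L)) {
    cp <- proportion_ci_cp(x, 18762)
    wi <- proportion_ci_wilson(x, 18762)
    expect_true(cp$ci_low <= cp$rate && cp$rate <= cp$ci_high)
    expect_true(wi$ci_low <= wi$rate && wi$rate <= wi$ci_high)
    # the exact interval contains the score interval's point estimate
    expect_true(cp$ci_low <= wi$rate && wi$rate <= cp$ci_high)
    if (x > 0) expect_gt(wi$ci_low, 0)
  }
})

test_that("domain violations raise argument errors", {
  expect_error(proportion_ci_cp(5, 0), "denominator")
  expect_error(proportion_ci_cp(11, 10), "events")
  expect_error(proportion_ci_cp(5, 10, level = 1), "level")
  expect_error(proportion_ci_wilson(-1, 10), "events")
})

test_that("rate_table renders both methods and matches direct recomputation", {
  log <- simulate_cohort(small_sim(n = 2500L, seed = 8L,
                                   p_prep_error_laterality = 0.01,
                                   p_prep_error_iol = 0.01))
  tab <- rate_table(log)
  expect_setequal(unique(tab$method), c("clopper_pearson", "wilson"))
  s <- summarize_cohort(log)
  post_nm <- s$period$near_misses[s$period$period == "post"]
  row <- tab[tab$label == "near_miss_post" & tab$method == "clopper_pearson", ]
  direct <- proportion_ci_cp(post_nm, s$period$n[s$period$period == "post"])
  expect_equal(row$rate, direct$rate)
  expect_equal(row$ci_low, direct$ci_low)
  expect_equal(row$ci_high, direct$ci_high)
  expect_identical(tab$rate[tab$label == "flagged_face_post"][1],
                   sum(s$stage$near_miss[s$stage$stage == "face"] +
                         s$stage$error[s$stage$stage == "face"]) /
                     s$stage$eligible[s$stage$stage == "face"])
  expect_error(rate_table(data.frame()), "empty|columns")
})
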