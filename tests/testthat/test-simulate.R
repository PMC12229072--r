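test_that("invalid configurations are rejected naming the offending field", {
  expect_error(sim_config(n_pre = 0), "n_pre")
  expect_error(sim_config(p_iol = 1.2), "p_iol")
  expect_error(sim_config(adoption_curve = c(0.5, 1.4)), "adoption_curve")
  expect_error(sim_config(p_quality_failure = c(face = 0.1, laterality = 0.1)),
               "p_quality_failure")
  expect_error(sim_config(attempts_mean = c(face = 0.5, laterality = 1, iol = 1)),
               "attempts_mean")
  expect_error(sim_config(p_human_report = -0.1), "p_human_report")
})

test_that("a cohort with no latent preparation errors has no incidents", {
  log <- simulate_cohort(small_sim(p_prep_error_laterality = 0,
                                   p_prep_error_iol = 0))
  expect_identical(nrow(log$cases), 3000L)
  expect_identical(sum(log$cases$near_miss), 0L)
  expect_identical(sum(log$cases$final_error), 0L)
  expect_identical(sum(log$events$outcome %in% c("near_miss", "error")), 0L)
})

test_that("perfect detection converts every latent error into a near miss", {
  log <- simulate_cohort(small_sim(
    n = 4000L,
    p_prep_error_laterality = 0.02, p_prep_error_iol = 0.02,
    adoption_curve = rep(1, 25), p_detect_given_auth = 1,
    p_unlearned_iol = 0, p_quality_failure = c(face = 0, laterality = 0, iol = 0),
    p_correction = 1, p_human_report = 1))
  post <- log$cases[log$cases$period == "post", ]
  latent <- post$latent_error_laterality | post$latent_error_iol
  expect_gt(sum(latent), 0)
  expect_identical(sum(post$final_error), 0L)
  expect_true(all(post$near_miss[latent]))
  expect_identical(sum(log$events$outcome == "error"), 0L)
})

test_that("identical seed and config reproduce the case log exactly", {
  cf <- small_sim(seed = 99L)
  expect_identical(simulate_cohort(cf), simulate_cohort(cf))
  # a different seed moves at least something
  other <- simulate_cohort(small_sim(seed = 100L))
  expect_false(identical(simulate_cohort(cf)$events, other$events))
})

test_that("generated events satisfy the per-event structural invariants", {
  log <- simulate_cohort(small_sim(n = 5000L, p_prep_error_laterality = 0.01,
                                   p_prep_error_iol = 0.02,
                                   p_detect_given_auth = 0.8,
                                   p_correction = 0.9))
  ev <- log$events
  expect_true(all(ev$attempts[!ev$performed] == 0L))
  expect_true(all(ev$outcome[!ev$performed] == "not_performed"))
  expect_true(all(ev$outcome[ev$performed & !ev$quality_ok] == "auth_failure"))
  expect_true(all(ev$ai_flagged[ev$outcome == "near_miss"]))
  expect_true(all(ev$attempts[ev$performed] >= 1L))
  expect_true(all(ev$duration_s >= 0))
  # no IOL stage event without an IOL, and no latent IOL error either
  no_iol <- log$cases$case_id[!log$cases$has_iol]
  expect_identical(sum(ev$stage == "iol" & ev$case_id %in% no_iol), 0L)
  expect_true(all(!log$cases$latent_error_iol[!log$cases$has_iol]))
  # a final error requires an uncorrected latent error
  fe <- log$cases$final_error
  latent <- log$cases$latent_error_laterality | log$cases$latent_error_iol
  expect_true(all(latent[fe]))
})

test_that("per-stage outcome tallies are conserved against eligible cases", {
  log <- simulate_cohort(small_sim(n = 4000L, seed = 3L))
  s <- summarize_cohort(log)
  tot <- s$stage$not_performed + s$stage$successful + s$stage$near_miss +
    s$stage$error + s$stage$auth_failure
  expect_identical(as.integer(tot), as.integer(s$stage$eligible))
  n_post <- sum(log$cases$period == "post")
  expect_identical(s$stage$eligible[s$stage$stage == "face"], n_post)
  expect_identical(s$stage$eligible[s$stage$stage == "iol"],
                   sum(log$cases$has_iol & log$cases$period == "post"))
})

test_that("raising detection probability never hurts, under common random numbers", {
  base <- small_sim(n = 6000L, seed = 21L,
                    p_prep_error_laterality = 0.01, p_prep_error_iol = 0.02,
                    p_correction = 1)
  lo <- base; lo$p_detect_given_auth <- 0.3
  hi <- base; hi$p_detect_given_auth <- 0.9
  s_lo <- summarize_cohort(simulate_cohort(lo))$period
  s_hi <- summarize_cohort(simulate_cohort(hi))$period
  post_lo <- s_lo[s_lo$period == "post", ]
  post_hi <- s_hi[s_hi$period == "post", ]
  expect_gte(post_hi$near_misses, post_lo$near_misses)
  expect_lte(post_hi$final_errors, post_lo$final_errors)
})

test_that("flagged laterality events match the analytic binomial expectation", {
  # choose the latent-error probability so that the expected number of
  # flagged laterality preparations is exactly 7, then compare the
  # replicate mean against the binomial standard error of that mean
  n_post <- 6000L
  cf0 <- sim_config(n_pre = 2L, n_post = n_post, seed = 1L)
  p_eff <- mean(cf0$adoption_curve) *
    (1 - cf0$p_quality_failure[["laterality"]]) * cf0$p_detect_given_auth
  target <- 7
  p_lat <- target / (n_post * p_eff)
  reps <- 30L
  flagged <- vapply(seq_len(reps), function(s) {
    cf <- sim_config(n_pre = 2L, n_post = n_post,
                     p_prep_error_laterality = p_lat, seed = s)
    log <- simulate_cohort(cf)
    sum(log$events$ai_flagged[log$events$stage == "laterality"])
  }, numeric(1))
  se_mean <- sqrt(target) / sqrt(reps)   # Poisson-scale sd of a count of 7
  expect_lt(abs(mean(flagged) - target), 3 * se_mean)
})
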