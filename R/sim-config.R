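#' Configuration for the synthetic surgical case-log generator
#'
#' Bundles and validates every parameter of the two-period cohort simulator.
#' The defaults reproduce the statistical structure of the evaluated cohort:
#' 18 767 pre-implementation and 18 762 post-implementation surgeries, about
#' 51.8% of cases with an intraocular-lens (IOL) implantation, 7.3% of IOL
#' cases involving a lens model the recognition system has not yet learned,
#' and a three-month adoption ramp rising from 84.5% to a 99.4% steady-state
#' authentication rate.
#'
#' Latent preparation-error probabilities default to values anchored to the
#' observed per-opportunity flag rates (about 7 laterality and 30 IOL
#' mismatched preparations per study period). Attempts-to-success are
#' shifted-geometric with the observed means (face 1.13, laterality 1.05,
#' IOL 1.15); per-stage durations are log-normal with the observed mean
#' seconds (11.8, 3.10, 8.57).
#'
#' @param n_pre,n_post number of surgeries in each period.
#' @param p_iol probability a case includes IOL implantation.
#' @param p_prep_error_laterality per-case probability of a latent
#'   wrong-side preparation (misplaced drape/marking).
#' @param p_prep_error_iol per-IOL-case probability of a latent wrong-lens
#'   preparation.
#' @param p_unlearned_iol probability an IOL case involves a lens unknown to
#'   the recognition model; unlearned lenses are never flagged.
#' @param adoption_curve per-month probability that authentication is
#'   performed, indexed by post-period month (`month_index + 1`).
#' @param p_quality_failure named per-stage probability that every capture
#'   attempt fails the image-quality standard (outcome `auth_failure`).
#' @param p_detect_given_auth probability the system flags a latent error
#'   given a successful, quality-passing authentication of a learned item.
#' @param p_correction probability a flagged mismatch is corrected before
#'   surgery (1 models full compliance; lower values model ignored alerts).
#' @param p_human_report pre-implementation probability that staff catch and
#'   report a latent error as a near miss (under-reporting model).
#' @param attempts_mean named per-stage mean attempts-to-success (>= 1);
#'   attempts are `1 + Geometric(1/mean)`.
#' @param duration_mean named per-stage mean authentication seconds (> 0).
#' @param duration_sdlog log-scale standard deviation of the log-normal
#'   duration model.
#' @param seed integer RNG seed; fixes the whole case log.
#' @return an object of class `sim_config` (a validated named list).
#' @seealso [simulate_cohort()], [summarize_cohort()]
#' @export
sim_config <- function(n_pre = 18767L,
                       n_post = 18762L,
                       p_iol = 0.518,
                       p_prep_error_laterality = 4.0e-4,
                       p_prep_error_iol = 3.1e-3,
                       p_unlearned_iol = 0.073,
                       adoption_curve = c(0.845, 0.93, 0.99, rep(0.994, 22)),
                       p_quality_failure = c(face = 0.0025,
                                             laterality = 0.0024,
                                             iol = 0.0066),
                       p_detect_given_auth = 1,
                       p_correction = 1,
                       p_human_report = 0.3,
                       attempts_mean = c(face = 1.13,
                                         laterality = 1.05,
                                         iol = 1.15),
                       duration_mean = c(face = 11.8,
                                         laterality = 3.10,
                                         iol = 8.57),
                       duration_sdlog = 0.5,
                       seed = 1L) {
  check_count(n_pre, "n_pre", positive = TRUE)
  check_count(n_post, "n_post", positive = TRUE)
  check_prob(p_iol, "p_iol")
  check_prob(p_prep_error_laterality, "p_prep_error_laterality")
  check_prob(p_prep_error_iol, "p_prep_error_iol")
  check_prob(p_unlearned_iol, "p_unlearned_iol")
  if (length(adoption_curve) < 1L)
    stop_arg("adoption_curve", "must have at least one month")
  check_prob(adoption_curve, "adoption_curve", len = length(adoption_curve))
  p_quality_failure <- p_quality_failure[STAGES]
  if (anyNA(p_quality_failure))
    stop_arg("p_quality_failure", "must be named for stages face/laterality/iol")
  check_prob(unname(p_quality_failure), "p_quality_failure", len = 3L)
  check_prob(p_detect_given_auth, "p_detect_given_auth")
  check_prob(p_correction, "p_correction")
  check_prob(p_human_report, "p_human_report")
  attempts_mean <- attempts_mean[STAGES]
  if (anyNA(attempts_mean) || any(attempts_mean < 1))
    stop_arg("attempts_mean", "must be named per stage with mean >= 1")
  duration_mean <- duration_mean[STAGES]
  if (anyNA(duration_mean) || any(duration_mean <= 0))
    stop_arg("duration_mean", "must be named per stage with mean > 0")
  check_nonneg(duration_sdlog, "duration_sdlog")
  check_count(seed, "seed")

  structure(list(
    n_pre = as.integer(n_pre), n_post = as.integer(n_post),
    p_iol = p_iol,
    p_prep_error_laterality = p_prep_error_laterality,
    p_prep_error_iol = p_prep_error_iol,
    p_unlearned_iol = p_unlearned_iol,
    adoption_curve = as.numeric(adoption_curve),
    p_quality_failure = p_quality_failure,
    p_detect_given_auth = p_detect_given_auth,
    p_correction = p_correction,
    p_human_report = p_human_report,
    attempts_mean = attempts_mean,
    duration_mean = duration_mean,
    duration_sdlog = duration_sdlog,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic surgical cohort configuration\n")
  cat(sprintf("  surgeries: %d pre / %d post (%d adoption months)\n",
              x$n_pre, x$n_post, length(x$adoption_curve)))
  cat(sprintf("  IOL cases: %.1f%% (unlearned lenses %.1f%%)\n",
              100 * x$p_iol, 100 * x$p_unlearned_iol))
  cat(sprintf("  latent prep errors: laterality %.4f%%, IOL %.4f%%\n",
              100 * x$p_prep_error_laterality, 100 * x$p_prep_error_iol))
  cat(sprintf("  detection | auth: %.2f, correction | flag: %.2f, human report (pre): %.2f\n",
              x$p_detect_given_auth, x$p_correction, x$p_human_report))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
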