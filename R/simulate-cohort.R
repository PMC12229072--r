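#' Simulate a two-period surgical case log
#'
#' Generates a synthetic before/after cohort with the generative structure
#' the incident analysis assumes. Pre-implementation cases carry latent
#' preparation errors that staff catch (and report as near misses) with
#' probability `p_human_report`; uncaught latent errors proceed to surgery
#' as final errors. Post-implementation cases pass through the three
#' authentication checkpoints (face, laterality, IOL): whether
#' authentication is performed follows the monthly adoption ramp, image
#' quality can fail wholesale, latent errors on a performed, quality-passing
#' authentication of a *learned* item are flagged with probability
#' `p_detect_given_auth` and corrected with probability `p_correction`
#' (a corrected flag is a near miss); unlearned IOLs are never flagged.
#' Any latent error that is not corrected becomes a final error.
#'
#' The generator is deterministic for a fixed `seed` and uses a fixed
#' draw order (one vectorised draw per stochastic variable), so two runs
#' under the same seed that differ only in a probability parameter are
#' coupled by common random numbers: raising `p_detect_given_auth` can only
#' convert missed errors into near misses, never the reverse.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `case_log`: a list with
#'   \describe{
#'     \item{cases}{one row per surgery: `case_id`, `period`, `month_index`,
#'       `has_iol`, `unlearned_iol`, `latent_error_laterality`,
#'       `latent_error_iol`, `near_miss`, `final_error`, `reported`.}
#'     \item{events}{one row per eligible post-period authentication stage:
#'       `case_id`, `stage`, `performed`, `attempts`, `duration_s`,
#'       `quality_ok`, `ai_flagged`, `corrected`, `outcome`.}
#'     \item{config}{the generating configuration.}
#'   }
#' @examples
#' log <- simulate_cohort(sim_config(n_pre = 500, n_post = 500, seed = 42))
#' summarize_cohort(log)
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config"))
    config <- do.call(sim_config, as.list(config))
  cf <- config
  n_pre <- cf$n_pre; n_post <- cf$n_post
  n <- n_pre + n_post
  n_months <- length(cf$adoption_curve)

  set.seed(cf$seed)
  period <- rep(c("pre", "post"), c(n_pre, n_post))
  is_post <- period == "post"

  # fixed draw order: every variable is drawn once for all n cases
  month_index <- sample.int(n_months, n, replace = TRUE) - 1L
  has_iol <- stats::runif(n) < cf$p_iol
  latent_lat <- stats::runif(n) < cf$p_prep_error_laterality
  latent_iol <- (stats::runif(n) < cf$p_prep_error_iol) & has_iol
  unlearned <- (stats::runif(n) < cf$p_unlearned_iol) & has_iol
  human_catch <- stats::runif(n) < cf$p_human_report

  stage_draws <- lapply(STAGES, function(st) {
    list(performed = stats::runif(n) < cf$adoption_curve[month_index + 1L],
         quality_ok = stats::runif(n) >= cf$p_quality_failure[[st]],
         detect = stats::runif(n) < cf$p_detect_given_auth,
         correct = stats::runif(n) < cf$p_correction,
         attempts = stats::rgeom(n, prob = 1 / cf$attempts_mean[[st]]) + 1L,
         duration = round(stats::rlnorm(
           n,
           meanlog = log(cf$duration_mean[[st]]) - cf$duration_sdlog^2 / 2,
           sdlog = cf$duration_sdlog), 1))
  })
  names(stage_draws) <- STAGES

  case_id <- sprintf("case_%06d", seq_len(n))

  # post-period stage events
  ev <- vector("list", length(STAGES))
  corrected_by_stage <- matrix(FALSE, n, length(STAGES),
                               dimnames = list(NULL, STAGES))
  for (st in STAGES) {
    eligible <- is_post & (st != "iol" | has_iol)
    d <- stage_draws[[st]]
    latent <- switch(st,
                     face = rep(FALSE, n),
                     laterality = latent_lat,
                     iol = latent_iol)
    learned <- if (st == "iol") !unlearned else rep(TRUE, n)
    performed <- d$performed & eligible
    quality_ok <- !performed | d$quality_ok
    flagged <- performed & quality_ok & latent & learned & d$detect
    corrected <- flagged & d$correct
    corrected_by_stage[, st] <- corrected
    outcome <- classify_outcome(performed, quality_ok, latent, flagged,
                                corrected)
    keep <- which(eligible)
    ev[[match(st, STAGES)]] <- data.frame(
      case_id = case_id[keep],
      stage = st,
      performed = performed[keep],
      attempts = ifelse(performed[keep], d$attempts[keep], 0L),
      duration_s = ifelse(performed[keep], d$duration[keep], 0),
      quality_ok = quality_ok[keep],
      ai_flagged = flagged[keep],
      corrected = corrected[keep],
      outcome = outcome[keep],
      stringsAsFactors = FALSE
    )
  }
  events <- do.call(rbind, ev)
  events <- events[order(events$case_id, match(events$stage, STAGES)), ]
  rownames(events) <- NULL

  # case-level resolution
  latent_any <- latent_lat | latent_iol
  # post: a latent error survives unless its own stage corrected it
  post_uncorrected <- (latent_lat & !corrected_by_stage[, "laterality"]) |
    (latent_iol & !corrected_by_stage[, "iol"])
  post_near_miss <- corrected_by_stage[, "laterality"] |
    corrected_by_stage[, "iol"]
  # pre: staff catch -> reported near miss; otherwise the error proceeds
  pre_caught <- latent_any & human_catch
  final_error <- ifelse(is_post, latent_any & post_uncorrected,
                        latent_any & !human_catch)
  near_miss <- ifelse(is_post, post_near_miss, pre_caught)
  reported <- ifelse(is_post, near_miss | final_error,
                     pre_caught | final_error)

  cases <- data.frame(
    case_id = case_id,
    period = period,
    month_index = ifelse(is_post, month_index, NA_integer_),
    has_iol = has_iol,
    unlearned_iol = unlearned,
    latent_error_laterality = latent_lat,
    latent_error_iol = latent_iol,
    near_miss = as.logical(near_miss),
    final_error = as.logical(final_error),
    reported = as.logical(reported),
    stringsAsFactors = FALSE
  )

  structure(list(cases = cases, events = events, config = cf),
            class = "case_log")
}

#' @export
print.case_log <- function(x, ...) {
  n <- nrow(x$cases)
  cat(sprintf("Synthetic surgical case log: %d cases (%d pre, %d post), %d authentication events\n",
              n, sum(x$cases$period == "pre"), sum(x$cases$period == "post"),
              nrow(x$events)))
  cat(sprintf("  near misses: %d pre / %d post; final errors: %d pre / %d post\n",
              sum(x$cases$near_miss & x$cases$period == "pre"),
              sum(x$cases$near_miss & x$cases$period == "post"),
              sum(x$cases$final_error & x$cases$period == "pre"),
              sum(x$cases$final_error & x$cases$period == "post")))
  invisible(x)
}
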