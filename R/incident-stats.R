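#' Two-period incident counts
#'
#' The atom of every rate and association statistic: event counts and
#' denominators for an exposed/post period (`a`) and a reference/pre
#' period (`b`).
#'
#' @param events_a,n_a events and denominator in the post (exposed) period.
#' @param events_b,n_b events and denominator in the pre (reference) period.
#' @param label optional label for reports.
#' @return an object of class `counts_2x2`.
#' @examples
#' counts_2x2(30, 18762, 9, 18767, label = "near_miss")
#' @export
counts_2x2 <- function(events_a, n_a, events_b, n_b, label = NULL) {
  events_a <- check_count(events_a, "events_a")
  n_a <- check_count(n_a, "n_a", positive = TRUE)
  events_b <- check_count(events_b, "events_b")
  n_b <- check_count(n_b, "n_b", positive = TRUE)
  if (events_a > n_a) stop_arg("events_a", "exceeds its denominator n_a")
  if (events_b > n_b) stop_arg("events_b", "exceeds its denominator n_b")
  structure(list(events_a = events_a, n_a = n_a,
                 events_b = events_b, n_b = n_b,
                 label = label),
            class = "counts_2x2")
}

#' @export
print.counts_2x2 <- function(x, ...) {
  cat(sprintf("2x2 incident counts%s: post %d/%d vs pre %d/%d\n",
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              x$events_a, x$n_a, x$events_b, x$n_b))
  invisible(x)
}

new_rate_estimate <- function(events, denominator, rate, ci_low, ci_high,
                              level, method) {
  structure(list(events = events, denominator = denominator, rate = rate,
                 ci_low = ci_low, ci_high = ci_high, level = level,
                 method = method),
            class = "rate_estimate")
}

check_rate_args <- function(events, denominator, level) {
  events <- check_count(events, "events")
  denominator <- check_count(denominator, "denominator", positive = TRUE)
  if (events > denominator)
    stop_arg("events", "exceeds denominator")
  if (!is.numeric(level) || length(level) != 1L || is.na(level) ||
      level <= 0 || level >= 1)
    stop_arg("level", "must be in (0, 1)")
  list(events = events, denominator = denominator, level = level)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' The exact interval via beta quantiles:
#' lower = `qbeta(alpha/2, x, n - x + 1)` (0 when `x = 0`),
#' upper = `qbeta(1 - alpha/2, x + 1, n - x)` (1 when `x = n`).
#' Conservative coverage; this is the interval behind the study's
#' text-reported incident rates (e.g. 5/18 762 -> 0.027%, 95% CI 0.009%
#' to 0.062%).
#'
#' @param events number of incident cases.
#' @param denominator number of opportunities (surgeries).
#' @param level confidence level, default 0.95.
#' @return a `rate_estimate` with fields `events`, `denominator`, `rate`,
#'   `ci_low`, `ci_high`, `level`, `method`; all rates are proportions.
#' @seealso [proportion_ci_wilson()]
#' @export
proportion_ci_cp <- function(events, denominator, level = 0.95) {
  a <- check_rate_args(events, denominator, level)
  alpha <- 1 - a$level
  lo <- if (a$events == 0L) 0 else
    stats::qbeta(alpha / 2, a$events, a$denominator - a$events + 1)
  hi <- if (a$events == a$denominator) 1 else
    stats::qbeta(1 - alpha / 2, a$events + 1, a$denominator - a$events)
  new_rate_estimate(a$events, a$denominator, a$events / a$denominator,
                    lo, hi, a$level, "clopper_pearson")
}

#' Wilson score binomial confidence interval
#'
#' The score-test interval: with `p = x/n` and `z` the normal quantile,
#' bounds are `(p + z^2/2n +/- z sqrt(p(1-p)/n + z^2/4n^2)) / (1 + z^2/n)`.
#' Strictly inside (0, 1) for `0 < x < n`; this is the interval behind the
#' study's per-checkpoint rates (7/18 762 -> 0.039%, 95% CI 0.018% to
#' 0.077%).
#'
#' @inheritParams proportion_ci_cp
#' @return a `rate_estimate`; see [proportion_ci_cp()].
#' @export
proportion_ci_wilson <- function(events, denominator, level = 0.95) {
  a <- check_rate_args(events, denominator, level)
  z <- stats::qnorm(1 - (1 - a$level) / 2)
  n <- a$denominator
  p <- a$events / n
  denom <- 1 + z^2 / n
  centre <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  new_rate_estimate(a$events, n, p,
                    max(0, (centre - half) / denom),
                    min(1, (centre + half) / denom),
                    a$level, "wilson")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("Incident rate: %d/%d = %s (%d%% CI %s to %s, %s)\n",
              x$events, x$denominator, format_pct(x$rate),
              round(100 * x$level), format_pct(x$ci_low),
              format_pct(x$ci_high),
              c(clopper_pearson = "Clopper-Pearson exact",
                wilson = "Wilson score")[[x$method]]))
  invisible(x)
}

#' Odds ratio with Woolf (logit) confidence interval
#'
#' For post events `a` of `n_a` and pre events `b` of `n_b`, the odds
#' ratio is `(a / (n_a - a)) / (b / (n_b - b))`; the Woolf interval
#' exponentiates `log(OR) +/- z * sqrt(1/a + 1/(n_a - a) + 1/b + 1/(n_b - b))`.
#' The attached two-sided p-value is the Fisher exact test on the same
#' table ([fisher_exact_two_sided()]). All four implied cells must be
#' positive; zero cells raise an error instructing the caller to apply a
#' continuity correction explicitly (no silent +0.5 is ever added).
#'
#' @param counts a [counts_2x2()].
#' @param level confidence level, default 0.95.
#' @return an object of class `odds_ratio_result` with fields
#'   `odds_ratio`, `ci_low`, `ci_high`, `p_two_sided`, `method`, `level`.
#' @examples
#' odds_ratio_woolf(counts_2x2(30, 18762, 9, 18767))  # OR 3.34
#' @export
odds_ratio_woolf <- function(counts, level = 0.95) {
  stopifnot(inherits(counts, "counts_2x2"))
  a <- counts$events_a; c_ <- counts$n_a - counts$events_a
  b <- counts$events_b; d <- counts$n_b - counts$events_b
  if (min(a, b, c_, d) == 0L)
    stop(paste("odds ratio undefined: the 2x2 table has a zero cell;",
               "apply a continuity correction explicitly before calling"),
         call. = FALSE)
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop_arg("level", "must be in (0, 1)")
  or <- (a / c_) / (b / d)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(odds_ratio = or,
                 ci_low = or * exp(-z * se),
                 ci_high = or * exp(z * se),
                 p_two_sided = fisher_exact_two_sided(counts),
                 method = "woolf_logit",
                 level = level,
                 counts = counts),
            class = "odds_ratio_result")
}

#' @export
print.odds_ratio_result <- function(x, ...) {
  cat(sprintf("Odds ratio (post vs pre)%s: %.2f (%d%% CI %.2f to %.2f), Fisher two-sided p = %.2g\n",
              if (is.null(x$counts$label)) "" else
                paste0(" [", x$counts$label, "]"),
              x$odds_ratio, round(100 * x$level), x$ci_low, x$ci_high,
              x$p_two_sided))
  invisible(x)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Self-contained conditional exact test. With margins fixed, the first
#' cell follows a hypergeometric distribution; the two-sided p-value is
#' the sum of hypergeometric probabilities of all tables no more probable
#' than the observed one (the standard "small-p" convention, as in the
#' study's p = 0.00067 for near-miss detection and p = 0.125 for errors).
#'
#' @param counts a [counts_2x2()].
#' @return the two-sided p-value, in (0, 1].
#' @examples
#' fisher_exact_two_sided(counts_2x2(5, 18762, 1, 18767))  # 0.125
#' @export
fisher_exact_two_sided <- function(counts) {
  stopifnot(inherits(counts, "counts_2x2"))
  x <- counts$events_a
  m <- counts$events_a + counts$events_b   # total events
  n_a <- counts$n_a; n_b <- counts$n_b
  if (m == 0L || m == n_a + n_b) return(1)
  support <- max(0L, m - n_b):min(m, n_a)
  dens <- stats::dhyper(support, n_a, n_b, m)
  obs <- stats::dhyper(x, n_a, n_b, m)
  # relative tolerance guards against ties broken by floating-point noise
  min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
}

#' Rate table across periods and checkpoints
#'
#' Renders the per-period, per-checkpoint incident rates with both
#' confidence-interval methods attached, from either a summarised cohort
#' or explicit counts.
#'
#' @param x a `cohort_summary` (from [summarize_cohort()]), a `case_log`,
#'   or a data.frame with columns `label`, `events`, `denominator`.
#' @param level confidence level, default 0.95.
#' @return a data.frame with one row per (label, CI method): columns
#'   `label`, `events`, `denominator`, `rate`, `ci_low`, `ci_high`,
#'   `method`, `level`; rates as proportions.
#' @export
rate_table <- function(x, level = 0.95) {
  if (inherits(x, "case_log")) x <- summarize_cohort(x)
  if (inherits(x, "cohort_summary")) {
    per <- x$period
    rows <- data.frame(
      label = c(paste0("near_miss_", per$period),
                paste0("error_", per$period)),
      events = c(per$near_misses, per$final_errors),
      denominator = rep(per$n, 2L),
      stringsAsFactors = FALSE)
    if (!is.null(x$stage)) {
      st <- x$stage
      rows <- rbind(rows, data.frame(
        label = paste0("flagged_", st$stage, "_post"),
        events = st$near_miss + st$error,
        denominator = st$eligible,
        stringsAsFactors = FALSE))
    }
    x <- rows
  }
  if (!is.data.frame(x) ||
      !all(c("label", "events", "denominator") %in% names(x)))
    stop("`x` must be a case_log, cohort_summary, or data.frame with columns label/events/denominator",
         call. = FALSE)
  if (nrow(x) == 0L) stop("empty input: no counts to tabulate", call. = FALSE)
  out <- lapply(seq_len(nrow(x)), function(i) {
    ests <- list(proportion_ci_cp(x$events[i], x$denominator[i], level),
                 proportion_ci_wilson(x$events[i], x$denominator[i], level))
    do.call(rbind, lapply(ests, function(e) data.frame(
      label = x$label[i], events = e$events, denominator = e$denominator,
      rate = e$rate, ci_low = e$ci_low, ci_high = e$ci_high,
      method = e$method, level = e$level, stringsAsFactors = FALSE)))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
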