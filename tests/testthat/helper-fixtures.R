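# Headline incident counts from the evaluated study, used across tests.
study_counts <- list(
  near_miss = list(a = 30L, na = 18762L, b = 9L, nb = 18767L),
  error = list(a = 5L, na = 18762L, b = 1L, nb = 18767L)
)

study_econ <- function(...) econ_config(...)

# small, fast simulator configuration for unit tests
small_sim <- function(n = 1500L, seed = 11L, ...) {
  sim_config(n_pre = n, n_post = n, seed = seed, ...)
}

# a hand-built two-case log: one reported pre-period near miss, one clean
# post-period case — the smallest input summarize_cohort accepts
tiny_case_log <- function() {
  cases <- data.frame(
    case_id = c("case_000001", "case_000002"),
    period = c("pre", "post"),
    month_index = c(NA_integer_, 0L),
    has_iol = c(TRUE, FALSE),
    unlearned_iol = FALSE,
    latent_error_laterality = FALSE,
    latent_error_iol = c(TRUE, FALSE),
    near_miss = c(TRUE, FALSE),
    final_error = FALSE,
    reported = c(TRUE, FALSE),
    stringsAsFactors = FALSE)
  events <- data.frame(
    case_id = "case_000002",
    stage = c("face", "laterality"),
    performed = TRUE, attempts = 1L, duration_s = c(10.5, 3.1),
    quality_ok = TRUE, ai_flagged = FALSE, corrected = FALSE,
    outcome = "successful", stringsAsFactors = FALSE)
  structure(list(cases = cases, events = events, config = NULL),
            class = "case_log")
}

# independent oracle: exhaustive two-sided Fisher p over all feasible
# first-cell values, summing hypergeometric pmfs computed from factorials
fisher_enumerate <- function(a, na, b, nb) {
  m <- a + b
  if (m == 0 || m == na + nb) return(1)
  support <- max(0, m - nb):min(m, na)
  logp <- vapply(support, function(k) {
    lchoose(na, k) + lchoose(nb, m - k) - lchoose(na + nb, m)
  }, numeric(1))
  p <- exp(logp)
  obs <- p[match(a, support)]
  min(1, sum(p[p <= obs * (1 + 1e-7)]))
}
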