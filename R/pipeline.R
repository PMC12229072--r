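#' Load labelled 2x2 incident counts from CSV
#'
#' Expects a header `label,events_a,n_a,events_b,n_b`; every row is
#' validated into a [counts_2x2()] and validation failures report the
#' offending row.
#'
#' @param path CSV path.
#' @return a named list of `counts_2x2` objects.
#' @export
load_counts <- function(path) {
  if (!file.exists(path))
    stop(sprintf("counts file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("label", "events_a", "n_a", "events_b", "n_b")
  if (!all(req %in% names(df)))
    stop(sprintf("malformed counts file %s: need columns %s", path,
                 paste(req, collapse = ", ")), call. = FALSE)
  if (nrow(df) == 0L)
    stop(sprintf("empty counts file: %s", path), call. = FALSE)
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    out[[i]] <- tryCatch(
      counts_2x2(df$events_a[i], df$n_a[i], df$events_b[i], df$n_b[i],
                 label = df$label[i]),
      error = function(e) stop(sprintf("%s, data row %d (%s): %s", path, i,
                                       df$label[i], conditionMessage(e)),
                               call. = FALSE))
  }
  names(out) <- df$label
  out
}

#' Pipeline run configuration
#'
#' @param mode `"from_counts"` (printed study counts) or
#'   `"from_simulation"` (synthetic cohort).
#' @param counts either a path to a counts CSV (see [load_counts()]) or a
#'   list of [counts_2x2()]; required in `from_counts` mode.
#' @param sim a [sim_config()] or a path to a case-log CSV; required in
#'   `from_simulation` mode.
#' @param econ an [econ_config()] or a path to a YAML/JSON config.
#' @param out_dir output directory for reports (`NULL` = no files
#'   written).
#' @param seed global seed; overrides the simulator's and PSA's seeds.
#' @param ci_method `"cp"`, `"wilson"` or `"both"` for the rate table.
#' @return an object of class `run_config`.
#' @export
run_config <- function(mode = c("from_counts", "from_simulation"),
                       counts = NULL, sim = NULL, econ = econ_config(),
                       out_dir = NULL, seed = 1L,
                       ci_method = c("both", "cp", "wilson")) {
  mode <- match.arg(mode)
  ci_method <- match.arg(ci_method)
  if (mode == "from_counts" && is.null(counts))
    stop_arg("counts", "required in from_counts mode")
  if (mode == "from_simulation" && is.null(sim))
    stop_arg("sim", "required in from_simulation mode")
  if (is.character(econ)) econ <- read_econ_config(econ)
  stopifnot(inherits(econ, "econ_config"))
  seed <- check_count(seed, "seed")
  structure(list(mode = mode, counts = counts, sim = sim, econ = econ,
                 out_dir = out_dir, seed = seed, ci_method = ci_method),
            class = "run_config")
}

#' Run the full evaluation pipeline
#'
#' Orchestrates the three stages end-to-end: obtain incident counts
#' (from a counts CSV, a case-log CSV, or a fresh simulation), compute
#' rate and association statistics, and evaluate the economic model with
#' its scenario grid, tornado sensitivity and Monte Carlo PSA. The run is
#' deterministic given the configuration and seed; when `out_dir` is set,
#' `report.json`, `rates.csv` and `tornado.csv` are written (no
#' timestamps, so identical configurations produce byte-identical
#' reports).
#'
#' @param config a [run_config()].
#' @return an object of class `report_bundle`: incident table (rates and
#'   odds ratios), economic scenario table, PSA summary, and run metadata
#'   (seed, mode, package version).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed

  cohort_summary <- NULL
  if (config$mode == "from_counts") {
    counts <- if (is.character(config$counts)) load_counts(config$counts)
    else config$counts
    rates_in <- do.call(rbind, lapply(counts, function(ct) data.frame(
      label = c(paste0(ct$label, "_post"), paste0(ct$label, "_pre")),
      events = c(ct$events_a, ct$events_b),
      denominator = c(ct$n_a, ct$n_b), stringsAsFactors = FALSE)))
  } else {
    log <- if (is.character(config$sim)) read_case_log(config$sim)
    else {
      sc <- config$sim
      sc$seed <- seed
      simulate_cohort(sc)
    }
    cohort_summary <- summarize_cohort(log)
    counts <- cohort_summary$counts
    rates_in <- NULL
  }

  rates <- if (is.null(rates_in)) rate_table(cohort_summary)
  else rate_table(rates_in)
  if (config$ci_method != "both") {
    keep <- c(cp = "clopper_pearson", wilson = "wilson")[[config$ci_method]]
    rates <- rates[rates$method == keep, ]
    rownames(rates) <- NULL
  }

  assoc <- lapply(counts, function(ct) {
    or <- tryCatch(odds_ratio_woolf(ct), error = function(e) NULL)
    data.frame(label = ct$label %||% NA_character_,
               events_post = ct$events_a, n_post = ct$n_a,
               events_pre = ct$events_b, n_pre = ct$n_b,
               odds_ratio = if (is.null(or)) NA_real_ else or$odds_ratio,
               or_ci_low = if (is.null(or)) NA_real_ else or$ci_low,
               or_ci_high = if (is.null(or)) NA_real_ else or$ci_high,
               fisher_p = fisher_exact_two_sided(ct),
               stringsAsFactors = FALSE)
  })
  assoc <- do.call(rbind, assoc)
  rownames(assoc) <- NULL

  econ_cf <- config$econ
  econ_cf$mc_seed <- seed
  model <- cba_model(econ_cf)
  psa <- monte_carlo_psa(econ_cf, pi = 0.5)

  bundle <- structure(list(
    incident = list(rates = rates, associations = assoc),
    cohort_summary = cohort_summary,
    econ = scenario_frame(model),
    tornado = model$tornado,
    psa = psa[c("n_iterations", "seed", "scenario_pi", "npv_mean",
                "npv_ci_low", "npv_ci_high", "npv_deterministic")],
    meta = list(mode = config$mode, seed = seed,
                ci_method = config$ci_method,
                package_version = as.character(utils::packageVersion("surgsafe")))
  ), class = "report_bundle")

  if (!is.null(config$out_dir)) write_report(bundle, config$out_dir)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("Evaluation report (mode: %s, seed %d)\n\nIncident rates:\n",
              x$meta$mode, x$meta$seed))
  rr <- x$incident$rates
  rr$rate <- format_pct(rr$rate)
  rr$ci_low <- format_pct(rr$ci_low)
  rr$ci_high <- format_pct(rr$ci_high)
  print(rr, row.names = FALSE)
  cat("\nAssociations (post vs pre):\n")
  print(x$incident$associations, row.names = FALSE, digits = 4)
  cat("\nEconomic scenarios:\n")
  print(x$econ, row.names = FALSE, digits = 10)
  cat(sprintf("\nPSA: NPV mean $%.2f, 95%% CI [$%.2f, $%.2f] (%d iterations)\n",
              x$psa$npv_mean, x$psa$npv_ci_low, x$psa$npv_ci_high,
              x$psa$n_iterations))
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits `report.json` (full-precision numbers, no timestamps),
#' `rates.csv` and `tornado.csv` under `out_dir`.
#'
#' @param bundle a `report_bundle` from [run_pipeline()].
#' @param out_dir directory, created if missing.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  json <- list(incident = bundle$incident, econ = bundle$econ,
               psa = bundle$psa, meta = bundle$meta)
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE, na = "null")
  utils::write.csv(bundle$incident$rates, file.path(out_dir, "rates.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(bundle$tornado),
                   file.path(out_dir, "tornado.csv"), row.names = FALSE)
  invisible(out_dir)
}

#' Path to the bundled printed-count fixtures
#'
#' The package ships the study's headline incident counts
#' (`paper_counts.csv`: near-miss and error 2x2 tables) and single-period
#' rate denominators (`paper_rates.csv`: per-checkpoint flagged events)
#' so the whole report can be reproduced with zero downloads.
#'
#' @param file one of `"paper_counts.csv"`, `"paper_rates.csv"`.
#' @return the installed file path.
#' @export
surgsafe_fixture <- function(file = c("paper_counts.csv", "paper_rates.csv")) {
  file <- match.arg(file)
  system.file("extdata", file, package = "surgsafe", mustWork = TRUE)
}
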