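#' Write and read case logs as flat CSV
#'
#' The on-disk format is one row per authentication event for post-period
#' cases (three rows for an IOL case, two otherwise) and one row per case
#' for the pre-implementation period (no authentication stages exist there;
#' `stage` is empty and the outcome column carries the case-level
#' resolution). Columns: `case_id`, `period`, `month_index`, `has_iol`,
#' `unlearned_iol`, `latent_error_laterality`, `latent_error_iol`, `stage`,
#' `performed`, `attempts`, `duration_s`, `quality_ok`, `ai_flagged`,
#' `corrected`, `outcome`, `near_miss`, `final_error`, `reported`.
#' UTF-8, header row, RFC 4180 quoting. `read_case_log()` inverts
#' `write_case_log()` exactly (round-trip identity on cases and events).
#'
#' @param log a `case_log` object.
#' @param path file path for the CSV.
#' @return `write_case_log()` returns `path` invisibly; `read_case_log()`
#'   returns a `case_log` (with `config = NULL`).
#' @export
write_case_log <- function(log, path) {
  if (!inherits(log, "case_log"))
    stop("`log` must be a case_log object", call. = FALSE)
  cases <- log$cases
  events <- log$events

  case_cols <- c("period", "month_index", "has_iol", "unlearned_iol",
                 "latent_error_laterality", "latent_error_iol",
                 "near_miss", "final_error", "reported")
  if (!is.null(events) && nrow(events) > 0L) {
    long <- merge(events, cases, by = "case_id", sort = FALSE)
  } else {
    long <- NULL
  }
  pre <- cases[!cases$case_id %in% (if (is.null(events)) character() else
    events$case_id), , drop = FALSE]
  if (nrow(pre) > 0L) {
    pre_rows <- data.frame(
      case_id = pre$case_id, stage = NA_character_, performed = FALSE,
      attempts = 0L, duration_s = 0, quality_ok = TRUE, ai_flagged = FALSE,
      corrected = pre$near_miss,
      outcome = ifelse(pre$near_miss, "near_miss",
                       ifelse(pre$final_error, "error", "successful")),
      stringsAsFactors = FALSE)
    pre_rows <- cbind(pre_rows, pre[case_cols])
    long <- rbind(long, pre_rows[names(long) %||% names(pre_rows)])
  }
  ord <- order(long$case_id, match(long$stage, STAGES))
  long <- long[ord, c("case_id", "period", "month_index", "has_iol",
                      "unlearned_iol", "latent_error_laterality",
                      "latent_error_iol", "stage", "performed", "attempts",
                      "duration_s", "quality_ok", "ai_flagged", "corrected",
                      "outcome", "near_miss", "final_error", "reported")]
  utils::write.csv(long, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_case_log
#' @export
read_case_log <- function(path) {
  if (!file.exists(path))
    stop(sprintf("case-log file not found: %s", path), call. = FALSE)
  long <- utils::read.csv(path, stringsAsFactors = FALSE,
                          na.strings = "", fileEncoding = "UTF-8")
  req <- c("case_id", "period", "stage", "performed", "outcome",
           "final_error", "reported")
  missing_cols <- setdiff(req, names(long))
  if (length(missing_cols) > 0L)
    stop(sprintf("malformed case log %s: missing column(s) %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  if (nrow(long) == 0L)
    stop(sprintf("empty case log: %s", path), call. = FALSE)
  bad <- which(!long$outcome %in% OUTCOME_LEVELS)
  if (length(bad) > 0L)
    stop(sprintf("malformed case log %s: unknown outcome %s at data row %d",
                 path, dQuote(long$outcome[bad[1]]), bad[1]), call. = FALSE)

  first <- !duplicated(long$case_id)
  cases <- long[first, c("case_id", "period", "month_index", "has_iol",
                         "unlearned_iol", "latent_error_laterality",
                         "latent_error_iol", "near_miss", "final_error",
                         "reported")]
  cases$month_index <- as.integer(cases$month_index)
  rownames(cases) <- NULL
  ev <- long[!is.na(long$stage),
             c("case_id", "stage", "performed", "attempts", "duration_s",
               "quality_ok", "ai_flagged", "corrected", "outcome")]
  ev$attempts <- as.integer(ev$attempts)
  rownames(ev) <- NULL
  structure(list(cases = cases, events = ev, config = NULL),
            class = "case_log")
}
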