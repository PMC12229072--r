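#' Tally a case log into per-period and per-stage incident counts
#'
#' Produces the counts every downstream statistic consumes: per-period
#' case-level tallies (near misses, final errors, latent preparation
#' errors) and, for the post period, per-stage outcome tallies over the
#' five-outcome taxonomy. Outcome categories are conservative: for each
#' stage, `not_performed + successful + near_miss + error + auth_failure`
#' equals the number of cases eligible for that stage (the IOL stage counts
#' only IOL cases).
#'
#' @param log a `case_log` from [simulate_cohort()] or [read_case_log()].
#' @return an object of class `cohort_summary`: a list with
#'   \describe{
#'     \item{period}{data.frame of per-period case tallies.}
#'     \item{stage}{data.frame of post-period per-stage outcome tallies,
#'       with an `eligible` column.}
#'     \item{counts}{named list of [counts_2x2()] objects (`near_miss`,
#'       `error`) ready for rate/odds-ratio statistics, post vs pre.}
#'   }
#' @export
summarize_cohort <- function(log) {
  if (!inherits(log, "case_log"))
    stop("`log` must be a case_log object", call. = FALSE)
  cases <- log$cases
  if (is.null(cases) || nrow(cases) == 0L)
    stop("empty case log: no cases to summarise", call. = FALSE)
  events <- log$events

  per <- lapply(c("pre", "post"), function(p) {
    cc <- cases[cases$period == p, , drop = FALSE]
    data.frame(period = p,
               n = nrow(cc),
               n_iol = sum(cc$has_iol),
               latent_laterality = sum(cc$latent_error_laterality),
               latent_iol = sum(cc$latent_error_iol),
               near_misses = sum(cc$near_miss),
               final_errors = sum(cc$final_error),
               reported = sum(cc$reported),
               stringsAsFactors = FALSE)
  })
  period <- do.call(rbind, per)

  stage <- NULL
  if (!is.null(events) && nrow(events) > 0L) {
    tab <- table(factor(events$stage, levels = STAGES),
                 factor(events$outcome, levels = OUTCOME_LEVELS))
    stage <- as.data.frame.matrix(tab)
    stage <- cbind(stage = rownames(stage), stage,
                   eligible = as.integer(rowSums(tab)))
    rownames(stage) <- NULL
    stage$stage <- as.character(stage$stage)
  }

  pre <- period[period$period == "pre", ]
  post <- period[period$period == "post", ]
  counts <- list(
    near_miss = counts_2x2(post$near_misses, post$n, pre$near_misses, pre$n,
                           label = "near_miss"),
    error = counts_2x2(post$final_errors, post$n, pre$final_errors, pre$n,
                       label = "error")
  )

  structure(list(period = period, stage = stage, counts = counts),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary\n\nPer-period case tallies:\n")
  print(x$period, row.names = FALSE)
  if (!is.null(x$stage)) {
    cat("\nPost-period stage outcomes:\n")
    print(x$stage, row.names = FALSE)
  }
  invisible(x)
}
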