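#' @keywords internal
"_PACKAGE"

# stage labels used throughout: the three authentication checkpoints
STAGES <- c("face", "laterality", "iol")

OUTCOME_LEVELS <- c("not_performed", "successful", "near_miss", "error",
                    "auth_failure")

stop_arg <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field, len = 1L) {
  if (!is.numeric(x) || length(x) != len || anyNA(x) || any(x < 0) || any(x > 1))
    stop_arg(field, sprintf("must be %s in [0, 1]",
                            if (len == 1L) "a probability" else
                              paste(len, "probabilities")))
  invisible(x)
}

check_count <- function(x, field, positive = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && x == round(x) &&
    (if (positive) x > 0 else x >= 0)
  if (!ok) stop_arg(field, if (positive) "must be a positive integer"
                    else "must be a non-negative integer")
  invisible(as.integer(x))
}

check_nonneg <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    stop_arg(field, "must be a non-negative number")
  invisible(as.numeric(x))
}

# percentage formatting that follows the study's mixed precision:
# 3 decimals of a percent below 0.1%, 2 decimals otherwise
format_pct <- function(p) {
  pct <- 100 * p
  ifelse(pct < 0.1, sprintf("%.3f%%", pct), sprintf("%.2f%%", pct))
}
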