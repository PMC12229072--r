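#' Classify a per-stage authentication outcome
#'
#' Maps the state of one authentication attempt onto the five-outcome
#' taxonomy used for every checkpoint (patient face, surgical laterality,
#' intraocular lens): `not_performed`, `successful`, `near_miss`, `error`,
#' `auth_failure`. The taxonomy is mutually exclusive and exhaustive:
#'
#' * authentication never attempted -> `not_performed`;
#' * attempted but no capture met the image-quality standard (surgery
#'   proceeded at the surgeon's discretion) -> `auth_failure`;
#' * a mismatched preparation was flagged and corrected before surgery ->
#'   `near_miss`;
#' * a latent preparation error went to surgery uncorrected (missed, or
#'   flagged but the warning was not acted on) -> `error`;
#' * otherwise -> `successful`.
#'
#' All arguments are vectorised and recycled to a common length; the
#' function is pure and total over logical inputs.
#'
#' @param performed logical; was authentication attempted?
#' @param quality_ok logical; did some capture meet quality standards?
#' @param latent_error logical; was a mismatched item/side actually prepared?
#' @param ai_flagged logical; did the system raise a mismatch alert?
#' @param corrected logical; was the flagged mismatch fixed before surgery?
#' @return character vector of outcome labels (see `Details`).
#' @examples
#' classify_outcome(FALSE, FALSE, FALSE, FALSE, FALSE)   # "not_performed"
#' classify_outcome(TRUE, TRUE, TRUE, TRUE, TRUE)        # "near_miss"
#' classify_outcome(TRUE, TRUE, TRUE, TRUE, FALSE)       # "error"
#' @export
classify_outcome <- function(performed, quality_ok, latent_error,
                             ai_flagged, corrected) {
  n <- max(length(performed), length(quality_ok), length(latent_error),
           length(ai_flagged), length(corrected))
  performed <- rep_len(as.logical(performed), n)
  quality_ok <- rep_len(as.logical(quality_ok), n)
  latent_error <- rep_len(as.logical(latent_error), n)
  ai_flagged <- rep_len(as.logical(ai_flagged), n)
  corrected <- rep_len(as.logical(corrected), n)

  out <- rep("successful", n)
  out[latent_error] <- "error"
  out[ai_flagged & corrected] <- "near_miss"
  out[!quality_ok] <- "auth_failure"
  out[!performed] <- "not_performed"
  out
}
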