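#' @keywords internal
"_PACKAGE"

#' @importFrom stats runif setNames
#' @importFrom utils read.delim write.table
NULL

.log_levels <- c(debug = 1L, info = 2L, warning = 3L, error = 4L)

#' Structured logging to stderr
#'
#' Messages at or above the threshold set by `options(circsrna.verbosity = )`
#' ("debug", "info", "warning" or "error"; default "warning") are written to
#' stderr, prefixed with the level.
#'
#' @param level One of "debug", "info", "warning", "error".
#' @param ... Message parts, pasted with no separator.
#' @return Invisibly, `TRUE` if the message was emitted.
#' @export
circ_log <- function(level = "info", ...) {
  level <- match.arg(level, names(.log_levels))
  threshold <- getOption("circsrna.verbosity", "warning")
  emit <- .log_levels[[level]] >= .log_levels[[threshold]]
  if (emit) {
    message(sprintf("[%s] %s", toupper(level), paste0(...)))
  }
  invisible(emit)
}

# Reverse complement of a plain character vector of DNA strings.
# Used throughout; U already normalized to T upstream.
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", x))
}

# Normalize a nucleotide string: RNA->DNA, upper case. Validation separate.
normalize_nt <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

assert_alphabet <- function(x, what = "sequence", allow_n = TRUE) {
  pat <- if (allow_n) "[^ACGTN]" else "[^ACGT]"
  bad <- stringi::stri_detect_regex(x, pat)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside the %s alphabet (first offender: record %d)",
                 what, if (allow_n) "{A,C,G,T,N}" else "{A,C,G,T}",
                 which(bad)[1]), call. = FALSE)
  }
  invisible(TRUE)
}

#' Convert 1-based inclusive coordinates to BED (0-based half-open)
#'
#' The pipeline's internal frame is 1-based inclusive, so an interval
#' `(start, end)` of length `end - start + 1` becomes the BED pair
#' `(start - 1, end)` with identical length `bedEnd - bedStart`.
#'
#' @param start,end Integer vectors, 1-based inclusive, `end >= start`.
#' @return A data.frame with columns `bed_start`, `bed_end`.
#' @export
to_bed_coords <- function(start, end) {
  stopifnot(all(end >= start), all(start >= 1))
  data.frame(bed_start = as.integer(start) - 1L, bed_end = as.integer(end))
}

#' @rdname to_bed_coords
#' @param bed_start,bed_end Integer vectors in BED convention.
#' @return For `from_bed_coords`, a data.frame with 1-based inclusive
#'   `start`, `end`.
#' @export
from_bed_coords <- function(bed_start, bed_end) {
  stopifnot(all(bed_end > bed_start), all(bed_start >= 0))
  data.frame(start = as.integer(bed_start) + 1L, end = as.integer(bed_end))
}
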