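#' Build an exact-match index over a genome
#'
#' The index supports [locate_matches()]: enumerate every exact placement of
#' a query on either strand of every genome record. Minus-strand placements
#' are reported in plus-strand coordinates, meaning the reverse complement of
#' the query matches the forward genome over the reported interval. The
#' search is overlap-aware (a query occurring at overlapping offsets yields
#' every offset).
#'
#' @param g A `circ_genome` (see [genome()]).
#' @return An object of class `circ_index`.
#' @examples
#' idx <- genome_index(genome(c(chr = "ACGTACGT")))
#' locate_matches(idx, "ACGT")
#' @export
genome_index <- function(g) {
  stopifnot(inherits(g, "circ_genome"))
  structure(
    list(genome = g,
         seqs = unclass(g),
         lengths = genome_lengths(g)),
    class = "circ_index"
  )
}

#' @export
print.circ_index <- function(x, ...) {
  cat(sprintf("circ_index over %d record(s), %d nt total\n",
              length(x$seqs), sum(x$lengths)))
  invisible(x)
}

#' Locate all exact placements of a query sequence
#'
#' @param index A `circ_index`.
#' @param query A single DNA string. Queries containing N (or longer than the
#'   genome record) have no placements by contract.
#' @return A data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive, plus-strand frame) and `strand` ("+" or "-"), zero rows when
#'   the query places nowhere.
#' @export
locate_matches <- function(index, query) {
  stopifnot(inherits(index, "circ_index"), is.character(query), length(query) == 1)
  query <- normalize_nt(query)
  k <- nchar(query)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  if (k == 0 || stringi::stri_detect_regex(query, "[^ACGT]")) return(empty)
  rc <- revcomp(query)
  out <- vector("list", 2L * length(index$seqs))
  j <- 0L
  for (i in seq_along(index$seqs)) {
    subject <- index$seqs[[i]]
    chrom <- names(index$seqs)[i]
    fwd <- stringi::stri_locate_all_fixed(subject, query, overlap = TRUE)[[1]]
    if (!is.na(fwd[1, 1])) {
      j <- j + 1L
      out[[j]] <- data.frame(chrom = chrom, start = fwd[, 1], end = fwd[, 2],
                             strand = "+", stringsAsFactors = FALSE)
    }
    rev <- stringi::stri_locate_all_fixed(subject, rc, overlap = TRUE)[[1]]
    if (!is.na(rev[1, 1])) {
      j <- j + 1L
      out[[j]] <- data.frame(chrom = chrom, start = rev[, 1], end = rev[, 2],
                             strand = "-", stringsAsFactors = FALSE)
    }
  }
  if (j == 0L) return(empty)
  res <- do.call(rbind, out[seq_len(j)])
  res[order(res$chrom, res$start, res$strand), , drop = FALSE]
}

#' Count exact placements of a query on both strands
#'
#' Convenience over [locate_matches()] used e.g. for flank-uniqueness checks.
#'
#' @inheritParams locate_matches
#' @return Integer placement count.
#' @export
count_matches <- function(index, query) {
  nrow(locate_matches(index, query))
}
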