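empty_hits <- function() {
  data.frame(read_id = character(), chrom = character(), strand = character(),
             split_pos = integer(), up_start = integer(), up_end = integer(),
             down_start = integer(), down_end = integer(),
             circ_start = integer(), circ_end = integer(),
             stringsAsFactors = FALSE)
}

#' Find circular-junction evidence in a single read
#'
#' A read spans a circular junction when it can be split into two parts, each
#' at least `min_segment_len` nt, that both match the genome exactly on the
#' same strand of the same record but in inverse genomic order: reading the
#' transcript 5' to 3', the read's first part lies downstream of its second
#' part. On the plus strand that means the first part's placement starts
#' strictly after the second part's placement ends; minus-strand geometry is
#' mirrored so that `circ_start <= circ_end` always, with `circ_start` the
#' 5'-most and `circ_end` the 3'-most genomic position of the circle in the
#' plus-strand frame.
#'
#' Reads that also place contiguously full-length anywhere in the genome are
#' vetoed as linear. At a given split, when both parts place at more than one
#' genomic position the split is discarded as ambiguous (repeat-induced);
#' pairs are emitted only when at least one part places uniquely. Distinct
#' splits describing the same `(circ_start, circ_end)` junction are collapsed
#' to the leftmost split, so counts are per read.
#'
#' @param read A single read sequence (character) or a one-row data.frame
#'   with columns `id`, `sequence`.
#' @param index A `circ_index` from [genome_index()].
#' @param cfg An [analysis_config()].
#' @param read_id Identifier recorded in the hits (default "read1" when
#'   `read` is a bare string).
#' @return A data.frame of junction hits with columns `read_id`, `chrom`,
#'   `strand`, `split_pos` (length of the read's first part), `up_start`,
#'   `up_end` (placement of the first part), `down_start`, `down_end`
#'   (placement of the second part), `circ_start`, `circ_end`.
#' @examples
#' g <- genome(c(chr = strrep("ACGT", 30)))
#' idx <- genome_index(g)
#' find_circular_junctions("ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGT", idx,
#'                         analysis_config())
#' @export
find_circular_junctions <- function(read, index, cfg = analysis_config(),
                                    read_id = NULL) {
  if (is.data.frame(read)) {
    if (is.null(read_id)) read_id <- read$id[1]
    read <- read$sequence[1]
  }
  if (is.null(read_id)) read_id <- "read1"
  seq <- normalize_nt(read)
  hits <- junction_hits_for_sequence(seq, index, cfg)
  if (nrow(hits) == 0) return(empty_hits())
  cbind(data.frame(read_id = read_id, stringsAsFactors = FALSE), hits)
}

# Core per-sequence search; no read_id so results can be memoized across
# duplicate reads. Returns the hit columns minus read_id.
junction_hits_for_sequence <- function(seq, index, cfg) {
  no_hits <- empty_hits()[, -1, drop = FALSE]
  len <- nchar(seq)
  msl <- cfg$min_segment_len
  if (len < 2L * msl) {
    circ_log("debug", "read shorter than 2 x min_segment_len (", len, " nt); skipped")
    return(no_hits)
  }
  # Linear veto: a contiguous full-length placement on either strand.
  if (nrow(locate_matches(index, seq)) > 0) return(no_hits)

  acc <- list()
  n_acc <- 0L
  seen <- character()
  for (s in msl:(len - msl)) {
    p1 <- locate_matches(index, substr(seq, 1L, s))
    if (nrow(p1) == 0) next
    p2 <- locate_matches(index, substr(seq, s + 1L, len))
    if (nrow(p2) == 0) next
    if (nrow(p1) > 1 && nrow(p2) > 1) {
      circ_log("debug", "split ", s, " ambiguous (both parts multi-placed); discarded")
      next
    }
    for (i in seq_len(nrow(p1))) {
      same <- p2$chrom == p1$chrom[i] & p2$strand == p1$strand[i]
      if (!any(same)) next
      for (j in which(same)) {
        strand <- p1$strand[i]
        if (strand == "+") {
          # inverse order: first part strictly downstream of second part
          if (p1$start[i] <= p2$end[j]) next
          circ_start <- p2$start[j]
          circ_end <- p1$end[i]
        } else {
          # minus strand: transcript runs right-to-left in the + frame,
          # so the first part sits at lower + coordinates
          if (p1$end[i] >= p2$start[j]) next
          circ_start <- p1$start[i]
          circ_end <- p2$end[j]
        }
        key <- paste(p1$chrom[i], strand, circ_start, circ_end, sep = ":")
        if (key %in% seen) next
        seen <- c(seen, key)
        n_acc <- n_acc + 1L
        acc[[n_acc]] <- data.frame(
          chrom = p1$chrom[i], strand = strand, split_pos = s,
          up_start = p1$start[i], up_end = p1$end[i],
          down_start = p2$start[j], down_end = p2$end[j],
          circ_start = as.integer(circ_start), circ_end = as.integer(circ_end),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (n_acc == 0L) return(no_hits)
  do.call(rbind, acc)
}

#' Detect circular junctions across a whole sample
#'
#' Runs [find_circular_junctions()] over every read and concatenates the
#' hits. Identical read sequences necessarily produce identical hits, so the
#' per-sequence search is memoized; results are deterministic and
#' independent of read order.
#'
#' @param reads Data.frame with columns `id`, `sequence` (e.g. from
#'   [read_reads_fastq()] or [simulate_reads()]).
#' @inheritParams find_circular_junctions
#' @return A list with elements `hits` (data.frame as in
#'   [find_circular_junctions()], in read order) and `summary` (list:
#'   `total_reads`, `reads_with_hits`).
#' @export
detect_sample <- function(reads, index, cfg = analysis_config()) {
  stopifnot(is.data.frame(reads), all(c("id", "sequence") %in% names(reads)))
  if (nrow(reads) > 0) {
    len <- nchar(reads$sequence)
    if (any(len < 2L * cfg$min_segment_len)) {
      circ_log("warning", sum(len < 2L * cfg$min_segment_len),
               " read(s) shorter than 2 x min_segment_len; junctions cannot",
               " be detected in them")
    }
  }
  seqs <- normalize_nt(reads$sequence)
  useq <- unique(seqs)
  u_of_read <- match(seqs, useq)
  uhits <- lapply(useq, junction_hits_for_sequence, index = index, cfg = cfg)
  nh <- vapply(uhits, nrow, integer(1))
  n_with <- sum(nh[u_of_read] > 0L)
  if (n_with == 0L) {
    hits <- empty_hits()
  } else {
    # concatenate the distinct hit blocks once, then expand per read by
    # row indexing (reads sharing a sequence share a block)
    block <- do.call(rbind, uhits[nh > 0L])
    block_start <- integer(length(useq))
    block_start[nh > 0L] <- cumsum(c(1L, nh[nh > 0L]))[seq_len(sum(nh > 0L))]
    sel <- which(nh[u_of_read] > 0L)   # reads with hits, in read order
    u_sel <- u_of_read[sel]
    row_idx <- sequence(nh[u_sel], from = block_start[u_sel])
    hits <- cbind(
      data.frame(read_id = rep(reads$id[sel], nh[u_sel]),
                 stringsAsFactors = FALSE),
      block[row_idx, , drop = FALSE]
    )
    rownames(hits) <- NULL
  }
  list(hits = hits,
       summary = list(total_reads = nrow(reads), reads_with_hits = n_with))
}

#' Write junction hits as TSV
#' @param hits Hits data.frame from [detect_sample()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hits_tsv <- function(hits, path) {
  cols <- c("read_id", "chrom", "strand", "circ_start", "circ_end", "split_pos")
  utils::write.table(hits[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
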