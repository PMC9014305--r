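#' Scan a sequence for C/D box consensus motifs
#'
#' C/C' boxes match the consensus RUGAUGA (IUPAC R = A or G) and D/D' boxes
#' match CUGA. Scanning is strand-local (the given sequence only), reports
#' every match including overlapping ones, and accepts RNA or DNA input.
#'
#' @param sequence A single RNA/DNA string.
#' @return Data.frame with `motif_class` ("C_box"/"D_box"), `position`
#'   (1-based offset of the match start) and `matched` (the matched
#'   substring, in the normalized DNA alphabet).
#' @examples
#' scan_cdbox_motifs("AUGAUGACCCCUGA")
#' @export
scan_cdbox_motifs <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  seq <- normalize_nt(sequence)
  hits <- list()
  subject <- Biostrings::DNAString(seq)
  cpat <- Biostrings::matchPattern("RTGATGA", subject, fixed = FALSE)
  if (length(cpat)) {
    hits[[1]] <- data.frame(motif_class = "C_box",
                            position = IRanges::start(cpat),
                            matched = as.character(cpat),
                            stringsAsFactors = FALSE)
  }
  dpat <- Biostrings::matchPattern("CTGA", subject, fixed = TRUE)
  if (length(dpat)) {
    hits[[length(hits) + 1L]] <- data.frame(motif_class = "D_box",
                                            position = IRanges::start(dpat),
                                            matched = as.character(dpat),
                                            stringsAsFactors = FALSE)
  }
  if (!length(hits)) {
    return(data.frame(motif_class = character(), position = integer(),
                      matched = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$position, out$motif_class), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count terminal-stem base pairings of a sequence
#'
#' The 5'-terminal window is aligned against the 3'-terminal window from the
#' outside in (base 1 vs the last base, base 2 vs the second-to-last, ...)
#' and consecutive complementary pairs are counted, stopping at the first
#' non-pair; no gaps or bulges are considered. Watson-Crick pairs (A:U/T,
#' G:C) always count; G:U/T wobble pairs count when `count_gu` is TRUE
#' (default, standard RNA duplex chemistry). Note wobble pairing is not
#' preserved under reverse complement (a G:U pair maps to C:A), so only the
#' Watson-Crick score is strand-symmetric.
#'
#' @param sequence A single RNA/DNA string of length >= 2 * `window`.
#' @param window Terminal window length in nt (default 8).
#' @param count_gu Count G:U wobble pairs (default TRUE).
#' @return Integer pairing count in `[0, window]`.
#' @examples
#' terminal_stem_pairs("GGCGCAAAAAAAAAAGCGCC", window = 5)  # 5
#' @export
terminal_stem_pairs <- function(sequence, window = 8L, count_gu = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1, window >= 1)
  seq <- normalize_nt(sequence)
  L <- nchar(seq)
  if (L < 2L * window) {
    stop("sequence shorter than twice the stem window", call. = FALSE)
  }
  five <- substring(seq, 1:window, 1:window)
  three <- substring(seq, L:(L - window + 1L), L:(L - window + 1L))
  wc <- c(A = "T", T = "A", G = "C", C = "G")
  n <- 0L
  for (i in seq_len(window)) {
    a <- five[i]; b <- three[i]
    pair <- (!is.na(wc[a]) && identical(unname(wc[a]), b)) ||
      (count_gu && ((a == "G" && b == "T") || (a == "T" && b == "G")))
    if (!pair) break
    n <- n + 1L
  }
  n
}

#' Call a terminal stem circularizable
#'
#' Loci whose termini can form three or more consecutive base pairings are
#' predicted circularizable; two or fewer pairings predict a locus unlikely
#' to form the terminal stem needed for end joining.
#'
#' @param stem_pairs Integer pairing count(s) from [terminal_stem_pairs()].
#' @param cfg An [analysis_config()].
#' @return Logical vector.
#' @export
classify_circularizable <- function(stem_pairs, cfg = analysis_config()) {
  stem_pairs >= cfg$min_stem_pairs_circular
}

# Extract the strand-aware sequence of a candidate interval.
candidate_sequence <- function(g, chrom, start, end, strand = "+") {
  stopifnot(inherits(g, "circ_genome"))
  if (!chrom %in% names(g)) stop("unknown genome record: ", chrom, call. = FALSE)
  L <- nchar(g[[chrom]])
  if (start < 1 || end > L || end < start) {
    stop(sprintf("interval %d-%d out of bounds for record %s (1-%d)",
                 start, end, chrom, L), call. = FALSE)
  }
  s <- substr(unclass(g)[[chrom]], start, end)
  if (strand == "-") revcomp(s) else s
}

#' Annotate a circRNA candidate as a C/D box sRNA
#'
#' Extracts the candidate's strand-aware sequence, scans it for C/D box
#' motifs and applies the positional rule: a C box must start within the 5'
#' third of the sequence and a D box must end within the 3' third for the
#' locus to be called a C/D box sRNA; the 5'-most qualifying C box and the
#' 3'-most qualifying D box are assigned as C and D, and remaining internal
#' hits become C' (the next C hit after the C box) and D' (the first D hit
#' between C and D). Terminal stem pairing and the circularizability call
#' are reported alongside.
#'
#' @param candidate One candidate row (data.frame with `chrom`,
#'   `circ_start`, `circ_end`, `strand`, optionally `locus_name`).
#' @param g A `circ_genome`.
#' @param cfg An [analysis_config()].
#' @return One-row data.frame: `locus_name`, `is_cdbox`, `c_box`, `c_prime`,
#'   `d_prime`, `d_box` (1-based motif start positions, NA when absent),
#'   `stem_pairs`, `circularizable`.
#' @export
annotate_locus <- function(candidate, g, cfg = analysis_config()) {
  stopifnot(is.data.frame(candidate), nrow(candidate) == 1)
  seq <- candidate_sequence(g, candidate$chrom, candidate$circ_start,
                            candidate$circ_end,
                            if ("strand" %in% names(candidate)) candidate$strand else "+")
  L <- nchar(seq)
  hits <- scan_cdbox_motifs(seq)
  five_third <- floor(L / 3)
  c_hits <- hits[hits$motif_class == "C_box", , drop = FALSE]
  d_hits <- hits[hits$motif_class == "D_box", , drop = FALSE]
  c_ok <- c_hits[c_hits$position <= five_third, , drop = FALSE]
  d_ok <- d_hits[d_hits$position + 4L - 1L >= L - five_third + 1L, , drop = FALSE]
  c_box <- if (nrow(c_ok)) min(c_ok$position) else NA_integer_
  d_box <- if (nrow(d_ok)) max(d_ok$position) else NA_integer_
  c_prime <- NA_integer_
  d_prime <- NA_integer_
  if (!is.na(c_box)) {
    later_c <- c_hits$position[c_hits$position > c_box &
                                 (is.na(d_box) | c_hits$position < d_box)]
    if (length(later_c)) c_prime <- min(later_c)
  }
  if (!is.na(d_box)) {
    inner_d <- d_hits$position[d_hits$position < d_box &
                                 (is.na(c_box) | d_hits$position > c_box)]
    if (length(inner_d)) d_prime <- min(inner_d)
  }
  stem <- if (L >= 2L * cfg$stem_window) {
    terminal_stem_pairs(seq, cfg$stem_window, cfg$count_gu_wobble)
  } else {
    NA_integer_
  }
  data.frame(
    locus_name = if ("locus_name" %in% names(candidate)) candidate$locus_name else NA_character_,
    is_cdbox = !is.na(c_box) && !is.na(d_box),
    c_box = c_box, c_prime = c_prime, d_prime = d_prime, d_box = d_box,
    stem_pairs = stem,
    circularizable = if (is.na(stem)) NA else classify_circularizable(stem, cfg),
    stringsAsFactors = FALSE
  )
}

#' Annotate every candidate in a table
#'
#' Applies [annotate_locus()] row-wise and merges the annotation columns
#' (`is_cdbox` summarised as `cdbox_call`, box positions, `stem_pairs`,
#' `circularizable`) onto the candidate table.
#'
#' @param candidates Candidate data.frame from [aggregate_sample()].
#' @param g A `circ_genome`.
#' @param cfg An [analysis_config()].
#' @return The candidates with annotation columns appended.
#' @export
annotate_candidates <- function(candidates, g, cfg = analysis_config()) {
  if (nrow(candidates) == 0) {
    candidates$cdbox_call <- logical()
    candidates$stem_pairs <- integer()
    candidates$circularizable <- logical()
    return(candidates)
  }
  ann <- do.call(rbind, lapply(seq_len(nrow(candidates)), function(i) {
    annotate_locus(candidates[i, , drop = FALSE], g, cfg)
  }))
  candidates$cdbox_call <- ann$is_cdbox
  candidates$c_box <- ann$c_box
  candidates$c_prime <- ann$c_prime
  candidates$d_prime <- ann$d_prime
  candidates$d_box <- ann$d_box
  candidates$stem_pairs <- ann$stem_pairs
  candidates$circularizable <- ann$circularizable
  candidates
}
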