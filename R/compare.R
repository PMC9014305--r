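#' Reads per kilobase per million mapped reads
#'
#' `count * 1e9 / (total_mapped * gene_length)`, before any flooring. Linear
#' in `count` and invariant under joint scaling of count and library size.
#'
#' @param count Mapped read count(s) for the gene.
#' @param gene_length Gene length(s) in nt, positive.
#' @param total_mapped Total mapped reads in the library, positive.
#' @return Numeric RPKM value(s).
#' @examples
#' compute_rpkm(10, 1000, 1e6)  # 10
#' @export
compute_rpkm <- function(count, gene_length, total_mapped) {
  if (any(gene_length <= 0)) stop("gene_length must be positive", call. = FALSE)
  if (any(total_mapped <= 0)) stop("total_mapped must be positive", call. = FALSE)
  # double arithmetic throughout: integer counts x library sizes overflow
  as.numeric(count) * 1e9 / (as.numeric(total_mapped) * as.numeric(gene_length))
}

#' Apply RPKM flooring and omission filters to an expression table
#'
#' Raw RPKM values below `rpkm_floor` (default 1) are stored as 0; records
#' whose floored RPKM is below `rpkm_min_either` (default 2) in both samples
#' are retained but marked `omitted` and excluded from fold-change calls.
#'
#' @param records Data.frame with columns `gene_id`, `rpkm_wt`, `rpkm_ko`
#'   (raw RPKM; see [expression_table()] to build one from counts).
#' @param cfg An [analysis_config()].
#' @return The records with floored `rpkm_wt`/`rpkm_ko` and a `status`
#'   column (`"omitted"` or `NA` for records still to be classified).
#' @export
apply_expression_filters <- function(records, cfg = analysis_config()) {
  stopifnot(all(c("rpkm_wt", "rpkm_ko") %in% names(records)))
  records$rpkm_wt <- ifelse(records$rpkm_wt < cfg$rpkm_floor, 0, records$rpkm_wt)
  records$rpkm_ko <- ifelse(records$rpkm_ko < cfg$rpkm_floor, 0, records$rpkm_ko)
  records$status <- ifelse(records$rpkm_wt < cfg$rpkm_min_either &
                             records$rpkm_ko < cfg$rpkm_min_either,
                           "omitted", NA_character_)
  records
}

#' Classify a gene's expression fold change between WT and KO
#'
#' The boundary is strict: `up` requires `rpkm_ko > cutoff * rpkm_wt` and
#' `down` requires `rpkm_ko < rpkm_wt / cutoff` (default cutoff 2, i.e.
#' ">2-fold"). A floored 0 on one side with the other side at or above
#' `rpkm_min_either` satisfies the corresponding strict inequality, so such
#' records are called directly. Swapping WT and KO swaps up and down.
#'
#' @param rpkm_wt,rpkm_ko Floored RPKM values (vectors allowed).
#' @param cfg An [analysis_config()].
#' @return Character vector: `"up"`, `"down"` or `"unchanged"`.
#' @examples
#' classify_fold_change(9.05, 0.04)  # "down" after flooring 0.04 to 0
#' @export
classify_fold_change <- function(rpkm_wt, rpkm_ko, cfg = analysis_config()) {
  wt <- ifelse(rpkm_wt < cfg$rpkm_floor, 0, rpkm_wt)
  ko <- ifelse(rpkm_ko < cfg$rpkm_floor, 0, rpkm_ko)
  ifelse(ko > cfg$fold_change_cutoff * wt, "up",
         ifelse(ko < wt / cfg$fold_change_cutoff, "down", "unchanged"))
}

#' Build and classify a WT-vs-KO expression table from counts
#'
#' Computes RPKM for both samples, applies flooring and omission, then
#' classifies the surviving records by fold change.
#'
#' @param gene_id Character vector of gene identifiers.
#' @param length Gene lengths (nt).
#' @param count_wt,count_ko Mapped read counts per gene.
#' @param total_wt,total_ko Total mapped reads in each library.
#' @param cfg An [analysis_config()].
#' @return Data.frame with `gene_id`, `length`, counts, floored RPKM values
#'   and `status` in `{up, down, unchanged, omitted}`.
#' @export
expression_table <- function(gene_id, length, count_wt, count_ko,
                             total_wt, total_ko, cfg = analysis_config()) {
  rec <- data.frame(gene_id = gene_id, length = as.integer(length),
                    count_wt = count_wt, count_ko = count_ko,
                    rpkm_wt = compute_rpkm(count_wt, length, total_wt),
                    rpkm_ko = compute_rpkm(count_ko, length, total_ko),
                    stringsAsFactors = FALSE)
  rec <- apply_expression_filters(rec, cfg)
  keep <- is.na(rec$status)
  rec$status[keep] <- classify_fold_change(rec$rpkm_wt[keep], rec$rpkm_ko[keep], cfg)
  rec
}

#' Classify circRNA depletion in the knockout
#'
#' A locus with no circular reads in WT cannot be assessed
#' (`not_detected_in_wt`, ratio undefined). Otherwise the KO/WT circular
#' read ratio is compared against `depletion_ratio` (default 0.05): below it
#' the locus is `depleted` (absent or strongly reduced in the knockout),
#' otherwise `retained`.
#'
#' @param circ_wt,circ_ko Circular read counts (vectors allowed), >= 0.
#' @param cfg An [analysis_config()].
#' @return Data.frame with `circ_wt`, `circ_ko`, `ratio` (NA when undefined)
#'   and `call` in `{depleted, retained, not_detected_in_wt}`.
#' @examples
#' classify_depletion(395, 7)$call      # depleted (ratio ~0.018)
#' classify_depletion(2023, 1292)$call  # retained (ratio ~0.64)
#' @export
classify_depletion <- function(circ_wt, circ_ko, cfg = analysis_config()) {
  if (any(circ_wt < 0 | circ_ko < 0)) stop("counts must be >= 0", call. = FALSE)
  ratio <- ifelse(circ_wt == 0, NA_real_, circ_ko / circ_wt)
  call <- ifelse(circ_wt == 0, "not_detected_in_wt",
                 ifelse(ratio < cfg$depletion_ratio, "depleted", "retained"))
  data.frame(circ_wt = circ_wt, circ_ko = circ_ko, ratio = ratio,
             call = call, stringsAsFactors = FALSE)
}

#' Compare WT and KO circRNA candidate sets
#'
#' WT candidates that passed filters anchor the report; each is matched to a
#' KO candidate (passed or not) whose representative junction lies within
#' the clustering tolerance on both endpoints, same record and strand. Loci
#' with no KO counterpart get `circ_ko = 0`. Each row carries both samples'
#' circular read counts, the predicted length, and the depletion call.
#'
#' @param candidates_wt,candidates_ko Candidate data.frames from
#'   [aggregate_sample()], derived from the same genome.
#' @param cfg An [analysis_config()].
#' @return Report data.frame: `locus_name`, `chrom`, `strand`, `circ_start`,
#'   `circ_end`, `predicted_length`, `circ_wt`, `circ_ko`, `ratio`, `call`.
#' @export
compare_samples <- function(candidates_wt, candidates_ko,
                            cfg = analysis_config()) {
  wt <- candidates_wt[candidates_wt$passed_filters, , drop = FALSE]
  tol <- cfg$junction_group_tolerance
  circ_ko <- integer(nrow(wt))
  for (i in seq_len(nrow(wt))) {
    m <- candidates_ko$chrom == wt$chrom[i] &
      candidates_ko$strand == wt$strand[i] &
      abs(candidates_ko$circ_start - wt$circ_start[i]) <= tol &
      abs(candidates_ko$circ_end - wt$circ_end[i]) <= tol
    circ_ko[i] <- if (any(m)) sum(candidates_ko$total_count[m]) else 0L
  }
  dep <- classify_depletion(wt$total_count, circ_ko, cfg)
  out <- data.frame(locus_name = wt$locus_name, chrom = wt$chrom,
                    strand = wt$strand, circ_start = wt$circ_start,
                    circ_end = wt$circ_end,
                    predicted_length = wt$predicted_length,
                    circ_wt = wt$total_count, circ_ko = circ_ko,
                    ratio = dep$ratio, call = dep$call,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-base read coverage from contiguous exact placements
#'
#' Each read is placed full-length by exact match on either strand;
#' multi-placed reads contribute fractionally (1/n per placement), unplaced
#' reads contribute nothing. Before normalization the depth sums to the
#' total placed read length. When `normalize_to` (a coverage object from the
#' reference sample) is supplied, depths are scaled by the ratio of total
#' placed reads (reference / this sample), putting e.g. a KO track on the WT
#' scale.
#'
#' @param reads Data.frame with `id`, `sequence`.
#' @param index A `circ_index`.
#' @param normalize_to Optional `circ_coverage` object to scale against.
#' @return A `circ_coverage` object: list with `depth` (named list of
#'   per-record numeric vectors), `placed_reads` (fraction-weighted read
#'   count), and `scale` (applied normalization factor).
#' @export
compute_coverage <- function(reads, index, normalize_to = NULL) {
  depth <- lapply(index$lengths, function(L) numeric(L))
  placed <- 0
  # identical reads place identically; memoize the lookup
  seqs <- normalize_nt(reads$sequence)
  useq <- unique(seqs)
  uplace <- lapply(useq, locate_matches, index = index)
  u_of_read <- match(seqs, useq)
  for (r in seq_len(nrow(reads))) {
    p <- uplace[[u_of_read[r]]]
    n <- nrow(p)
    if (n == 0) next
    placed <- placed + 1
    w <- 1 / n
    for (i in seq_len(n)) {
      ch <- p$chrom[i]
      depth[[ch]][p$start[i]:p$end[i]] <- depth[[ch]][p$start[i]:p$end[i]] + w
    }
  }
  scale <- 1
  if (!is.null(normalize_to)) {
    stopifnot(inherits(normalize_to, "circ_coverage"))
    if (placed > 0) scale <- normalize_to$placed_reads / placed
    depth <- lapply(depth, function(d) d * scale)
  }
  structure(list(depth = depth, placed_reads = placed, scale = scale),
            class = "circ_coverage")
}

#' @export
print.circ_coverage <- function(x, ...) {
  cat(sprintf("circ_coverage: %s placed reads, scale %.4g\n",
              format(x$placed_reads), x$scale))
  invisible(x)
}

#' Write a coverage track as bedGraph
#' @param cov A `circ_coverage` from [compute_coverage()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(cov, path) {
  stopifnot(inherits(cov, "circ_coverage"))
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(cov$depth)) {
    d <- cov$depth[[ch]]
    if (!length(d)) next
    r <- rle(d)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths  # bedGraph is 0-based half-open
    keep <- r$values != 0
    if (any(keep)) {
      writeLines(sprintf("%s\t%d\t%d\t%g", ch, starts[keep], ends[keep],
                         r$values[keep]), con)
    }
  }
  invisible(path)
}
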