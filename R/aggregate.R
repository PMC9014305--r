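#' Predicted circRNA length from its junction coordinates
#'
#' The circular junction `(circ_start, circ_end)` delimits the genomic span
#' between the two homologous read segments, 1-based inclusive, so the
#' predicted circle length is `circ_end - circ_start + 1`.
#'
#' @param circ_start,circ_end Integer vectors of junction coordinates,
#'   `circ_end >= circ_start`.
#' @return Integer vector of predicted lengths (nt).
#' @examples
#' predicted_length(47786, 47847)  # 62
#' @export
predicted_length <- function(circ_start, circ_end) {
  circ_start <- as.integer(circ_start)
  circ_end <- as.integer(circ_end)
  if (any(is.na(circ_start) | is.na(circ_end))) {
    stop("junction coordinates must be non-missing integers", call. = FALSE)
  }
  if (any(circ_end < circ_start)) {
    stop("malformed junction: circ_end < circ_start", call. = FALSE)
  }
  circ_end - circ_start + 1L
}

# Collapse per-read hits to raw junction counts.
tally_junctions <- function(hits) {
  if (nrow(hits) == 0) {
    return(data.frame(chrom = character(), strand = character(),
                      circ_start = integer(), circ_end = integer(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  key <- paste(hits$chrom, hits$strand, hits$circ_start, hits$circ_end,
               sep = "\r")
  tab <- table(key)
  parts <- stringi::stri_split_fixed(names(tab), "\r", simplify = TRUE)
  data.frame(chrom = parts[, 1], strand = parts[, 2],
             circ_start = as.integer(parts[, 3]),
             circ_end = as.integer(parts[, 4]),
             count = as.integer(tab), stringsAsFactors = FALSE)
}

#' Group junction hits into clusters within a coordinate tolerance
#'
#' Raw junctions (distinct `(chrom, strand, circ_start, circ_end)` tuples
#' with per-read counts) are grouped greedily: the highest-count unassigned
#' junction seeds a cluster (ties broken by smaller `circ_start`, then
#' smaller `circ_end`) and absorbs every unassigned junction on the same
#' record and strand whose endpoints both lie within `tol` nt of the seed.
#' The seed is the cluster's representative junction. Each raw junction
#' belongs to exactly one cluster, and the result is independent of input
#' order.
#'
#' @param hits Per-read junction hits (from [detect_sample()]) or an already
#'   tallied data.frame with a `count` column.
#' @param tol Coordinate tolerance in nt (default: the classic +/- 5).
#' @return A data.frame with one row per cluster: `chrom`, `strand`,
#'   `rep_start`, `rep_end`, `n_members`, `total_count`, and a list-column
#'   `members` of per-junction data.frames.
#' @export
cluster_junctions <- function(hits, tol = 5L) {
  stopifnot(tol >= 0)
  raw <- if ("count" %in% names(hits)) {
    as.data.frame(hits, stringsAsFactors = FALSE)
  } else {
    tally_junctions(hits)
  }
  empty <- data.frame(chrom = character(), strand = character(),
                      rep_start = integer(), rep_end = integer(),
                      n_members = integer(), total_count = integer(),
                      stringsAsFactors = FALSE)
  empty$members <- list()
  if (nrow(raw) == 0) return(empty)

  ord <- order(-raw$count, raw$circ_start, raw$circ_end)
  raw <- raw[ord, , drop = FALSE]
  assigned <- rep(FALSE, nrow(raw))
  rows <- list()
  while (!all(assigned)) {
    seed <- which(!assigned)[1]
    member <- !assigned &
      raw$chrom == raw$chrom[seed] & raw$strand == raw$strand[seed] &
      abs(raw$circ_start - raw$circ_start[seed]) <= tol &
      abs(raw$circ_end - raw$circ_end[seed]) <= tol
    assigned[member] <- TRUE
    mem <- raw[member, c("circ_start", "circ_end", "count"), drop = FALSE]
    rownames(mem) <- NULL
    row <- data.frame(chrom = raw$chrom[seed], strand = raw$strand[seed],
                      rep_start = raw$circ_start[seed],
                      rep_end = raw$circ_end[seed],
                      n_members = nrow(mem),
                      total_count = sum(mem$count),
                      stringsAsFactors = FALSE)
    row$members <- list(mem)
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$rep_start, out$rep_end, out$strand), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply count and length filters to junction clusters
#'
#' Total-RNA libraries require at least `min_count_total_rna` circular reads
#' per cluster; small-RNA libraries require `min_count_small_rna` reads and
#' additionally discard candidates with predicted length above
#' `max_predicted_len` (the length filter does not apply to total-RNA
#' libraries). Failed candidates are kept with a reason, not dropped.
#'
#' @param clusters Cluster data.frame from [cluster_junctions()].
#' @param cfg An [analysis_config()].
#' @param library_type `"total"` or `"small"`.
#' @return A candidate data.frame: `locus_name` (NA until assigned), `chrom`,
#'   `strand`, `circ_start`, `circ_end` (representative junction),
#'   `predicted_length`, `total_count`, `passed_filters`, `filter_reason`.
#' @export
filter_clusters <- function(clusters, cfg = analysis_config(),
                            library_type = c("small", "total")) {
  library_type <- match.arg(library_type)
  min_count <- switch(library_type,
                      total = cfg$min_count_total_rna,
                      small = cfg$min_count_small_rna)
  n <- nrow(clusters)
  plen <- if (n) predicted_length(clusters$rep_start, clusters$rep_end) else integer()
  reason <- character(n)
  passed <- rep(TRUE, n)
  if (n) {
    low <- clusters$total_count < min_count
    passed[low] <- FALSE
    reason[low] <- sprintf("count<%d", min_count)
    if (library_type == "small") {
      long <- plen > cfg$max_predicted_len
      passed[long & !low] <- FALSE
      reason[long & !low] <- sprintf("length>%dkb", cfg$max_predicted_len %/% 1000L)
      passed[long & low] <- FALSE
      reason[long & low] <- paste0(reason[long & low], ";length>",
                                   cfg$max_predicted_len %/% 1000L, "kb")
    }
  }
  data.frame(locus_name = rep(NA_character_, n),
             chrom = clusters$chrom, strand = clusters$strand,
             circ_start = clusters$rep_start, circ_end = clusters$rep_end,
             predicted_length = plen,
             total_count = clusters$total_count,
             passed_filters = passed, filter_reason = reason,
             stringsAsFactors = FALSE)
}

# Name candidates by overlap with an annotation table (name, chrom, start,
# end): the representative junction interval must be contained within the
# annotated interval, or reciprocally overlap it by >= 50%.
assign_locus_names <- function(candidates, annotation) {
  if (is.null(annotation) || nrow(candidates) == 0) return(candidates)
  stopifnot(all(c("name", "chrom", "start", "end") %in% names(annotation)))
  for (i in seq_len(nrow(candidates))) {
    cs <- candidates$circ_start[i]; ce <- candidates$circ_end[i]
    same <- annotation$chrom == candidates$chrom[i]
    if (!any(same)) next
    ann <- annotation[same, , drop = FALSE]
    ov <- pmin(ce, ann$end) - pmax(cs, ann$start) + 1L
    clen <- ce - cs + 1L
    alen <- ann$end - ann$start + 1L
    contained <- cs >= ann$start & ce <= ann$end
    reciprocal <- ov >= 0.5 * clen & ov >= 0.5 * alen
    hit <- which(contained | reciprocal)
    if (length(hit)) {
      # prefer the tightest annotated interval
      candidates$locus_name[i] <- ann$name[hit[which.min(alen[hit])]]
    }
  }
  candidates
}

#' Aggregate a sample's junction hits into named circRNA candidates
#'
#' Composition of [cluster_junctions()], [filter_clusters()] and locus
#' naming: candidates whose representative junction is contained within (or
#' reciprocally overlaps at least half of) an annotated interval take its
#' name; the rest are auto-named `circ_<chrom>_<start>_<end>`. Output is
#' sorted by record and junction start, deterministically.
#'
#' @param hits Per-read junction hits (from [detect_sample()]).
#' @inheritParams filter_clusters
#' @param annotation Optional data.frame of named loci (`name`, `chrom`,
#'   `start`, `end`, 1-based inclusive).
#' @return Candidate data.frame as in [filter_clusters()], named and sorted.
#' @export
aggregate_sample <- function(hits, cfg = analysis_config(),
                             library_type = c("small", "total"),
                             annotation = NULL) {
  library_type <- match.arg(library_type)
  clusters <- cluster_junctions(hits, tol = cfg$junction_group_tolerance)
  cands <- filter_clusters(clusters, cfg, library_type)
  cands <- assign_locus_names(cands, annotation)
  auto <- is.na(cands$locus_name)
  cands$locus_name[auto] <- sprintf("circ_%s_%d_%d", cands$chrom[auto],
                                    cands$circ_start[auto], cands$circ_end[auto])
  cands <- cands[order(cands$chrom, cands$circ_start, cands$circ_end), ,
                 drop = FALSE]
  rownames(cands) <- NULL
  cands
}
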