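#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: a prokaryote-scale
#' genome carrying circularized C/D-box-like sRNA loci of 61-71 nt alongside
#' non-circular C/D loci and plain linear genes, sequenced as 51-nt
#' single-end reads in two samples — a wild type and a ligase knockout in
#' which circular-junction reads are depleted to `ko_circ_ratio` of their
#' wild-type abundance.
#'
#' @param genome_len Genome length in nt.
#' @param n_circ_loci Number of planted circular C/D-box-like loci (terminal
#'   stems of >= 3 designed pairings).
#' @param n_noncirc_cd_loci Number of planted non-circular C/D loci (stems
#'   broken to <= 2 pairings).
#' @param n_linear_genes Number of plain linear genes.
#' @param circ_locus_len_range Circular locus length range, nt (inclusive).
#' @param linear_gene_len_range Linear gene length range, nt.
#' @param read_len Read length, nt.
#' @param n_reads_per_sample Reads drawn per sample.
#' @param junction_read_fraction Fraction of a circular locus's reads that
#'   span its junction.
#' @param ko_circ_ratio KO circular-junction-read abundance relative to WT.
#' @param error_rate Per-base substitution error rate (0 keeps truth exact).
#' @param with_rrna_gap Plant one rRNA-like locus carrying a 40-nt internal
#'   segment excluded from read generation (a processing-excision coverage
#'   hole).
#' @param seed Integer seed; all randomness in the generator flows from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(genome_len = 100000L,
                       n_circ_loci = 20L,
                       n_noncirc_cd_loci = 10L,
                       n_linear_genes = 50L,
                       circ_locus_len_range = c(61L, 71L),
                       linear_gene_len_range = c(200L, 600L),
                       read_len = 51L,
                       n_reads_per_sample = 200000L,
                       junction_read_fraction = 0.5,
                       ko_circ_ratio = 0.01,
                       error_rate = 0,
                       with_rrna_gap = TRUE,
                       seed = 1L) {
  cfg <- list(genome_len = as.integer(genome_len),
              n_circ_loci = as.integer(n_circ_loci),
              n_noncirc_cd_loci = as.integer(n_noncirc_cd_loci),
              n_linear_genes = as.integer(n_linear_genes),
              circ_locus_len_range = as.integer(circ_locus_len_range),
              linear_gene_len_range = as.integer(linear_gene_len_range),
              read_len = as.integer(read_len),
              n_reads_per_sample = as.integer(n_reads_per_sample),
              junction_read_fraction = as.numeric(junction_read_fraction),
              ko_circ_ratio = as.numeric(ko_circ_ratio),
              error_rate = as.numeric(error_rate),
              with_rrna_gap = isTRUE(with_rrna_gap),
              seed = as.integer(seed))
  stopifnot(cfg$genome_len > 0, cfg$read_len > 0,
            cfg$n_reads_per_sample >= 0,
            cfg$junction_read_fraction >= 0, cfg$junction_read_fraction <= 1,
            cfg$ko_circ_ratio >= 0, cfg$ko_circ_ratio <= 1,
            cfg$error_rate >= 0, cfg$error_rate < 1,
            diff(cfg$circ_locus_len_range) >= 0,
            cfg$circ_locus_len_range[1] >= 40L)
  structure(cfg, class = "sim_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# GC-rich stem of k nt (drawn from G/C with one random A/T allowed at most).
random_stem <- function(k) {
  paste(sample(c("G", "C", "G", "C", "A", "T"), k, replace = TRUE,
               prob = c(0.35, 0.35, 0.1, 0.1, 0.05, 0.05)), collapse = "")
}

# Build a circular C/D-box-like locus: terminal stem of `pairs` designed
# Watson-Crick pairings (followed by a forced A:A non-pair so the designed
# count is exact), a C box in the 5' third and a D box ending in the 3'
# third.
build_cd_locus <- function(len, pairs) {
  stopifnot(len >= 2 * (pairs + 1) + 20)
  stem5 <- random_stem(pairs)
  stem3 <- revcomp(stem5)
  body_len <- len - 2L * (pairs + 1L)
  cbox <- paste0(sample(c("A", "G"), 1), "TGATGA")
  dbox <- "CTGA"
  # body layout: C box first, D box last, random filler between
  filler <- body_len - nchar(cbox) - nchar(dbox)
  body <- paste0(cbox, if (filler > 0) random_dna(filler) else "", dbox)
  paste0(stem5, "A", body, "A", stem3)
}

place_loci <- function(widths, genome_len, margin = 60L, max_tries = 2000L) {
  starts <- integer(length(widths))
  occ_start <- integer(0)
  occ_end <- integer(0)
  for (i in seq_along(widths)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      s <- sample.int(genome_len - widths[i] - margin, 1) + margin %/% 2L
      e <- s + widths[i] - 1L
      if (!any(s <= occ_end + margin & e >= occ_start - margin)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("could not place loci without overlap; use a larger genome",
           call. = FALSE)
    }
    starts[i] <- s
    occ_start <- c(occ_start, s)
    occ_end <- c(occ_end, e)
  }
  starts
}

#' Simulate a genome with planted loci and a truth table
#'
#' Generates a random background sequence and plants, non-overlapping:
#' circular C/D-box-like loci (GC-rich terminal stem with >= 3 designed
#' Watson-Crick pairings, C box near the 5' end, D box near the 3' end),
#' non-circular C/D loci (same layout, stems broken to <= 2 pairings),
#' plain random linear genes, and optionally one rRNA-like locus whose
#' internal 40-nt segment is excluded from read generation. Loci are
#' assigned random strands. Each locus's terminal flanks (the junction arm
#' sequences) are checked to be unique in the genome across both strands;
#' colliding loci are regenerated, with an error advising a larger genome
#' after bounded retries. Designed stem pairings are verified with
#' [terminal_stem_pairs()] (Watson-Crick mode) at construction.
#'
#' @param cfg A [sim_config()].
#' @return List with `genome` (a `circ_genome`, record "chrSim") and `truth`
#'   (data.frame: `locus_name`, `kind`, `chrom`, `start`, `end`, `strand`,
#'   `length`, `stem_pairs_designed`, `junction_start`, `junction_end`,
#'   `gap_start`, `gap_end`; junction columns are NA for non-circular loci,
#'   gap columns are NA except for the rRNA-like locus).
#' @export
simulate_genome <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  chrom <- "chrSim"
  n_loci <- cfg$n_circ_loci + cfg$n_noncirc_cd_loci + cfg$n_linear_genes +
    as.integer(cfg$with_rrna_gap)

  kinds <- c(rep("circular_cd", cfg$n_circ_loci),
             rep("noncirc_cd", cfg$n_noncirc_cd_loci),
             rep("linear_gene", cfg$n_linear_genes),
             if (cfg$with_rrna_gap) "rrna_like")
  lens <- integer(n_loci)
  for (i in seq_len(n_loci)) {
    lens[i] <- switch(kinds[i],
      circular_cd = ,
      noncirc_cd = sample(cfg$circ_locus_len_range[1]:cfg$circ_locus_len_range[2], 1),
      linear_gene = sample(cfg$linear_gene_len_range[1]:cfg$linear_gene_len_range[2], 1),
      rrna_like = 400L)
  }
  if (sum(lens + 120L) > cfg$genome_len * 0.9) {
    stop("loci do not fit in the genome; use a larger genome", call. = FALSE)
  }

  background <- random_dna(cfg$genome_len)
  starts <- place_loci(lens, cfg$genome_len)
  strands <- sample(c("+", "-"), n_loci, replace = TRUE)

  arm <- cfg$read_len - 20L  # longest junction arm; flank uniqueness unit
  seqs <- character(n_loci)
  stems <- integer(n_loci)
  gseq <- background
  counters <- c(circular_cd = 0L, noncirc_cd = 0L, linear_gene = 0L,
                rrna_like = 0L)
  names_out <- character(n_loci)

  for (i in seq_len(n_loci)) {
    counters[kinds[i]] <- counters[kinds[i]] + 1L
    names_out[i] <- switch(kinds[i],
      circular_cd = sprintf("circCD%02d", counters[kinds[i]]),
      noncirc_cd = sprintf("cdNC%02d", counters[kinds[i]]),
      linear_gene = sprintf("gene%02d", counters[kinds[i]]),
      rrna_like = "rrnaLike01")
    placed <- FALSE
    for (try in 1:50) {
      s <- switch(kinds[i],
        circular_cd = {
          stems[i] <- sample(3:6, 1)
          build_cd_locus(lens[i], stems[i])
        },
        noncirc_cd = {
          stems[i] <- sample(0:2, 1)
          sq <- build_cd_locus(lens[i], max(stems[i], 1L))
          if (stems[i] == 0L) sq <- paste0("A", substr(sq, 2, lens[i] - 1), "A")
          sq
        },
        linear_gene = random_dna(lens[i]),
        rrna_like = random_dna(lens[i]))
      # verify designed stem count exactly (Watson-Crick, no wobble)
      if (kinds[i] %in% c("circular_cd", "noncirc_cd")) {
        got <- terminal_stem_pairs(s, window = 8L, count_gu = FALSE)
        ok_stem <- if (kinds[i] == "circular_cd") got == stems[i] else got <= 2L
        if (!ok_stem) next
        stems[i] <- got
      }
      cand <- paste0(substr(gseq, 1, starts[i] - 1L),
                     if (strands[i] == "-") revcomp(s) else s,
                     substr(gseq, starts[i] + lens[i], cfg$genome_len))
      # flank uniqueness: both terminal arms must occur exactly once
      # genome-wide across strands so junction evidence maps uniquely
      head_arm <- substr(s, 1, arm)
      tail_arm <- substr(s, lens[i] - arm + 1L, lens[i])
      n_head <- stringi::stri_count_fixed(cand, head_arm, overlap = TRUE) +
        stringi::stri_count_fixed(cand, revcomp(head_arm), overlap = TRUE)
      n_tail <- stringi::stri_count_fixed(cand, tail_arm, overlap = TRUE) +
        stringi::stri_count_fixed(cand, revcomp(tail_arm), overlap = TRUE)
      if (n_head == 1L && n_tail == 1L) {
        gseq <- cand
        seqs[i] <- s
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not generate a locus with unique flanks; use a larger genome",
           call. = FALSE)
    }
  }

  ends <- starts + lens - 1L
  truth <- data.frame(
    locus_name = names_out, kind = kinds, chrom = chrom,
    start = starts, end = ends, strand = strands, length = lens,
    stem_pairs_designed = ifelse(kinds %in% c("circular_cd", "noncirc_cd"),
                                 stems, NA_integer_),
    junction_start = ifelse(kinds == "circular_cd", starts, NA_integer_),
    junction_end = ifelse(kinds == "circular_cd", ends, NA_integer_),
    gap_start = NA_integer_, gap_end = NA_integer_,
    stringsAsFactors = FALSE
  )
  if (cfg$with_rrna_gap) {
    i <- which(kinds == "rrna_like")
    gs <- starts[i] + 180L  # internal 40-nt excised segment
    truth$gap_start[i] <- gs
    truth$gap_end[i] <- gs + 39L
  }
  truth <- truth[order(truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  list(genome = genome(setNames(gseq, chrom)), truth = truth)
}

# Transcript-orientation sequence of a truth locus.
locus_transcript <- function(g, rec) {
  candidate_sequence(g, rec$chrom, rec$start, rec$end, rec$strand)
}

apply_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  for (i in seq_along(seqs)) {
    n <- nchar(seqs[i])
    hit <- which(runif(n) < rate)
    if (!length(hit)) next
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    for (p in hit) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Simulate 51-nt reads for one sample
#'
#' Reads are drawn from the planted loci with equal per-locus abundance. A
#' circular locus emits junction-spanning reads (the read runs off the
#' transcript's 3' end and continues at its 5' end, with both arms at least
#' `min_arm` nt) with probability `junction_read_fraction`, and ordinary
#' body reads otherwise. In the KO sample the junction-read abundance of
#' circular loci is multiplied by `ko_circ_ratio`; all other abundances are
#' unchanged. Reads from minus-strand loci are reverse-complemented; the
#' rRNA-like locus never yields reads overlapping its excised segment.
#' Per-base substitution errors are applied at `error_rate`.
#'
#' @param g A `circ_genome` from [simulate_genome()].
#' @param truth Truth table from [simulate_genome()].
#' @param cfg A [sim_config()].
#' @param sample_name `"WT"` or `"KO"`.
#' @param min_arm Minimum junction-arm length in nt (default 20, matching
#'   the detector's minimum segment length).
#' @return List with `reads` (data.frame `id`, `sequence`) and `provenance`
#'   (data.frame `id`, `locus_name`, `kind`, `is_junction`).
#' @export
simulate_reads <- function(g, truth, cfg = sim_config(),
                           sample_name = c("WT", "KO"), min_arm = 20L) {
  sample_name <- match.arg(sample_name)
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + if (sample_name == "WT") 104729L else 224737L)
  n <- cfg$n_reads_per_sample
  rl <- cfg$read_len
  empty <- list(reads = data.frame(id = character(), sequence = character(),
                                   stringsAsFactors = FALSE),
                provenance = data.frame(id = character(), locus_name = character(),
                                        kind = character(), is_junction = logical(),
                                        stringsAsFactors = FALSE))
  if (n == 0) return(empty)

  usable <- truth[truth$length >= rl, , drop = FALSE]
  if (nrow(usable) == 0) stop("no locus is long enough to yield reads", call. = FALSE)
  txs <- vapply(seq_len(nrow(usable)), function(i) {
    locus_transcript(g, usable[i, , drop = FALSE])
  }, character(1))

  jf <- cfg$junction_read_fraction
  is_circ <- usable$kind == "circular_cd"
  # per-locus sampling weights: 1 per locus, circular split junction/body;
  # KO scales the junction share by ko_circ_ratio
  jw <- ifelse(is_circ, jf * (if (sample_name == "KO") cfg$ko_circ_ratio else 1), 0)
  bw <- ifelse(is_circ, 1 - jf, 1)
  w <- c(jw, bw)
  pick <- sample.int(2L * nrow(usable), n, replace = TRUE, prob = w / sum(w))
  li <- ((pick - 1L) %% nrow(usable)) + 1L
  is_j <- pick <= nrow(usable)

  arms <- min_arm:(rl - min_arm)
  seqs <- character(n)
  for (r in seq_len(n)) {
    tx <- txs[li[r]]
    L <- nchar(tx)
    if (is_j[r]) {
      a <- if (length(arms) == 1) arms else sample(arms, 1)
      seqs[r] <- paste0(substr(tx, L - a + 1L, L), substr(tx, 1L, rl - a))
    } else {
      rec <- usable[li[r], ]
      repeat {
        s <- sample.int(L - rl + 1L, 1)
        if (is.na(rec$gap_start)) break
        # transcript coords of the excised segment (plus-strand locus here;
        # minus-strand handled by mapping genome gap into transcript frame)
        gs <- if (rec$strand == "+") rec$gap_start - rec$start + 1L else rec$end - rec$gap_end + 1L
        ge <- gs + (rec$gap_end - rec$gap_start)
        if (s > ge || s + rl - 1L < gs) break
      }
      seqs[r] <- substr(tx, s, s + rl - 1L)
    }
  }
  seqs <- apply_errors(seqs, cfg$error_rate)
  ids <- sprintf("%s_r%06d_%s", sample_name, seq_len(n),
                 ifelse(is_j, "J", "L"))
  list(reads = data.frame(id = ids, sequence = seqs, stringsAsFactors = FALSE),
       provenance = data.frame(id = ids, locus_name = usable$locus_name[li],
                               kind = usable$kind[li], is_junction = is_j,
                               stringsAsFactors = FALSE))
}

#' Write / read the simulation truth table as TSV
#'
#' The round trip is lossless: `read_truth(emit_truth(truth, path))` equals
#' `truth` column for column.
#'
#' @param truth Truth data.frame from [simulate_genome()].
#' @param path Output path.
#' @return `emit_truth` invisibly returns `path`; `read_truth` returns the
#'   data.frame.
#' @export
emit_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname emit_truth
#' @export
read_truth <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in c("start", "end", "length", "stem_pairs_designed",
                "junction_start", "junction_end", "gap_start", "gap_end")) {
    if (col %in% names(out)) out[[col]] <- as.integer(out[[col]])
  }
  out
}
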