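#' Construct a genome object from named sequences
#'
#' A genome is a named character vector of upper-case DNA sequences (class
#' `circ_genome`), the coordinate frame for every junction position in the
#' pipeline (1-based inclusive). U is normalized to T; characters outside
#' {A,C,G,T,N} are rejected; record names must be unique and non-empty.
#'
#' @param sequences Named character vector (or named list) of sequences.
#' @return A `circ_genome` object.
#' @examples
#' g <- genome(c(chr = "ACGUacgt"))
#' unclass(g)
#' @export
genome <- function(sequences) {
  seqs <- vapply(sequences, as.character, character(1))
  if (length(seqs) == 0) stop("no records", call. = FALSE)
  nm <- names(seqs)
  if (is.null(nm) || any(!nzchar(nm))) {
    stop("genome records must be named", call. = FALSE)
  }
  if (anyDuplicated(nm)) stop("duplicate genome record names", call. = FALSE)
  if (any(!nzchar(seqs))) stop("empty genome sequence", call. = FALSE)
  seqs <- normalize_nt(seqs)
  assert_alphabet(seqs, what = "genome")
  structure(seqs, class = "circ_genome")
}

#' @export
print.circ_genome <- function(x, ...) {
  cat(sprintf("circ_genome with %d record(s):\n", length(x)))
  for (i in seq_along(x)) {
    cat(sprintf("  %s  %d nt\n", names(x)[i], nchar(x[[i]])))
  }
  invisible(x)
}

#' Genome record lengths
#' @param g A `circ_genome`.
#' @return Named integer vector of sequence lengths (nt).
#' @export
genome_lengths <- function(g) {
  stopifnot(inherits(g, "circ_genome"))
  setNames(nchar(unclass(g)), names(g))
}

#' Read a reference genome from FASTA
#'
#' @param path Path to a (multi-)FASTA file.
#' @return A `circ_genome` with normalized alphabet (U to T, upper case).
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) stop("FASTA parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0) stop("no records in FASTA file '", path, "'", call. = FALSE)
  nm <- sub("\\s.*$", "", names(set))
  genome(setNames(as.character(set), nm))
}

#' Write a genome to FASTA
#' @param g A `circ_genome`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genome_fasta <- function(g, path) {
  stopifnot(inherits(g, "circ_genome"))
  set <- Biostrings::DNAStringSet(unclass(g))
  Biostrings::writeXStringSet(set, path, format = "fasta")
  invisible(path)
}

#' Read sequencing reads from FASTQ
#'
#' Qualities are parsed (and validated against sequence lengths) but not used
#' for filtering: inputs are assumed adapter- and quality-trimmed upstream.
#' A warning is logged when read lengths vary wildly (max > 2x min), since
#' the junction search expects reads of roughly one nominal length.
#'
#' @param path Path to an uncompressed or gzipped FASTQ file.
#' @return A data.frame with columns `id` (character) and `sequence`
#'   (upper-case DNA, possibly containing N), in file order.
#' @export
read_reads_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  n <- length(lines)
  if (n %% 4L != 0L) {
    stop(sprintf("FASTQ parse error in '%s': truncated record %d", path,
                 n %/% 4L + 1L), call. = FALSE)
  }
  if (n == 0L) {
    return(data.frame(id = character(), sequence = character(),
                      stringsAsFactors = FALSE))
  }
  heads <- lines[seq(1L, n, by = 4L)]
  seqs <- lines[seq(2L, n, by = 4L)]
  seps <- lines[seq(3L, n, by = 4L)]
  quals <- lines[seq(4L, n, by = 4L)]
  bad <- which(!startsWith(heads, "@") | !startsWith(seps, "+"))
  if (length(bad)) {
    stop(sprintf("FASTQ parse error in '%s': malformed record %d", path,
                 bad[1]), call. = FALSE)
  }
  mism <- which(nchar(seqs) != nchar(quals))
  if (length(mism)) {
    stop(sprintf(paste0("FASTQ parse error in '%s': sequence/quality length",
                        " mismatch in record %d"), path, mism[1]),
         call. = FALSE)
  }
  seqs <- normalize_nt(seqs)
  assert_alphabet(seqs, what = paste0("FASTQ '", path, "'"))
  reads <- data.frame(
    id = sub("\\s.*$", "", substring(heads, 2L)),
    sequence = seqs,
    stringsAsFactors = FALSE
  )
  if (nrow(reads) > 0) {
    len <- nchar(reads$sequence)
    if (max(len) > 2L * min(len)) {
      circ_log("warning", "read lengths vary wildly (", min(len), "-", max(len),
               " nt); inputs are expected pre-trimmed to a nominal length")
    }
  }
  reads
}

#' Write reads to FASTQ
#'
#' Qualities are synthetic (constant 'I', Phred 40): simulated reads carry no
#' quality model and the pipeline never filters on quality.
#'
#' @param reads Data.frame with columns `id`, `sequence`.
#' @param path Output path (".gz" suffix compresses).
#' @return Invisibly, `path`.
#' @export
write_reads_fastq <- function(reads, path) {
  stopifnot(is.data.frame(reads), all(c("id", "sequence") %in% names(reads)))
  con <- if (endsWith(path, ".gz")) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (nrow(reads)) {
    writeLines(as.vector(rbind(paste0("@", reads$id), reads$sequence, "+",
                               strrep("I", nchar(reads$sequence)))), con)
  }
  invisible(path)
}

#' Write circRNA candidates as TSV / BED6
#'
#' The TSV mirrors the candidate report: one row per candidate with locus
#' name, representative junction coordinates (1-based inclusive), predicted
#' length, strand, circular read count, filter status, and (when annotated)
#' the C/D box call and terminal stem pairing count. BED6 output converts to
#' 0-based half-open coordinates; the score column carries the circular read
#' count (capped at 1000 per BED convention).
#'
#' @param candidates Candidate data.frame from [aggregate_sample()] (columns
#'   `cdbox_call` and `stem_pairs` are optional and written as NA when absent).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_candidates_tsv <- function(candidates, path) {
  cols <- c("locus_name", "chrom", "junction_start", "junction_end",
            "predicted_length", "strand", "circ_read_count", "passed_filters",
            "cdbox_call", "stem_pairs")
  out <- as.data.frame(candidates, stringsAsFactors = FALSE)
  if (!"junction_start" %in% names(out) && "circ_start" %in% names(out)) {
    out$junction_start <- out$circ_start
    out$junction_end <- out$circ_end
  }
  if (!"circ_read_count" %in% names(out) && "total_count" %in% names(out)) {
    out$circ_read_count <- out$total_count
  }
  for (col in cols) if (!col %in% names(out)) out[[col]] <- rep(NA, nrow(out))
  utils::write.table(out[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_candidates_tsv
#' @export
write_bed <- function(candidates, path) {
  out <- as.data.frame(candidates, stringsAsFactors = FALSE)
  if (!"junction_start" %in% names(out) && "circ_start" %in% names(out)) {
    out$junction_start <- out$circ_start
    out$junction_end <- out$circ_end
  }
  if (!"circ_read_count" %in% names(out) && "total_count" %in% names(out)) {
    out$circ_read_count <- out$total_count
  }
  if (nrow(out) == 0) {
    file.create(path)
    return(invisible(path))
  }
  bed <- data.frame(
    chrom = out$chrom,
    start = as.integer(out$junction_start) - 1L,
    end = as.integer(out$junction_end),
    name = if ("locus_name" %in% names(out)) out$locus_name else ".",
    score = pmin(as.integer(out$circ_read_count), 1000L),
    strand = if ("strand" %in% names(out)) out$strand else ".",
    stringsAsFactors = FALSE
  )
  bed$name[is.na(bed$name)] <- "."
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a candidate TSV written by [write_candidates_tsv()]
#' @param path Path to the TSV.
#' @return A data.frame with the report columns.
#' @export
read_candidates_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Packaged catalog of T. kodakarensis circular RNA loci
#'
#' A catalog of 31 circular RNA loci identified in Thermococcus kodakarensis
#' KOD1 small-RNA sequencing of a wild-type strain and an ATP-dependent
#' RNA-ligase (tk1545) knockout. Columns: `locus`, `category` (cdbox, ncRNA,
#' protein_coding, tRNA_intron, rRNA), circular junction coordinates
#' `circ_start`/`circ_end` (1-based inclusive on the NC_006624.1 frame),
#' `predicted_length` (nt), aligned and circular small-RNA read counts for
#' both strains (`aligned_wt`, `circ_wt`, `aligned_ko`, `circ_ko`), and the
#' circular read counts observed in the matching total-RNA libraries
#' (`total_circ_wt`, `total_circ_ko`).
#'
#' @return A 31-row data.frame.
#' @examples
#' cat31 <- tk_circ_catalog()
#' nrow(cat31)
#' @export
tk_circ_catalog <- function() {
  path <- system.file("extdata", "tk_circRNA_catalog.tsv", package = "circsrna",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
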