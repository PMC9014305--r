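# Independent brute-force oracles. These deliberately avoid the package's
# engine (stringi fixed search / Biostrings matchPattern) and recompute
# everything with naive base-R string enumeration.

rc_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(chartr("ACGTN", "TGCAN", strsplit(s, "", fixed = TRUE)[[1]])),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Every exact placement of q in genome gseqs (named character vector),
# both strands, by scanning all start offsets.
oracle_locate <- function(gseqs, q) {
  k <- nchar(q)
  out <- data.frame(chrom = character(), start = integer(), end = integer(),
                    strand = character(), stringsAsFactors = FALSE)
  if (k == 0 || grepl("[^ACGT]", q)) return(out)
  qr <- rc_chr(q)
  for (ch in names(gseqs)) {
    g <- gseqs[[ch]]
    L <- nchar(g)
    if (L < k) next
    starts <- seq_len(L - k + 1L)
    wins <- substring(g, starts, starts + k - 1L)
    f <- starts[wins == q]
    r <- starts[wins == qr]
    if (length(f)) out <- rbind(out, data.frame(chrom = ch, start = f,
                                                end = f + k - 1L, strand = "+",
                                                stringsAsFactors = FALSE))
    if (length(r)) out <- rbind(out, data.frame(chrom = ch, start = r,
                                                end = r + k - 1L, strand = "-",
                                                stringsAsFactors = FALSE))
  }
  out
}

# Brute-force split x scan junction enumerator implementing the documented
# policy: full-length linear veto; both parts >= msl; splits with both parts
# multi-placed are discarded; pairs need at least one uniquely placed part,
# same chrom and strand, inverse order; per-read dedup keeps the leftmost
# split for each distinct junction.
oracle_junctions <- function(seq, gseqs, msl = 20L) {
  none <- data.frame(strand = character(), split_pos = integer(),
                     chrom = character(), circ_start = integer(),
                     circ_end = integer(), stringsAsFactors = FALSE)
  len <- nchar(seq)
  if (len < 2L * msl) return(none)
  if (nrow(oracle_locate(gseqs, seq)) > 0) return(none)
  found <- none
  for (s in msl:(len - msl)) {
    p1 <- oracle_locate(gseqs, substr(seq, 1, s))
    p2 <- oracle_locate(gseqs, substr(seq, s + 1, len))
    if (nrow(p1) == 0 || nrow(p2) == 0) next
    if (nrow(p1) > 1 && nrow(p2) > 1) next
    for (i in seq_len(nrow(p1))) for (j in seq_len(nrow(p2))) {
      if (p1$chrom[i] != p2$chrom[j] || p1$strand[i] != p2$strand[j]) next
      if (p1$strand[i] == "+") {
        if (!(p1$start[i] > p2$end[j])) next
        cs <- p2$start[j]; ce <- p1$end[i]
      } else {
        if (!(p1$end[i] < p2$start[j])) next
        cs <- p1$start[i]; ce <- p2$end[j]
      }
      dup <- found$chrom == p1$chrom[i] & found$strand == p1$strand[i] &
        found$circ_start == cs & found$circ_end == ce
      if (any(dup)) next
      found <- rbind(found, data.frame(strand = p1$strand[i], split_pos = s,
                                       chrom = p1$chrom[i],
                                       circ_start = cs, circ_end = ce,
                                       stringsAsFactors = FALSE))
    }
  }
  found
}

# Canonical form of a junction-hit table for set comparison.
junction_key <- function(df) {
  if (nrow(df) == 0) return(character())
  sort(paste(df$chrom, df$strand, df$split_pos, df$circ_start, df$circ_end,
             sep = ":"))
}

# Naive sliding-window motif oracle for the C/D box consensus.
oracle_cdbox <- function(seq) {
  seq <- chartr("Uu", "Tt", toupper(seq))
  n <- nchar(seq)
  hits <- data.frame(motif_class = character(), position = integer(),
                     stringsAsFactors = FALSE)
  for (p in seq_len(max(n - 6, 0))) {
    w <- substr(seq, p, p + 6)
    if (substr(w, 1, 1) %in% c("A", "G") && substr(w, 2, 7) == "TGATGA") {
      hits <- rbind(hits, data.frame(motif_class = "C_box", position = p,
                                     stringsAsFactors = FALSE))
    }
  }
  for (p in seq_len(max(n - 3, 0))) {
    if (substr(seq, p, p + 3) == "CTGA") {
      hits <- rbind(hits, data.frame(motif_class = "D_box", position = p,
                                     stringsAsFactors = FALSE))
    }
  }
  hits
}

# Build a genome string with a planted locus at a known position.
plant_locus <- function(background, locus, at, strand = "+") {
  ls <- if (strand == "-") rc_chr(locus) else locus
  paste0(substr(background, 1, at - 1), ls,
         substr(background, at + nchar(locus), nchar(background)))
}
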