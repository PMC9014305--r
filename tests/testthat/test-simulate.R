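test_that("simulate_genome is deterministic and honors the truth contract", {
  sc <- sim_config(genome_len = 30000, n_circ_loci = 8, n_noncirc_cd_loci = 5,
                   n_linear_genes = 10, n_reads_per_sample = 0, seed = 81)
  a <- simulate_genome(sc)
  b <- simulate_genome(sc)
  expect_identical(unclass(a$genome), unclass(b$genome))
  expect_identical(a$truth, b$truth)

  tr <- a$truth
  expect_identical(sum(tr$kind == "circular_cd"), 8L)
  expect_identical(sum(tr$kind == "noncirc_cd"), 5L)
  expect_identical(sum(tr$kind == "linear_gene"), 10L)
  expect_identical(sum(tr$kind == "rrna_like"), 1L)
  expect_true(all(tr$end - tr$start + 1L == tr$length))

  circ <- tr[tr$kind == "circular_cd", ]
  expect_true(all(circ$stem_pairs_designed >= 3))
  expect_identical(circ$junction_start, circ$start)
  expect_identical(circ$junction_end, circ$end)
  expect_true(all(circ$length >= 61 & circ$length <= 71))
  noncirc <- tr[tr$kind == "noncirc_cd", ]
  expect_true(all(noncirc$stem_pairs_designed <= 2))
  expect_true(all(is.na(noncirc$junction_start)))

  # designed stem counts match what the scorer measures on the transcript
  g <- a$genome
  for (i in which(tr$kind %in% c("circular_cd", "noncirc_cd"))) {
    s <- unclass(g)[[tr$chrom[i]]]
    seq <- substr(s, tr$start[i], tr$end[i])
    if (tr$strand[i] == "-") seq <- rc_chr(seq)
    expect_identical(terminal_stem_pairs(seq, 8, count_gu = FALSE),
                     tr$stem_pairs_designed[i], info = tr$locus_name[i])
  }

  # loci never overlap
  tr2 <- tr[order(tr$start), ]
  expect_true(all(tr2$start[-1] > tr2$end[-nrow(tr2)]))
})

test_that("impossible placements raise an error suggesting a larger genome", {
  expect_error(simulate_genome(sim_config(genome_len = 2000, n_circ_loci = 10,
                                          n_noncirc_cd_loci = 0,
                                          n_linear_genes = 10, seed = 1)),
               "larger genome")
})

test_that("read simulation respects sample geometry and provenance", {
  sc <- sim_config(genome_len = 20000, n_circ_loci = 4, n_noncirc_cd_loci = 2,
                   n_linear_genes = 5, n_reads_per_sample = 1500, seed = 82)
  sim <- simulate_genome(sc)
  wt <- simulate_reads(sim$genome, sim$truth, sc, "WT")
  expect_identical(nrow(wt$reads), 1500L)
  expect_true(all(nchar(wt$reads$sequence) == 51L))
  expect_identical(wt$reads$id, wt$provenance$id)
  # junction reads only ever come from circular loci
  jk <- wt$provenance$kind[wt$provenance$is_junction]
  expect_true(all(jk == "circular_cd"))

  # error-free junction reads are recovered at truth coordinates
  idx <- genome_index(sim$genome)
  det <- detect_sample(wt$reads, idx)
  truth_c <- sim$truth[sim$truth$kind == "circular_cd", ]
  agg <- aggregate_sample(det$hits, library_type = "small")
  passed <- agg[agg$passed_filters, ]
  found <- paste(passed$circ_start, passed$circ_end)
  expect_true(all(paste(truth_c$start, truth_c$end) %in% found))

  # empty stream
  sc0 <- sim_config(genome_len = 20000, n_circ_loci = 4, n_noncirc_cd_loci = 2,
                    n_linear_genes = 5, n_reads_per_sample = 0, seed = 82)
  empty <- simulate_reads(sim$genome, sim$truth, sc0, "WT")
  expect_identical(nrow(empty$reads), 0L)
})

test_that("the KO sample depletes circular junction reads by ko_circ_ratio", {
  sc <- sim_config(genome_len = 30000, n_circ_loci = 6, n_noncirc_cd_loci = 2,
                   n_linear_genes = 8, n_reads_per_sample = 20000,
                   ko_circ_ratio = 0.01, seed = 83)
  sim <- simulate_genome(sc)
  wt <- simulate_reads(sim$genome, sim$truth, sc, "WT")
  ko <- simulate_reads(sim$genome, sim$truth, sc, "KO")
  jwt <- sum(wt$provenance$is_junction)
  jko <- sum(ko$provenance$is_junction)
  # expected ratio ~ 0.01 (slightly shifted by renormalized totals);
  # binomial tolerance around the expectation
  expect_gt(jwt, 3000)
  expect_lt(jko / jwt, 0.03)
  expect_gt(jko, 0)
  # non-junction abundance per locus is roughly unchanged
  bwt <- table(wt$provenance$locus_name[!wt$provenance$is_junction])
  bko <- table(ko$provenance$locus_name[!ko$provenance$is_junction])
  shared <- intersect(names(bwt), names(bko))
  expect_gt(length(shared), 5)
})

test_that("truth tables round-trip losslessly and re-validate stems", {
  sc <- sim_config(genome_len = 20000, n_circ_loci = 3, n_noncirc_cd_loci = 2,
                   n_linear_genes = 3, n_reads_per_sample = 0, seed = 84)
  sim <- simulate_genome(sc)
  f <- withr::local_tempfile(fileext = ".tsv")
  emit_truth(sim$truth, f)
  back <- read_truth(f)
  expect_identical(back, sim$truth)
  # junction columns are empty exactly for non-circular loci
  expect_identical(is.na(back$junction_start), back$kind != "circular_cd")
  # the emitted stem column re-validates against the scorer
  cd <- back[back$kind %in% c("circular_cd", "noncirc_cd"), ]
  for (i in seq_len(nrow(cd))) {
    seq <- substr(unclass(sim$genome)[[cd$chrom[i]]], cd$start[i], cd$end[i])
    if (cd$strand[i] == "-") seq <- rc_chr(seq)
    expect_identical(terminal_stem_pairs(seq, 8, count_gu = FALSE),
                     cd$stem_pairs_designed[i])
  }
})

test_that("base-call errors reduce junction recovery without breaking truth", {
  sc <- sim_config(genome_len = 15000, n_circ_loci = 3, n_noncirc_cd_loci = 1,
                   n_linear_genes = 3, n_reads_per_sample = 400,
                   error_rate = 0.05, seed = 85)
  sim <- simulate_genome(sc)
  rd <- simulate_reads(sim$genome, sim$truth, sc, "WT")
  det <- detect_sample(rd$reads, genome_index(sim$genome))
  nj <- sum(rd$provenance$is_junction)
  # exact matching tolerates no mismatches: errored junction reads are lost
  expect_lt(det$summary$reads_with_hits, nj)
  # but every junction found still sits at a true junction (within tolerance)
  truth_c <- sim$truth[sim$truth$kind == "circular_cd", ]
  if (nrow(det$hits)) {
    ok <- vapply(seq_len(nrow(det$hits)), function(i) {
      any(abs(det$hits$circ_start[i] - truth_c$start) <= 5 &
            abs(det$hits$circ_end[i] - truth_c$end) <= 5)
    }, logical(1))
    expect_true(all(ok))
  }
})
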