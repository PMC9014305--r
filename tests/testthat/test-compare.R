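cfg <- analysis_config()

test_that("compute_rpkm arithmetic, linearity and scale invariance", {
  expect_equal(compute_rpkm(10, 1000, 1e6), 10.0)
  expect_equal(compute_rpkm(0, 500, 1e6), 0.0)
  expect_error(compute_rpkm(5, 0, 1e6), "gene_length")
  expect_error(compute_rpkm(5, 100, 0), "total_mapped")
  set.seed(61)
  for (i in 1:50) {
    c0 <- sample(1e4, 1); L <- sample(100:5000, 1); t0 <- sample(1e6:1e8, 1)
    expect_equal(compute_rpkm(2 * c0, L, 2 * t0), compute_rpkm(c0, L, t0))
    expect_equal(compute_rpkm(3 * c0, L, t0), 3 * compute_rpkm(c0, L, t0))
  }
})

test_that("RPKM flooring and both-low omission follow the published rules", {
  rec <- data.frame(gene_id = c("floored", "omitted", "kept"),
                    rpkm_wt = c(0.5, 1.9, 9.05),
                    rpkm_ko = c(5.0, 1.5, 0.04),
                    stringsAsFactors = FALSE)
  out <- apply_expression_filters(rec, cfg)
  expect_equal(out$rpkm_wt[1], 0)           # <1 RPKM stored as 0
  expect_equal(out$rpkm_ko[3], 0)
  expect_identical(out$status[2], "omitted")  # <2 in both samples
  expect_true(is.na(out$status[3]))           # WT >= 2 keeps the record
})

test_that("fold-change boundary is strict and flooring feeds direction calls", {
  # the knocked-out ligase gene itself: WT 9.05, KO 0.04 -> down
  expect_identical(classify_fold_change(9.05, 0.04, cfg), "down")
  expect_identical(classify_fold_change(4.0, 8.0, cfg), "unchanged")  # not > 2-fold
  expect_identical(classify_fold_change(4.0, 8.01, cfg), "up")
  expect_identical(classify_fold_change(5, 5, cfg), "unchanged")
  expect_identical(classify_fold_change(0, 2.0, cfg), "up")
})

test_that("fold-change classification is antisymmetric in the two samples", {
  set.seed(62)
  wt <- c(runif(200, 0, 50), 0, 2, 4)
  ko <- c(runif(200, 0, 50), 2, 0, 8)
  fwd <- classify_fold_change(wt, ko, cfg)
  bwd <- classify_fold_change(ko, wt, cfg)
  flip <- c(up = "down", down = "up", unchanged = "unchanged")
  expect_identical(unname(flip[fwd]), bwd)
})

test_that("expression_table composes RPKM, filters and classification", {
  out <- expression_table(gene_id = c("g1", "g2", "g3"),
                          length = c(1000L, 1000L, 1000L),
                          count_wt = c(100L, 1L, 10L),
                          count_ko = c(10L, 1L, 100L),
                          total_wt = 1e7, total_ko = 1e7, cfg = cfg)
  expect_identical(out$status, c("down", "omitted", "up"))
})

test_that("depletion calls follow the KO/WT circular-read ratio", {
  expect_identical(classify_depletion(395, 7, cfg)$call, "depleted")
  expect_equal(classify_depletion(395, 7, cfg)$ratio, 7 / 395, tolerance = 1e-12)
  expect_identical(classify_depletion(2023, 1292, cfg)$call, "retained")
  d <- classify_depletion(0, 5, cfg)
  expect_identical(d$call, "not_detected_in_wt")
  expect_true(is.na(d$ratio))
  expect_error(classify_depletion(-1, 0, cfg), ">= 0")
  # boundary: ratio exactly at the threshold is retained (strict <)
  expect_identical(classify_depletion(100, 5, cfg)$call, "retained")
  expect_identical(classify_depletion(100, 4, cfg)$call, "depleted")
})

test_that("compare_samples matches loci by tolerance and WT=KO depletes nothing", {
  cands <- data.frame(
    locus_name = c("a", "b"), chrom = "chr", strand = "+",
    circ_start = c(100L, 900L), circ_end = c(161L, 961L),
    predicted_length = 62L, total_count = c(500L, 80L),
    passed_filters = TRUE, filter_reason = "", stringsAsFactors = FALSE
  )
  same <- compare_samples(cands, cands, cfg)
  expect_identical(sum(same$call == "depleted"), 0L)
  expect_true(all(same$ratio == 1))

  # KO representative shifted by <= tol still matches; absent locus gets 0
  ko <- cands[1, ]
  ko$circ_start <- 103L
  ko$circ_end <- 158L
  ko$total_count <- 4L
  rep <- compare_samples(cands, ko, cfg)
  expect_identical(rep$circ_ko, c(4L, 0L))
  expect_identical(rep$call, c("depleted", "depleted"))  # absent in KO: ratio 0
})

test_that("coverage counts full-length placements with fractional multi-mapping", {
  g <- genome(c(chr = paste0(rand_dna(100), strrep("A", 0))))
  idx <- genome_index(g)
  r <- substr(unclass(g)[["chr"]], 10, 60)
  cov <- compute_coverage(data.frame(id = c("a", "b"), sequence = c(r, r)), idx)
  expect_equal(cov$depth$chr[10:60], rep(2, 51))
  expect_equal(sum(cov$depth$chr), 2 * 51)  # depth sums to placed bases
  expect_equal(cov$placed_reads, 2)

  # unplaced reads contribute nothing
  cov0 <- compute_coverage(data.frame(id = "x", sequence = strrep("N", 51)), idx)
  expect_equal(sum(cov0$depth$chr), 0)

  # multi-placed read spreads fractionally
  g2 <- genome(c(chr = paste0(rand_dna(40), "ACGTACGTACGTACGTACGTACGT")))
  idx2 <- genome_index(g2)
  covm <- compute_coverage(data.frame(id = "m", sequence = "ACGTACGTACGTACGTACGT"),
                           idx2)
  expect_equal(sum(covm$depth$chr), 20)  # one read length in total
})

test_that("KO coverage normalized to WT doubles when KO has half the reads", {
  set.seed(63)
  g <- genome(c(chr = rand_dna(300)))
  idx <- genome_index(g)
  r1 <- substr(unclass(g)[["chr"]], 20, 70)
  r2 <- substr(unclass(g)[["chr"]], 100, 150)
  wt <- compute_coverage(data.frame(id = c("w1", "w2"), sequence = c(r1, r2)), idx)
  ko <- compute_coverage(data.frame(id = "k1", sequence = r1), idx,
                         normalize_to = wt)
  expect_equal(ko$scale, 2)
  expect_equal(ko$depth$chr[20:70], rep(2, 51))
})

test_that("an excised internal segment leaves a coverage hole", {
  sc <- sim_config(genome_len = 12000, n_circ_loci = 0, n_noncirc_cd_loci = 0,
                   n_linear_genes = 2, n_reads_per_sample = 2000,
                   with_rrna_gap = TRUE, seed = 64)
  sim <- simulate_genome(sc)
  rd <- simulate_reads(sim$genome, sim$truth, sc, "WT")
  idx <- genome_index(sim$genome)
  cov <- compute_coverage(rd$reads, idx)
  rr <- sim$truth[sim$truth$kind == "rrna_like", ]
  gap <- cov$depth$chrSim[rr$gap_start:rr$gap_end]
  body <- cov$depth$chrSim[rr$start:(rr$gap_start - 52)]
  expect_equal(max(gap), 0)
  expect_gt(mean(body), 0)
})

test_that("bedGraph output covers exactly the nonzero runs", {
  g <- genome(c(chr = rand_dna(120)))
  idx <- genome_index(g)
  r <- substr(unclass(g)[["chr"]], 11, 61)
  cov <- compute_coverage(data.frame(id = "a", sequence = r), idx)
  f <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(cov, f)
  fields <- strsplit(readLines(f), "\t")
  expect_identical(length(fields), 1L)
  expect_identical(as.integer(fields[[1]][2:3]), c(10L, 61L))
  expect_equal(as.numeric(fields[[1]][4]), 1)
})
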