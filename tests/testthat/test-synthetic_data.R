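# The ground-truth generator: determinism, round-trips, forced cases.

small_cfg <- function(seed = 1, ...) {
  synthetic_config(seed = seed, n_transcripts = 120,
                   te_counts = c(Alu = 150, L1 = 150, LTR = 150,
                                 DNA = 150, L2 = 150, MIR = 150), ...)
}

test_that("the TE landscape respects counts, bounds and families", {
  set.seed(1)
  cfg <- small_cfg()
  tes <- simulate_te_landscape(cfg)
  expect_equal(nrow(tes), 900L)
  expect_equal(as.integer(table(tes$family)[TE_FAMILIES]), rep(150L, 6))
  expect_true(all(tes$millidiv >= 0))
  expect_true(all(tes$start >= 0))
  lens <- cfg$genome[tes$chrom]
  expect_true(all(tes$end <= lens))
  # demanding more TE bp than genome fails
  tiny <- synthetic_config(genome = c(chr1 = 1000),
                           te_counts = c(Alu = 100),
                           te_length = list(Alu = c(200, 350)))
  set.seed(1)
  expect_error(simulate_te_landscape(tiny), "exceeds genome")
})

test_that("identical config and seed give a byte-identical bundle", {
  cfg <- small_cfg(seed = 99)
  d1 <- file.path(tempdir(), "bundle_det1")
  d2 <- file.path(tempdir(), "bundle_det2")
  b1 <- simulate_bundle(cfg, d1)
  b2 <- simulate_bundle(cfg, d2)
  for (f in c("te.bed", "assembly_a.gtf", "assembly_b.gtf", "fpkm.tsv",
              file.path("signals", "DHS.bed"),
              file.path("truth", "exon_labels.tsv"))) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("every emitted file re-parses with zero records lost", {
  cfg <- small_cfg(seed = 42)
  d <- file.path(tempdir(), "bundle_rt")
  b <- simulate_bundle(cfg, d)
  te_back <- read_repeatmasker(b$paths$te, dialect = "bed")
  expect_equal(nrow(te_back), nrow(b$tes))
  expect_equal(te_back$start, b$tes$start)
  expect_equal(te_back$family, b$tes$family)

  ex_back <- read_gtf(b$paths$gtf_a)
  expect_equal(nrow(ex_back), nrow(b$exons_a))
  expect_equal(ex_back$start, b$exons_a$start)
  expect_equal(ex_back$exon_rank, b$exons_a$exon_rank)
  expect_equal(nrow(read_gtf(b$paths$gtf_b)), nrow(b$exons_b))

  fpkm_back <- read_fpkm(b$paths$fpkm)
  expect_equal(nrow(fpkm_back), nrow(b$fpkm))

  for (tr in names(b$signals)) {
    expect_equal(nrow(read_bed_features(b$paths$signals[[tr]], tr)),
                 nrow(b$signals[[tr]]))
  }
})

test_that("forced overlap rates produce the forced classifications", {
  set.seed(2)
  cfg <- small_cfg(seed = 2, rho_first = 1, rho_later = 0)
  tes <- simulate_te_landscape(cfg)
  txo <- simulate_transcriptome(cfg, tes)
  cls <- classify_exons(txo$exons_a, tes)
  expect_true(all(cls$exons$te_derived[cls$exons$is_first]))
  expect_true(!any(cls$exons$te_derived[!cls$exons$is_first]))

  set.seed(3)
  cfg0 <- small_cfg(seed = 3, rho_first = 0, rho_later = 0)
  tes0 <- simulate_te_landscape(cfg0)
  txo0 <- simulate_transcriptome(cfg0, tes0)
  cls0 <- classify_exons(txo0$exons_a, tes0)
  expect_equal(sum(cls0$exons$te_derived), 0L)
})

test_that("planted first-exon rate is recovered within binomial error", {
  set.seed(6)
  cfg <- synthetic_config(seed = 6, n_transcripts = 2000)
  tes <- simulate_te_landscape(cfg)
  txo <- simulate_transcriptome(cfg, tes)
  cls <- classify_exons(txo$exons_a, tes)
  first_frac <- fraction_te_derived(cls, "first_exons")$fraction
  expect_lt(abs(first_frac - 0.4), 3 * sqrt(0.4 * 0.6 / 2000))
})

test_that("expression generator plants DE genes and splits transcripts", {
  set.seed(7)
  cfg <- small_cfg(seed = 7, de_fraction = 0.2, de_log2fc = 3)
  tx <- data.frame(transcript_id = c("t1", "t2", "t3"),
                   gene_id = c("g1", "g1", "g2"), stringsAsFactors = FALSE)
  sim <- simulate_expression(cfg, tx)
  expect_setequal(unique(sim$fpkm$sample), c("A1", "A2", "B1", "B2"))
  expect_true(all(sim$fpkm$fpkm >= 0))
  expect_equal(sort(unique(sim$de_truth$gene_id)), c("g1", "g2"))
  # de_fraction = 0 is a clean global null
  cfg0 <- small_cfg(seed = 7, de_fraction = 0)
  expect_true(!any(simulate_expression(cfg0, tx)$de_truth$de))
  # zero planted effect is recorded as zero fold change
  cfgz <- small_cfg(seed = 7, de_fraction = 0.5, de_log2fc = 0)
  expect_true(all(simulate_expression(cfgz, tx)$de_truth$log2fc == 0))
})

test_that("signal generator honours its intercept/slope contract", {
  ex <- exon_grid(50)
  # b = 0, a = 1, no noise -> exactly one peak per exon
  set.seed(8)
  cfg1 <- synthetic_config(tracks = list(DHS = c(a = 1, b = 0, noise = 0)))
  sig <- simulate_signal_tracks(cfg1, ex, fpkm = rlnorm(50))$DHS
  expect_equal(nrow(sig), 50L)
  expect_equal(signal_per_exon(ex, sig, mode = "count"), rep(1, 50))
  # fpkm 0 everywhere with a = 0 -> no peaks
  cfg0 <- synthetic_config(tracks = list(DHS = c(a = 0, b = 5, noise = 0)))
  set.seed(8)
  none <- simulate_signal_tracks(cfg0, ex, fpkm = rep(0, 50))$DHS
  expect_equal(nrow(none), 0L)
  # peaks always fall inside their exon
  set.seed(9)
  cfg2 <- synthetic_config(tracks = list(DHS = c(a = 2, b = 1, noise = 0.5)))
  sig2 <- simulate_signal_tracks(cfg2, ex, fpkm = rlnorm(50))$DHS
  hits <- overlap_hits(interval_index(ex), sig2)
  expect_equal(nrow(hits), nrow(sig2))
})
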