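# Family attribution, background normalization, age ranking, chi-square.

te_row <- function(start, end, family, chrom = "chr1", millidiv = 100) {
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(end), strand = "+",
             name = paste0(family, "_", start),
             raw_class = family, family = family, millidiv = millidiv,
             stringsAsFactors = FALSE)
}

test_that("an exon counts once per distinct overlapping family", {
  ex <- make_exons(100, 300)
  # one Alu only
  h1 <- attribute_hits(classify_exons(ex, te_row(150, 250, "Alu")))
  expect_equal(h1[["Alu"]], 1L)
  expect_equal(sum(h1), 1L)
  # Alu + L1 -> one count each; two Alus -> still one Alu count
  tes <- rbind(te_row(150, 250, "Alu"), te_row(160, 260, "Alu"),
               te_row(200, 280, "L1"))
  h2 <- attribute_hits(classify_exons(ex, tes))
  expect_equal(h2[["Alu"]], 1L)
  expect_equal(h2[["L1"]], 1L)
  # no TE-derived exons -> all zero
  h3 <- attribute_hits(classify_exons(ex, te_row(5000, 5100, "Alu")))
  expect_true(all(h3 == 0L))
})

test_that("transcript-level attribution pools a transcript's exons", {
  ex <- make_exons(c(100, 500), c(200, 600))
  tes <- rbind(te_row(150, 160, "Alu"), te_row(550, 560, "Alu"))
  cls <- classify_exons(ex, tes)
  expect_equal(attribute_hits(cls, level = "exon")[["Alu"]], 2L)
  expect_equal(attribute_hits(cls, level = "transcript")[["Alu"]], 1L)
})

test_that("genomic abundance counts elements or sums bp", {
  tes <- rbind(te_row(0, 300, "Alu"), te_row(1000, 1300, "Alu"),
               te_row(2000, 2250, "Alu"))
  expect_equal(genomic_abundance(tes, "elements")[["Alu"]], 3)
  expect_equal(genomic_abundance(tes, "bp")[["Alu"]], 850)
  expect_equal(genomic_abundance(tes, "elements")[["MIR"]], 0)
  expect_error(genomic_abundance(tes[0, ], "elements"), "empty")
  # mixed families match a manual tally
  set.seed(3)
  fams <- sample(c("Alu", "L1", "MIR"), 50, replace = TRUE)
  mixed <- do.call(rbind, lapply(seq_along(fams), function(i) {
    te_row(i * 1000, i * 1000 + 100 + i, fams[i])
  }))
  ab <- genomic_abundance(mixed, "bp")
  for (f in c("Alu", "L1", "MIR")) {
    expect_equal(ab[[f]], sum((mixed$end - mixed$start)[mixed$family == f]))
  }
})

test_that("normalization divides by abundance and flags missing families", {
  hits <- setNames(c(10, 0, 0, 0, 0, 0, 0), c(TE_FAMILIES, "other"))
  ab <- setNames(c(1000, 500, 0, 0, 0, 0, 0), c(TE_FAMILIES, "other"))
  nc <- normalize_contribution(hits, ab)
  expect_equal(nc$normalized[nc$family == "Alu"], 0.01)
  expect_equal(nc$normalized[nc$family == "L1"], 0)
  expect_true(is.na(nc$normalized[nc$family == "LTR"]))
  # scale equivariance: doubling abundance halves every normalized value
  nc2 <- normalize_contribution(hits, ab * 2)
  expect_equal(nc2$normalized, nc$normalized / 2)
})

test_that("age ranking orders families by mean millidiv, ties alphabetical", {
  tes <- rbind(te_row(0, 100, "Alu", millidiv = 85),
               te_row(200, 300, "MIR", millidiv = 280))
  r <- age_rank(tes)
  expect_equal(r$family, c("Alu", "MIR"))
  expect_equal(r$age_rank, c(1L, 2L))

  tie <- rbind(te_row(0, 100, "L2", millidiv = 100),
               te_row(200, 300, "DNA", millidiv = 100))
  expect_equal(age_rank(tie)$family, c("DNA", "L2"))
  # "other" never enters the ranking
  expect_false("other" %in% age_rank(rbind(tes, te_row(1, 5, "other")))$family)
})

test_that("chi-square statistic follows the abundance-proportional expectation", {
  # hits exactly proportional to abundance -> statistic 0, p = 1
  h <- c(Alu = 30, L1 = 60)
  ab <- c(Alu = 1, L1 = 2)
  r0 <- chi_square_families(h, ab)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)

  r <- chi_square_families(c(Alu = 30, L1 = 10), c(Alu = 1, L1 = 1))
  expect_equal(r$statistic, 10)
  expect_equal(r$df, 1L)
  # independent route: stats::chisq.test with the same expectation
  ct <- suppressWarnings(stats::chisq.test(c(30, 10), p = c(0.5, 0.5)))
  expect_equal(r$statistic, unname(ct$statistic))
  expect_equal(r$p, ct$p.value)

  expect_error(chi_square_families(c(Alu = 1), c(Alu = 5)), ">= 2 families")
  expect_error(chi_square_families(c(Alu = 0, L1 = 0), c(Alu = 1, L1 = 1)),
               "at least one hit")
})

test_that("uniform-expectation alternative is exposed", {
  r <- chi_square_families(c(Alu = 30, L1 = 10), c(Alu = 3, L1 = 1),
                           expected = "uniform")
  expect_equal(r$statistic, 10)
  expect_equal(chi_square_families(c(Alu = 30, L1 = 10),
                                   c(Alu = 3, L1 = 1))$statistic, 0)
})

test_that("full family_contribution table joins ranks and millidiv", {
  set.seed(41)
  cfg <- synthetic_config(seed = 41, n_transcripts = 100)
  tes <- simulate_te_landscape(cfg)
  txo <- simulate_transcriptome(cfg, tes)
  fc <- family_contribution(classify_exons(txo$exons_a, tes))
  expect_equal(sort(fc$contribution$family), sort(c(TE_FAMILIES, "other")))
  six <- fc$contribution[fc$contribution$family %in% TE_FAMILIES, ]
  expect_setequal(six$age_rank, 1:6)
  expect_true(all(fc$contribution$normalized >= 0, na.rm = TRUE))
  expect_s3_class(fc$chi_square, "chi_square_result")
})
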