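# Format readers/writers and the coordinate convention.

gtf_line <- function(chrom, start, end, strand, tx = "t1", gene = "g1",
                     feature = "exon") {
  sprintf('%s\tsrc\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
          chrom, feature, start, end, strand, gene, tx)
}

test_that("GTF 1-based closed coordinates become 0-based half-open", {
  path <- write_lines_tmp(gtf_line("chr1", 101, 200, "+"))
  ex <- read_gtf(path)
  expect_equal(ex$start, 100L)
  expect_equal(ex$end, 200L)
  # internal length equals GTF end - start + 1
  expect_equal(ex$end - ex$start, 200L - 101L + 1L)
})

test_that("exons are ordered in transcription order with exon_rank", {
  path <- write_lines_tmp(c(gtf_line("chr1", 301, 400, "-"),
                            gtf_line("chr1", 101, 200, "-")))
  ex <- read_gtf(path)
  # on the minus strand the first exon is the rightmost one
  expect_equal(ex$end[ex$exon_rank == 1L], 400L)
  expect_equal(ex$end[ex$exon_rank == 2L], 200L)

  plus <- read_gtf(write_lines_tmp(c(gtf_line("chr1", 301, 400, "+"),
                                     gtf_line("chr1", 101, 200, "+"))))
  expect_equal(plus$start[plus$exon_rank == 1L], 100L)
})

test_that("empty GTF and non-exon features yield an empty table", {
  expect_equal(nrow(read_gtf(write_lines_tmp(character(0)))), 0L)
  path <- write_lines_tmp(gtf_line("chr1", 1, 10, "+", feature = "CDS"))
  expect_equal(nrow(read_gtf(path)), 0L)
})

test_that("malformed GTF lines fail with the offending line number", {
  expect_error(read_gtf(write_lines_tmp("chr1\tonly\tthree")), "line 1")
  bad_coord <- c(gtf_line("chr1", 101, 200, "+"),
                 gsub("101", "abc", gtf_line("chr1", 101, 200, "+")))
  expect_error(read_gtf(write_lines_tmp(bad_coord)), "line 2")
  expect_error(read_gtf(write_lines_tmp(gtf_line("chr1", 200, 100, "+"))),
               "end < start")
  no_tx <- 'chr1\tsrc\texon\t1\t10\t.\t+\t.\tgene_id "g1";'
  expect_error(read_gtf(write_lines_tmp(no_tx)), "transcript_id")
  expect_error(read_gtf(write_lines_tmp(gtf_line("chr1", 1, 10, "."))),
               "strand")
})

test_that("GTF round-trips through write_gtf with identical records", {
  path <- write_lines_tmp(c(gtf_line("chr1", 301, 400, "-"),
                            gtf_line("chr1", 101, 200, "-"),
                            gtf_line("chr2", 51, 90, "+", tx = "t2",
                                     gene = "g2")))
  ex <- read_gtf(path)
  out <- tempfile(fileext = ".gtf")
  write_gtf(ex, out)
  again <- read_gtf(out)
  expect_equal(again[c("chrom", "start", "end", "strand", "gene_id",
                       "transcript_id", "exon_rank")],
               ex[c("chrom", "start", "end", "strand", "gene_id",
                    "transcript_id", "exon_rank")])
})

test_that("FPKM attribute is picked up when present", {
  line <- paste0(gtf_line("chr1", 101, 200, "+"), ' FPKM "12.5";')
  expect_equal(read_gtf(write_lines_tmp(line))$fpkm, 12.5)
  expect_true(is.na(read_gtf(write_lines_tmp(gtf_line("chr1", 1, 9, "+")))$fpkm))
})

test_that("RepeatMasker .out and rmsk-bed dialects agree", {
  out_lines <- c(
    "   SW  perc perc perc  query     position in query",
    "score  div. del. ins.  sequence  begin  end",
    "",
    "  463   8.5  0.0  0.0  chr1      1001   1300  (0)  +  AluSx  SINE/Alu  1 300 (0) 1",
    "  300  28.0  1.0  0.0  chr1      5001   5200  (0)  C  MIR3   SINE/MIR  1 200 (0) 2"
  )
  te_out <- read_repeatmasker(write_lines_tmp(out_lines), dialect = "out")
  bed_lines <- c("chr1\t1000\t1300\tAluSx\t85\t+\tSINE/Alu",
                 "chr1\t5000\t5200\tMIR3\t280\t-\tSINE/MIR")
  te_bed <- read_repeatmasker(write_lines_tmp(bed_lines), dialect = "bed")
  cols <- c("chrom", "start", "end", "strand", "name", "raw_class",
            "family", "millidiv")
  expect_equal(te_out[cols], te_bed[cols])
  expect_equal(te_out$millidiv, c(85, 280))  # percent x 10
  expect_equal(te_out$family, c("Alu", "MIR"))
})

test_that("family grouping follows the prefix rules", {
  expect_equal(
    te_family_group(c("SINE/Alu", "SINE/MIR", "LINE/L1", "LINE/L2",
                      "LTR/ERVL-MaLR", "DNA/hAT", "Satellite",
                      "Simple_repeat")),
    c("Alu", "MIR", "L1", "L2", "LTR", "DNA", "other", "other"))
})

test_that("negative divergence and unknown dialect are rejected", {
  bad <- "chr1\t0\t100\tAluY\t-5\t+\tSINE/Alu"
  expect_error(read_repeatmasker(write_lines_tmp(bad), dialect = "bed"),
               "millidiv")
  expect_error(read_repeatmasker(write_lines_tmp(bad), dialect = "vcf"))
})

test_that("BED features parse natively with optional score", {
  f <- read_bed_features(write_lines_tmp("chr1\t150\t160\tp1\t7"), "DHS")
  expect_equal(f$start, 150L)
  expect_equal(f$end, 160L)
  expect_equal(f$score, 7)
  expect_equal(f$track, "DHS")

  f3 <- read_bed_features(write_lines_tmp("chr1\t10\t20\tx"), "CAGE")
  expect_true(is.na(f3$score))
  expect_error(read_bed_features(write_lines_tmp("chr1\t160\t150"), "DHS"),
               "end <= start")
  expect_error(read_bed_features(write_lines_tmp("chr1\t10\t20"), ""),
               "track")
})

test_that("write_table emits deterministic TSV with header", {
  df <- fraction_summary(3, 10, "demo")
  path <- tempfile(fileext = ".tsv")
  write_table(df, path)
  back <- read.delim(path)
  expect_equal(back$numerator, 3L)
  expect_equal(back$percent, 30)

  empty <- df[0, , drop = FALSE]
  write_table(empty, path)
  expect_equal(length(readLines(path)), 1L)  # header only
  expect_error(write_table(NULL, path), "non-null")
})
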