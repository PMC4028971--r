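# Independent brute-force oracles and small fixture builders used across
# the suite. These stay deliberately naive: linear scans and exhaustive
# enumeration, never the code paths they check.

# All stored intervals overlapping a query, by linear scan.
bf_overlap_rows <- function(df, chrom, start, end) {
  which(df$chrom == chrom & pmax(df$start, start) < pmin(df$end, end))
}

# Random interval table on a couple of chromosomes.
random_intervals <- function(n, max_pos = 10000, max_len = 500) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  data.frame(
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    start = start, end = start + len,
    strand = sample(c("+", "-"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# Exhaustive maximum-cardinality, minimum-total-distance one-to-one
# matching between two record sets under the wiggle rule. Returns the
# optimal (size, total distance).
bf_best_matching <- function(a, b, wiggle) {
  nb <- nrow(b)
  cand <- lapply(seq_len(nrow(a)), function(i) {
    which(b$chrom == a$chrom[i] & b$strand == a$strand[i] &
            abs(b$start - a$start[i]) <= wiggle &
            abs(b$end - a$end[i]) <= wiggle)
  })
  dmat <- function(i, j) abs(a$start[i] - b$start[j]) +
    abs(a$end[i] - b$end[j])
  best <- list(size = -1L, dist = Inf)
  rec <- function(i, used, size, dist) {
    if (i > nrow(a)) {
      if (size > best$size ||
          (size == best$size && dist < best$dist)) {
        best <<- list(size = size, dist = dist)
      }
      return(invisible())
    }
    rec(i + 1L, used, size, dist)          # leave a_i unmatched
    for (j in cand[[i]]) {
      if (!used[j]) {
        used[j] <- TRUE
        rec(i + 1L, used, size + 1L, dist + dmat(i, j))
        used[j] <- FALSE
      }
    }
  }
  rec(1L, logical(nb), 0L, 0)
  best
}

# Random small matchable record sets (dense enough to create candidate
# conflicts for the matcher).
random_match_sets <- function(n_a, n_b, span = 400) {
  mk <- function(n, prefix) {
    start <- sample.int(span, n, replace = TRUE)
    len <- 50L + sample.int(60L, n, replace = TRUE)
    data.frame(id = paste0(prefix, seq_len(n)), chrom = "chr1",
               start = start, end = start + len, strand = "+",
               stringsAsFactors = FALSE)
  }
  list(a = mk(n_a, "a"), b = mk(n_b, "b"))
}

# Minimal exon table (already in transcription order) for direct
# construction in tests; coordinates are 0-based half-open.
make_exons <- function(starts, ends, strand = "+", chrom = "chr1",
                       transcript_id = "t1", gene_id = "g1") {
  n <- length(starts)
  df <- data.frame(
    chrom = chrom, start = as.integer(starts), end = as.integer(ends),
    strand = strand, gene_id = gene_id, transcript_id = transcript_id,
    assembly = "test", fpkm = NA_real_, stringsAsFactors = FALSE
  )
  teexon:::order_exons(df)
}

# Regular non-overlapping exon grid, used as scaffold for signal tests.
exon_grid <- function(n, len = 200L, gap = 800L, chrom = "chr1") {
  start <- (seq_len(n) - 1L) * (len + gap)
  data.frame(
    chrom = chrom, start = start, end = start + len, strand = "+",
    gene_id = paste0("g", seq_len(n)),
    transcript_id = paste0("t", seq_len(n)),
    assembly = "test", fpkm = NA_real_, exon_rank = 1L,
    stringsAsFactors = FALSE
  )
}

write_lines_tmp <- function(lines) {
  path <- tempfile(fileext = ".txt")
  writeLines(lines, path)
  path
}
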