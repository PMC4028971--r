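# Readers and writers for the genomic file formats the pipeline touches.
# One coordinate convention everywhere: 0-based half-open. GTF (1-based
# closed) is converted on read and write; BED-family formats are native.

gtf_split_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  list(lines = lines[keep], lineno = keep)
}

extract_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexec(paste0(key, '\\s+"([^"]*)"'), attrs))
  vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, character(1))
}

#' Read exon models from a GTF file
#'
#' Parses `exon` feature lines of a GTF file into a table of exon records.
#' GTF 1-based closed coordinates are converted to the package-internal
#' 0-based half-open convention, so an exon annotated `101..200` becomes
#' `start = 100, end = 200` with `end - start` equal to its length.
#' Within each transcript, exons are sorted in transcription order
#' (ascending start on `+`, descending start on `-`) and numbered by
#' `exon_rank` (1 = first exon). Non-exon feature lines are ignored.
#'
#' Expression can ride along in two ways: an `FPKM` attribute on the exon
#' lines (picked up into the `fpkm` column), or a sidecar table supplied to
#' [read_fpkm()] and joined downstream. Unstranded (`.`) exon records are
#' rejected because first-exon calling is strand-dependent.
#'
#' @param path path to a GTF file.
#' @param assembly label recorded in the `assembly` column (e.g. `"nonref"`,
#'   `"refseq"`, `"gencode"`).
#' @return data.frame with columns `chrom, start, end, strand, gene_id,
#'   transcript_id, assembly, fpkm, exon_rank`, one row per exon.
#' @export
read_gtf <- function(path, assembly = "nonref") {
  if (!file.exists(path)) fail("GTF file not found: %s", path)
  parsed <- gtf_split_lines(path)
  if (length(parsed$lines) == 0L) {
    return(empty_exon_table(assembly))
  }
  fields <- strsplit(parsed$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- which(nf != 9L)[1]
    fail("malformed GTF line %d: expected 9 tab-separated columns, got %d",
         parsed$lineno[bad], nf[bad])
  }
  mat <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
  is_exon <- mat[, 3] == "exon"
  if (!any(is_exon)) return(empty_exon_table(assembly))
  mat <- mat[is_exon, , drop = FALSE]
  lineno <- parsed$lineno[is_exon]

  start1 <- suppressWarnings(as.integer(mat[, 4]))
  end1 <- suppressWarnings(as.integer(mat[, 5]))
  if (anyNA(start1) || anyNA(end1)) {
    bad <- which(is.na(start1) | is.na(end1))[1]
    fail("malformed GTF line %d: non-integer coordinates", lineno[bad])
  }
  if (any(end1 < start1)) {
    bad <- which(end1 < start1)[1]
    fail("malformed GTF line %d: end < start", lineno[bad])
  }
  strand <- mat[, 7]
  if (any(!strand %in% c("+", "-"))) {
    bad <- which(!strand %in% c("+", "-"))[1]
    fail("GTF line %d: exon records must be stranded '+' or '-', got '%s'",
         lineno[bad], strand[bad])
  }
  tx <- extract_attr(mat[, 9], "transcript_id")
  if (anyNA(tx) || any(!nzchar(tx))) {
    bad <- which(is.na(tx) | !nzchar(tx))[1]
    fail("GTF line %d: missing transcript_id attribute", lineno[bad])
  }
  gene <- extract_attr(mat[, 9], "gene_id")
  if (anyNA(gene) || any(!nzchar(gene))) {
    bad <- which(is.na(gene) | !nzchar(gene))[1]
    fail("GTF line %d: missing gene_id attribute", lineno[bad])
  }
  fpkm <- suppressWarnings(as.numeric(extract_attr(mat[, 9], "FPKM")))

  ex <- data.frame(
    chrom = mat[, 1], start = start1 - 1L, end = end1, strand = strand,
    gene_id = gene, transcript_id = tx, assembly = assembly, fpkm = fpkm,
    stringsAsFactors = FALSE
  )
  order_exons(ex)
}

empty_exon_table <- function(assembly = character(0)) {
  data.frame(
    chrom = character(0), start = integer(0), end = integer(0),
    strand = character(0), gene_id = character(0),
    transcript_id = character(0),
    assembly = character(0), fpkm = numeric(0), exon_rank = integer(0),
    stringsAsFactors = FALSE
  )
}

# Sort exons into transcription order within transcript, assign exon_rank,
# and enforce the per-transcript invariants (one chrom/strand, disjoint).
order_exons <- function(ex) {
  check_intervals(ex, require_strand = TRUE, what = "exon")
  key <- ifelse(ex$strand == "+", 1, -1) * ex$start
  o <- order(ex$transcript_id, key, ex$end - ex$start)
  ex <- ex[o, , drop = FALSE]
  rownames(ex) <- NULL
  ex$exon_rank <- stats::ave(seq_len(nrow(ex)), ex$transcript_id,
                             FUN = seq_along)
  # per-transcript invariants, vectorized over genomic-position order
  o2 <- order(ex$transcript_id, ex$start)
  tx2 <- ex$transcript_id[o2]
  same <- tx2[-length(tx2)] == tx2[-1]
  if (any(same & (ex$chrom[o2][-nrow(ex)] != ex$chrom[o2][-1] |
                  ex$strand[o2][-nrow(ex)] != ex$strand[o2][-1]))) {
    fail("a transcript mixes chromosomes or strands")
  }
  bad <- same & (ex$end[o2][-nrow(ex)] > ex$start[o2][-1])
  if (any(bad)) {
    fail("transcript %s has overlapping exons", tx2[which(bad)[1]])
  }
  ex
}

#' Write exon records back to GTF
#'
#' Inverse of [read_gtf()]: emits one `exon` feature line per row, shifting
#' the internal 0-based half-open coordinates back to GTF 1-based closed.
#' Reading the written file reproduces identical coordinates and IDs.
#'
#' @param exons exon table as returned by [read_gtf()].
#' @param path output path.
#' @param source value for the GTF source column.
#' @export
write_gtf <- function(exons, path, source = "teexon") {
  attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                   exons$gene_id, exons$transcript_id)
  has_fpkm <- !is.null(exons$fpkm) & !is.na(exons$fpkm)
  if (any(has_fpkm)) {
    attrs[has_fpkm] <- paste0(attrs[has_fpkm],
                              sprintf(' FPKM "%s";',
                                      format(exons$fpkm[has_fpkm], digits = 12)))
  }
  lines <- sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
                   exons$chrom, source, exons$start + 1L, exons$end,
                   exons$strand, attrs)
  writeLines(lines, path)
  invisible(path)
}

#' Read a transcript expression sidecar table
#'
#' Three tab-delimited columns with header: `transcript_id`, `sample`,
#' `fpkm`. FPKM values must be non-negative numbers.
#'
#' @param path path to the TSV.
#' @return data.frame with columns `transcript_id, sample, fpkm`.
#' @export
read_fpkm <- function(path) {
  if (!file.exists(path)) fail("FPKM table not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "sample", "fpkm")
  if (!all(need %in% names(df))) {
    fail("FPKM table must have columns: %s", paste(need, collapse = ", "))
  }
  df$fpkm <- as.numeric(df$fpkm)
  if (anyNA(df$fpkm) || any(df$fpkm < 0)) {
    fail("FPKM values must be non-negative numbers")
  }
  df[, need]
}

#' Map a RepeatMasker class/family string to a TE family group
#'
#' Prefix rules: `SINE/Alu` -> Alu, `SINE/MIR` -> MIR, `LINE/L1` -> L1,
#' `LINE/L2` -> L2, `LTR*` -> LTR, `DNA*` -> DNA, anything else -> other.
#' These are the six major families whose relative contribution and age
#' (millidiv) ordering the pipeline reports.
#'
#' @param raw_class character vector of RepeatMasker class/family strings.
#' @return character vector over
#'   `c("Alu","L1","LTR","DNA","L2","MIR","other")`.
#' @export
te_family_group <- function(raw_class) {
  out <- rep("other", length(raw_class))
  out[startsWith(raw_class, "SINE/Alu")] <- "Alu"
  out[startsWith(raw_class, "SINE/MIR")] <- "MIR"
  out[startsWith(raw_class, "LINE/L1")] <- "L1"
  out[startsWith(raw_class, "LINE/L2")] <- "L2"
  out[startsWith(raw_class, "LTR")] <- "LTR"
  out[startsWith(raw_class, "DNA")] <- "DNA"
  out
}

#' TE family group levels, youngest-family analyses order
#' @export
TE_FAMILIES <- c("Alu", "L1", "LTR", "DNA", "L2", "MIR")

#' Read repeat annotation (RepeatMasker .out or rmsk-style BED)
#'
#' Both dialects normalize to the same table. The `.out` dialect skips the
#' three header lines, reads whitespace-delimited columns, converts 1-based
#' closed coordinates, maps strand `C` to `-`, and multiplies the percent
#' divergence column by 10 so that divergence is stored per-mille (millidiv)
#' in both dialects. The `bed` dialect expects tab-delimited columns
#' `chrom, start(0-based), end, name, millidiv, strand, class/family`.
#'
#' @param path annotation file.
#' @param dialect `"out"` or `"bed"`.
#' @return data.frame with columns `chrom, start, end, strand, name,
#'   raw_class, family, millidiv`.
#' @export
read_repeatmasker <- function(path, dialect = c("bed", "out")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) fail("repeat annotation not found: %s", path)
  if (dialect == "out") {
    lines <- readLines(path, warn = FALSE)
    if (length(lines) > 3L) lines <- lines[-(1:3)] else lines <- character(0)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) return(empty_te_table())
    fields <- strsplit(trimws(lines), "\\s+")
    nf <- lengths(fields)
    if (any(nf < 11L)) {
      fail("malformed RepeatMasker .out line %d: fewer than 11 columns",
           which(nf < 11L)[1] + 3L)
    }
    mat <- t(vapply(fields, function(x) x[1:11], character(11)))
    perc_div <- suppressWarnings(as.numeric(mat[, 2]))
    start1 <- suppressWarnings(as.integer(mat[, 6]))
    end1 <- suppressWarnings(as.integer(mat[, 7]))
    if (anyNA(perc_div) || anyNA(start1) || anyNA(end1)) {
      fail("malformed RepeatMasker .out record: non-numeric coordinates or divergence")
    }
    te <- data.frame(
      chrom = mat[, 5], start = start1 - 1L, end = end1,
      strand = ifelse(mat[, 9] == "C", "-", mat[, 9]),
      name = mat[, 10], raw_class = mat[, 11],
      millidiv = perc_div * 10,
      stringsAsFactors = FALSE
    )
  } else {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 7L) fail("rmsk BED dialect requires >= 7 columns")
    te <- data.frame(
      chrom = as.character(df[[1]]), start = as.integer(df[[2]]),
      end = as.integer(df[[3]]), strand = as.character(df[[6]]),
      name = as.character(df[[4]]), raw_class = as.character(df[[7]]),
      millidiv = as.numeric(df[[5]]),
      stringsAsFactors = FALSE
    )
  }
  if (anyNA(te$millidiv) || any(te$millidiv < 0)) {
    fail("negative or missing divergence (millidiv) in repeat annotation")
  }
  check_intervals(te, what = "repeat annotation")
  te$family <- te_family_group(te$raw_class)
  rownames(te) <- NULL
  te[, c("chrom", "start", "end", "strand", "name", "raw_class",
         "family", "millidiv")]
}

empty_te_table <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             strand = character(0), name = character(0),
             raw_class = character(0), family = character(0),
             millidiv = numeric(0), stringsAsFactors = FALSE)
}

#' Read a BED file of signal features (peaks / clusters)
#'
#' BED is natively 0-based half-open, so no coordinate conversion happens.
#' The score is taken from column 5 when present (`.` or absent -> `NA`).
#'
#' @param path BED3/BED5/BED6 file.
#' @param track signal name recorded in the `track` column, e.g.
#'   `"H3K4me3"`, `"DHS"`, `"CAGE"`.
#' @return data.frame with columns `chrom, start, end, strand, name, score,
#'   track`.
#' @export
read_bed_features <- function(path, track) {
  if (!nzchar(track)) fail("track name must be non-empty")
  if (!file.exists(path)) fail("BED file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|track|browser|$)", lines))
  if (length(keep) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      name = character(0), score = numeric(0),
                      track = character(0), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    fail("malformed BED line %d: fewer than 3 columns", keep[which(nf < 3L)[1]])
  }
  get_col <- function(i) {
    vapply(fields, function(x) if (length(x) >= i) x[i] else NA_character_,
           character(1))
  }
  start <- suppressWarnings(as.integer(get_col(2)))
  end <- suppressWarnings(as.integer(get_col(3)))
  if (anyNA(start) || anyNA(end)) {
    fail("malformed BED line %d: non-integer coordinates",
         keep[which(is.na(start) | is.na(end))[1]])
  }
  if (any(end <= start)) {
    fail("malformed BED line %d: end <= start", keep[which(end <= start)[1]])
  }
  score_raw <- get_col(5)
  score <- suppressWarnings(as.numeric(ifelse(score_raw == ".", NA, score_raw)))
  strand <- get_col(6)
  strand[is.na(strand) | !strand %in% c("+", "-")] <- "."
  data.frame(
    chrom = get_col(1), start = start, end = end, strand = strand,
    name = get_col(4), score = score, track = track,
    stringsAsFactors = FALSE
  )
}

#' Write a result table as TSV
#'
#' Tab-delimited, UTF-8, header row, no quoting, no row names. Row order is
#' the caller's (every result constructor in the package documents and
#' applies its own deterministic sort key before writing).
#'
#' @param records a data.frame of results.
#' @param path output path.
#' @export
write_table <- function(records, path) {
  if (is.null(records)) fail("records must be non-null")
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
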