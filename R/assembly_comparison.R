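# Match transcripts/exons between two assemblies under a bounded start/end
# tolerance ("wiggle"), and produce Venn-style shared/unique counts.

#' Transcript spans from an exon table
#'
#' One interval per transcript from the start of its leftmost exon to the
#' end of its rightmost exon; this is the unit of transcript-level matching
#' between assemblies.
#'
#' @param exons exon table from [read_gtf()].
#' @return data.frame `id, chrom, start, end, strand, gene_id`, ordered by
#'   `id`.
#' @export
transcript_spans <- function(exons) {
  check_intervals(exons, require_strand = TRUE, what = "exon")
  ids <- sort(unique(exons$transcript_id))
  i <- match(ids, exons$transcript_id)
  data.frame(
    id = ids,
    chrom = exons$chrom[i],
    start = as.integer(tapply(exons$start, exons$transcript_id, min)[ids]),
    end = as.integer(tapply(exons$end, exons$transcript_id, max)[ids]),
    strand = exons$strand[i],
    gene_id = exons$gene_id[i],
    stringsAsFactors = FALSE
  )
}

#' Exon records as matchable intervals
#'
#' @param exons exon table.
#' @return data.frame `id, chrom, start, end, strand` with one row per exon
#'   record; `id` is `transcript_id:exon_rank`.
#' @export
exon_records <- function(exons) {
  if (is.null(exons$exon_rank)) exons <- order_exons(exons)
  data.frame(
    id = paste0(exons$transcript_id, ":", exons$exon_rank),
    chrom = exons$chrom, start = exons$start, end = exons$end,
    strand = exons$strand, stringsAsFactors = FALSE
  )
}

# Candidate pairs with |dstart| <= w and |dend| <= w, same chrom and strand.
# Found via point overlap of start coordinates expanded by w, to stay
# near-linear in input size.
wiggle_candidates <- function(a, b, wiggle) {
  ga <- GenomicRanges::GRanges(a$chrom,
                               IRanges::IRanges(a$start - wiggle,
                                                a$start + wiggle),
                               strand = a$strand)
  gb <- GenomicRanges::GRanges(b$chrom, IRanges::IRanges(b$start, b$start),
                               strand = b$strand)
  h <- suppressWarnings(GenomicRanges::findOverlaps(ga, gb,
                                                    ignore.strand = FALSE))
  ai <- S4Vectors::queryHits(h); bi <- S4Vectors::subjectHits(h)
  keep <- abs(a$end[ai] - b$end[bi]) <= wiggle
  data.frame(a = ai[keep], b = bi[keep])
}

#' Match records between two assemblies with coordinate wiggle room
#'
#' Two records are candidate matches when they lie on the same chromosome
#' and strand and both their starts and their ends agree to within `wiggle`
#' bp (default 10, compensating for imprecision in assembled coordinates).
#' A one-to-one matching is then chosen greedily by ascending distance
#' `|dstart| + |dend|`, with deterministic ties broken by coordinates and
#' record ids; leftovers on either side are reported unmatched.
#'
#' @param a,b data.frames with columns `id, chrom, start, end, strand`
#'   (see [transcript_spans()] / [exon_records()]).
#' @param wiggle non-negative tolerance in bp on start and end separately.
#' @return object of class `match_result`: list with `pairs` (data.frame
#'   `id_a, id_b, distance`), `unmatched_a`, `unmatched_b` (character ids),
#'   and `wiggle`.
#' @export
match_records <- function(a, b, wiggle = 10) {
  if (length(wiggle) != 1L || is.na(wiggle) || wiggle < 0) {
    fail("wiggle must be a single non-negative number")
  }
  for (nm in list(a, b)) check_intervals(nm, require_strand = TRUE,
                                         what = "match input")
  if (anyDuplicated(a$id) || anyDuplicated(b$id)) {
    fail("record ids must be unique within each set")
  }
  if (nrow(a) == 0L || nrow(b) == 0L) {
    cand <- data.frame(a = integer(0), b = integer(0))
  } else {
    cand <- wiggle_candidates(a, b, wiggle)
  }
  pairs <- data.frame(id_a = character(0), id_b = character(0),
                      distance = integer(0), stringsAsFactors = FALSE)
  if (nrow(cand) > 0L) {
    dist <- abs(a$start[cand$a] - b$start[cand$b]) +
      abs(a$end[cand$a] - b$end[cand$b])
    o <- order(dist, a$chrom[cand$a], a$start[cand$a], a$end[cand$a],
               a$id[cand$a], b$start[cand$b], b$end[cand$b], b$id[cand$b])
    cand <- cand[o, , drop = FALSE]
    dist <- dist[o]
    used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
    take <- logical(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      ia <- cand$a[k]; ib <- cand$b[k]
      if (!used_a[ia] && !used_b[ib]) {
        used_a[ia] <- TRUE; used_b[ib] <- TRUE; take[k] <- TRUE
      }
    }
    pairs <- data.frame(id_a = a$id[cand$a[take]], id_b = b$id[cand$b[take]],
                        distance = as.integer(dist[take]),
                        stringsAsFactors = FALSE)
    pairs <- pairs[order(pairs$distance, pairs$id_a), , drop = FALSE]
    rownames(pairs) <- NULL
  }
  structure(list(
    pairs = pairs,
    unmatched_a = sort(setdiff(a$id, pairs$id_a)),
    unmatched_b = sort(setdiff(b$id, pairs$id_b)),
    wiggle = wiggle
  ), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result: %d pairs, %d unmatched A, %d unmatched B (wiggle %g bp)>\n",
              nrow(x$pairs), length(x$unmatched_a), length(x$unmatched_b),
              x$wiggle))
  invisible(x)
}

#' Venn-style shared/unique counts for a match result
#'
#' Counts all records and TE-derived records on each side, plus the shared
#' (matched) counts; a shared pair counts as TE-shared only when both
#' members are TE-derived.
#'
#' @param match a [match_records()] result.
#' @param te_a,te_b named logical vectors of TE-derived flags covering
#'   every record id of the respective set.
#' @return data.frame with columns `set` and `count`, rows `A, B, shared,
#'   te_A, te_B, te_shared`.
#' @export
venn_counts <- function(match, te_a, te_b) {
  stopifnot(inherits(match, "match_result"))
  ids_a <- c(match$pairs$id_a, match$unmatched_a)
  ids_b <- c(match$pairs$id_b, match$unmatched_b)
  if (!all(ids_a %in% names(te_a)) || !all(ids_b %in% names(te_b))) {
    fail("TE flag missing for some records")
  }
  both_te <- te_a[match$pairs$id_a] & te_b[match$pairs$id_b]
  data.frame(
    set = c("A", "B", "shared", "te_A", "te_B", "te_shared"),
    count = c(length(ids_a), length(ids_b), nrow(match$pairs),
              sum(te_a[ids_a]), sum(te_b[ids_b]), sum(both_te)),
    stringsAsFactors = FALSE
  )
}
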