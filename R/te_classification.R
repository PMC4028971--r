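# Classify exons and transcripts as TE-derived by genomic overlap with
# repeat annotation; identify first exons and TSSs; summarize fractions.

#' Classify exons and transcripts as TE-derived
#'
#' An exon is TE-derived if any part of it overlaps a repeat annotation
#' (>= 1 bp, strand ignored); a transcript is TE-derived if any of its
#' exons is, and additionally carries a `te_first_exon` flag when its first
#' exon (transcription order) is TE-derived. Overlapping repeats are
#' recorded per exon so that downstream family attribution knows which
#' families donated sequence to which exons.
#'
#' @param exons exon table from [read_gtf()] (or [simulate_transcriptome()]).
#' @param tes repeat annotation from [read_repeatmasker()], or an
#'   [interval_index()] built over one.
#' @return object of class `te_classification`: a list with
#'   \describe{
#'     \item{exons}{input exons plus `te_derived` and `is_first` flags}
#'     \item{hits}{data.frame `exon` (row in `exons`), `te` (row in the
#'       repeat table), `family`}
#'     \item{transcripts}{one row per transcript: `transcript_id, gene_id,
#'       chrom, strand, n_exons, te_derived, te_first_exon`}
#'     \item{tes}{the repeat table used}
#'   }
#' @export
classify_exons <- function(exons, tes) {
  idx <- if (inherits(tes, "interval_index")) tes else interval_index(tes)
  te_tab <- idx$data
  if (is.null(te_tab$family)) {
    fail("repeat table must carry a 'family' column (see read_repeatmasker)")
  }
  check_intervals(exons, require_strand = TRUE, what = "exon")
  if (is.null(exons$exon_rank)) exons <- order_exons(exons)

  hits <- overlap_hits(idx, exons, ignore_strand = TRUE)
  hits <- data.frame(exon = hits$query, te = hits$subject,
                     family = te_tab$family[hits$subject],
                     stringsAsFactors = FALSE)

  exons$te_derived <- seq_len(nrow(exons)) %in% hits$exon
  exons$is_first <- exons$exon_rank == 1L

  tx_flag <- tapply(exons$te_derived, exons$transcript_id, any)
  first_rows <- exons[exons$is_first, , drop = FALSE]
  tx_first <- stats::setNames(first_rows$te_derived, first_rows$transcript_id)
  tx_ids <- names(tx_flag)
  meta <- exons[match(tx_ids, exons$transcript_id), , drop = FALSE]
  transcripts <- data.frame(
    transcript_id = tx_ids,
    gene_id = meta$gene_id,
    chrom = meta$chrom,
    strand = meta$strand,
    n_exons = as.integer(table(exons$transcript_id)[tx_ids]),
    te_derived = as.logical(tx_flag),
    te_first_exon = as.logical(tx_first[tx_ids]),
    stringsAsFactors = FALSE
  )
  transcripts <- transcripts[order(transcripts$transcript_id), , drop = FALSE]
  rownames(transcripts) <- NULL

  structure(list(exons = exons, hits = hits, transcripts = transcripts,
                 tes = te_tab),
            class = "te_classification")
}

#' @export
print.te_classification <- function(x, ...) {
  cat(sprintf(paste0("<te_classification: %d exons (%d TE-derived), ",
                     "%d transcripts (%d TE-derived, %d TE first exon)>\n"),
              nrow(x$exons), sum(x$exons$te_derived),
              nrow(x$transcripts), sum(x$transcripts$te_derived),
              sum(x$transcripts$te_first_exon)))
  invisible(x)
}

#' First exon of each transcript
#'
#' The first exon in transcription order: minimal start on `+`, maximal end
#' on `-`. Ties (possible only for degenerate inputs) are broken by longer
#' exon, then by position, so the result is deterministic.
#'
#' @param exons exon table with `transcript_id`, `strand` in `{+,-}`.
#' @return one exon row per transcript, ordered by `transcript_id`.
#' @export
first_exons <- function(exons) {
  check_intervals(exons, require_strand = TRUE, what = "exon")
  if (nrow(exons) == 0L) return(exons)
  key <- ifelse(exons$strand == "+", 1, -1) * exons$start
  # transcription-order position, then longer exon first, then coordinates
  o <- order(exons$transcript_id, key, -(exons$end - exons$start),
             exons$start, exons$end)
  sorted <- exons[o, , drop = FALSE]
  out <- sorted[!duplicated(sorted$transcript_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Transcription start sites
#'
#' The first transcribed base of each transcript: the first exon's `start`
#' on `+`, and `end - 1` (last covered base) on `-`.
#'
#' @param exons exon table (see [first_exons()]).
#' @return data.frame `transcript_id, chrom, pos, strand`.
#' @export
tss <- function(exons) {
  fe <- first_exons(exons)
  data.frame(
    transcript_id = fe$transcript_id,
    chrom = fe$chrom,
    pos = ifelse(fe$strand == "+", fe$start, fe$end - 1L),
    strand = fe$strand,
    stringsAsFactors = FALSE
  )
}

#' Build a fraction summary row
#'
#' Carries the raw ratio alongside the percent rounded half-up to one
#' decimal (the reporting convention for all fractions in the package).
#'
#' @param numerator,denominator non-negative counts, `numerator <=
#'   denominator`, `denominator > 0`.
#' @param label row label.
#' @return data.frame `label, numerator, denominator, fraction, percent`.
#' @export
fraction_summary <- function(numerator, denominator, label = "") {
  if (any(denominator <= 0)) fail("fraction undefined: empty universe")
  if (any(numerator < 0) || any(numerator > denominator)) {
    fail("numerator must lie in [0, denominator]")
  }
  frac <- numerator / denominator
  data.frame(label = label, numerator = numerator, denominator = denominator,
             fraction = frac, percent = round_half_up(100 * frac, 1),
             stringsAsFactors = FALSE)
}

#' Fraction of TE-derived records in a universe
#'
#' @param result a [classify_exons()] result.
#' @param universe `"all_exons"` (every exon record as emitted by the
#'   assembly, no coordinate dedup), `"first_exons"` (one per transcript) or
#'   `"transcripts"`.
#' @return a [fraction_summary()] row.
#' @export
fraction_te_derived <- function(result,
                                universe = c("all_exons", "first_exons",
                                             "transcripts")) {
  stopifnot(inherits(result, "te_classification"))
  universe <- match.arg(universe)
  flags <- switch(universe,
    all_exons = result$exons$te_derived,
    first_exons = result$exons$te_derived[result$exons$is_first],
    transcripts = result$transcripts$te_derived
  )
  if (length(flags) == 0L) fail("fraction undefined: empty universe")
  fraction_summary(sum(flags), length(flags), label = universe)
}
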