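# Expression-binned epigenetic signal profiles for TE-derived exons, and
# the Pearson-r / Student-t quantification of the trend.

#' Bin exons into equal-count expression bins
#'
#' Exons are sorted by ascending FPKM (ties broken deterministically by
#' chromosome, start and transcript id) and split into `nbins` bins of as
#' equal membership as possible: with `n = q * nbins + rem`, the first
#' `rem` bins receive `q + 1` exons and the rest `q`. Equal-count (not
#' equal-width) bins are the only reading under which heavy-tailed FPKM
#' distributions give "equal sized" bins.
#'
#' @param exons exon table carrying an `fpkm` column (or pass `fpkm`).
#' @param nbins number of bins (default 100, the profile resolution used
#'   throughout).
#' @param fpkm optional numeric vector overriding `exons$fpkm`.
#' @return the exon table sorted in binning order with an added integer
#'   `bin` column (1 = lowest expression).
#' @export
bin_by_expression <- function(exons, nbins = 100, fpkm = exons$fpkm) {
  if (is.null(fpkm) || anyNA(fpkm)) {
    fail("every exon needs a non-missing FPKM value for binning")
  }
  n <- nrow(exons)
  if (nbins < 1L) fail("nbins must be >= 1")
  if (n < nbins) fail("fewer exons (%d) than bins (%d)", n, nbins)
  o <- order(fpkm, exons$chrom, exons$start, exons$transcript_id)
  out <- exons[o, , drop = FALSE]
  out$fpkm <- fpkm[o]
  q <- n %/% nbins; rem <- n %% nbins
  sizes <- q + as.integer(seq_len(nbins) <= rem)
  out$bin <- rep.int(seq_len(nbins), sizes)
  rownames(out) <- NULL
  out
}

#' Per-exon signal from a feature track
#'
#' Aggregates one signal track over each exon by genomic overlap:
#' `count` = number of overlapping features, `bp` = total overlapped bp,
#' `score` = sum of scores of overlapping features. `flank` symmetrically
#' extends each exon before querying (default 0: the exon itself).
#'
#' @param exons exon table.
#' @param signals signal feature table for one track (see
#'   [read_bed_features()]) or an [interval_index()] over one.
#' @param mode `"count"`, `"bp"` or `"score"`.
#' @param flank bp added on both sides of each exon.
#' @return non-negative numeric vector, one value per exon row.
#' @export
signal_per_exon <- function(exons, signals, mode = c("count", "bp", "score"),
                            flank = 0) {
  mode <- match.arg(mode)
  idx <- if (inherits(signals, "interval_index")) signals
         else interval_index(signals)
  q <- exons
  if (flank > 0) {
    q$start <- pmax(0L, q$start - as.integer(flank))
    q$end <- q$end + as.integer(flank)
  }
  h <- overlap_hits(idx, q, ignore_strand = TRUE)
  out <- numeric(nrow(exons))
  if (nrow(h) == 0L) return(out)
  val <- switch(mode,
    count = rep(1, nrow(h)),
    bp = overlap_length(q$chrom[h$query], q$start[h$query], q$end[h$query],
                        idx$data$chrom[h$subject], idx$data$start[h$subject],
                        idx$data$end[h$subject]),
    score = {
      s <- idx$data$score[h$subject]
      if (is.null(idx$data$score) || anyNA(s)) {
        fail("score mode requires a score on every overlapping feature")
      }
      s
    })
  agg <- tapply(val, h$query, sum)
  out[as.integer(names(agg))] <- as.numeric(agg)
  out
}

#' Per-bin mean expression and mean signal
#'
#' @param binned output of [bin_by_expression()].
#' @param signal_values named list: track -> per-exon signal vector aligned
#'   to the rows of `binned` (see [signal_per_exon()]).
#' @return data.frame `bin, n_exons, mean_fpkm, track, mean_signal`, one
#'   row per bin per track, sorted by bin then track.
#' @export
bin_profile <- function(binned, signal_values) {
  if (is.null(binned$bin)) fail("input must come from bin_by_expression()")
  stopifnot(is.list(signal_values), length(signal_values) > 0L,
            !is.null(names(signal_values)))
  bins <- sort(unique(binned$bin))
  n_exons <- as.integer(table(binned$bin)[as.character(bins)])
  mean_fpkm <- as.numeric(tapply(binned$fpkm, binned$bin, mean)[as.character(bins)])
  out <- do.call(rbind, lapply(sort(names(signal_values)), function(tr) {
    v <- signal_values[[tr]]
    if (length(v) != nrow(binned)) {
      fail("signal vector '%s' does not align with the binned exons", tr)
    }
    data.frame(bin = bins, n_exons = n_exons, mean_fpkm = mean_fpkm,
               track = tr,
               mean_signal = as.numeric(tapply(v, binned$bin, mean)[as.character(bins)]),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$bin, out$track), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pearson product-moment correlation
#'
#' Thin guard around `stats::cor`: requires equal lengths, n >= 3, and
#' nonzero variance in both vectors.
#'
#' @param x,y numeric vectors.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) fail("x and y must have equal length")
  if (length(x) < 3L) fail("need at least 3 points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    fail("zero variance: correlation undefined")
  }
  stats::cor(x, y)
}

#' Significance of a correlation via the Student-t approximation
#'
#' The sampling distribution of Pearson's r is approximated by Student's t:
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` with `n - 2` degrees of freedom;
#' the p-value is two-sided.
#'
#' @param r correlation, `|r| < 1`.
#' @param n number of points, `>= 3`.
#' @return data.frame `r, n, t, df, p` (class `correlation_result`).
#' @export
pearson_t <- function(r, n) {
  if (n < 3L) fail("need n >= 3")
  if (abs(r) > 1) fail("|r| must be <= 1")
  if (abs(r) == 1) fail("|r| = 1: t statistic infinite")
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  out <- data.frame(r = r, n = as.integer(n), t = t, df = as.integer(n - 2),
                    p = 2 * stats::pt(-abs(t), n - 2))
  class(out) <- c("correlation_result", "data.frame")
  out
}

#' Correlate binned signal with binned expression, per track
#'
#' Computes Pearson's r between the per-bin mean FPKM and per-bin mean
#' signal (n = number of bins, matching the plotted trend) and its
#' Student-t significance for every track in a [bin_profile()].
#'
#' @param profile a [bin_profile()] table.
#' @return data.frame `track, r, n, t, df, p`, one row per track, ordered
#'   by track.
#' @export
correlate_profile <- function(profile) {
  tracks <- sort(unique(profile$track))
  out <- do.call(rbind, lapply(tracks, function(tr) {
    p <- profile[profile$track == tr, , drop = FALSE]
    res <- pearson_t(pearson_r(p$mean_fpkm, p$mean_signal), nrow(p))
    cbind(data.frame(track = tr, stringsAsFactors = FALSE), res)
  }))
  rownames(out) <- NULL
  out
}
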