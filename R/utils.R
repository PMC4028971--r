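# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Reported percentages are rounded half-up to a fixed number of decimals
#' (base `round()` uses round-half-even, which disagrees on exact midpoints).
#' Raw ratios are always carried alongside rounded values.
#'
#' @param x numeric vector.
#' @param digits decimal places to keep.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# Validate a data.frame of genomic intervals (0-based half-open).
# Returns the frame invisibly; stops with an informative message otherwise.
check_intervals <- function(df, require_strand = FALSE, what = "interval") {
  stopifnot(is.data.frame(df))
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop(sprintf("%s table lacks column(s): %s", what, paste(miss, collapse = ", ")))
  }
  if (nrow(df) == 0L) return(invisible(df))
  if (any(is.na(df$chrom)) || any(!nzchar(df$chrom))) {
    stop(sprintf("%s table has empty chromosome names", what))
  }
  if (any(df$start < 0)) stop(sprintf("%s table has negative start coordinates", what))
  if (any(df$end <= df$start)) stop(sprintf("%s table has end <= start", what))
  if (require_strand) {
    if (is.null(df$strand) || any(!df$strand %in% c("+", "-"))) {
      stop(sprintf("%s table requires strand '+' or '-' on every row", what))
    }
  }
  invisible(df)
}

# Convert an interval data.frame to GRanges (internally shifts to 1-based
# closed as GenomicRanges expects). Strand "." or absent becomes "*".
as_granges <- function(df, use_strand = FALSE) {
  s <- if (use_strand && !is.null(df$strand)) {
    ifelse(df$strand %in% c("+", "-"), df$strand, "*")
  } else rep("*", nrow(df))
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = s
  )
}

# stop() without the "Error in ..." call prefix noise
fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
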