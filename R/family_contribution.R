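# Per-family TE contribution normalized by genomic background abundance,
# millidiv-based age ranking, and a chi-square test of heterogeneity.

family_levels <- function() c(TE_FAMILIES, "other")

#' Attribute TE-derived exons (or transcripts) to TE families
#'
#' Each TE-derived record contributes one count to each *distinct* family
#' among its overlapping repeats: an exon overlapping both an Alu and an L1
#' adds 1 to Alu and 1 to L1, but an exon overlapping two Alus adds only 1
#' to Alu.
#'
#' @param classification a [classify_exons()] result.
#' @param level `"exon"` (default; the primitive) or `"transcript"`.
#' @return named integer vector over `Alu, L1, LTR, DNA, L2, MIR, other`.
#' @export
attribute_hits <- function(classification, level = c("exon", "transcript")) {
  stopifnot(inherits(classification, "te_classification"))
  level <- match.arg(level)
  h <- classification$hits
  unit <- if (level == "exon") {
    h$exon
  } else {
    classification$exons$transcript_id[h$exon]
  }
  pairs <- unique(data.frame(unit = unit, family = h$family,
                             stringsAsFactors = FALSE))
  counts <- table(factor(pairs$family, levels = family_levels()))
  stats::setNames(as.integer(counts), family_levels())
}

#' Genomic background abundance per TE family
#'
#' @param tes repeat annotation table.
#' @param mode `"elements"` counts annotation records; `"bp"` sums interval
#'   lengths.
#' @return named numeric vector over the family levels.
#' @export
genomic_abundance <- function(tes, mode = c("elements", "bp")) {
  mode <- match.arg(mode)
  if (is.null(tes) || nrow(tes) == 0L) fail("empty repeat annotation")
  fam <- factor(tes$family, levels = family_levels())
  x <- if (mode == "elements") {
    table(fam)
  } else {
    tapply(tes$end - tes$start, fam, sum, default = 0)
  }
  out <- stats::setNames(as.numeric(x), family_levels())
  out[is.na(out)] <- 0
  out
}

#' Normalize per-family hits by background abundance
#'
#' `normalized = hits / abundance`, dimensionless; families with zero
#' abundance are reported with `normalized = NA` (missing), never divided.
#' Doubling every abundance halves every normalized value.
#'
#' @param hits named counts from [attribute_hits()].
#' @param abundance named abundances from [genomic_abundance()] (one mode).
#' @return data.frame `family, hits, abundance, normalized`, in family
#'   level order.
#' @export
normalize_contribution <- function(hits, abundance) {
  fams <- family_levels()
  hits <- hits[fams]; abundance <- abundance[fams]
  normalized <- ifelse(abundance > 0, hits / abundance, NA_real_)
  data.frame(family = fams, hits = as.integer(hits),
             abundance = as.numeric(abundance), normalized = normalized,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Rank TE families by age (mean millidiv)
#'
#' Divergence from the family consensus (millidiv) is a proxy for element
#' age; families are ranked by ascending mean millidiv, rank 1 = youngest.
#' Only the six named families are ranked ("other" is excluded); ties break
#' alphabetically.
#'
#' @param tes repeat annotation table with `family` and `millidiv`.
#' @return data.frame `family, mean_millidiv, age_rank`, ordered by rank.
#' @export
age_rank <- function(tes) {
  six <- tes[tes$family %in% TE_FAMILIES, , drop = FALSE]
  if (nrow(six) == 0L) fail("no annotations in the six ranked families")
  means <- tapply(six$millidiv, factor(six$family, levels = TE_FAMILIES),
                  mean)
  present <- names(means)[!is.na(means)]
  m <- means[present]
  o <- order(m, present)
  data.frame(family = present[o], mean_millidiv = as.numeric(m[o]),
             age_rank = seq_along(o), stringsAsFactors = FALSE)
}

#' Chi-square test of family contribution heterogeneity
#'
#' Tests whether observed per-family hit counts deviate from expectations
#' proportional to genomic abundance (default) or uniform across families.
#' Families with zero abundance are dropped before testing. `statistic =
#' sum((obs - exp)^2 / exp)`, `df = k - 1`, upper-tail p.
#'
#' @param hits named per-family counts.
#' @param abundance named per-family background abundance.
#' @param expected `"abundance"` (proportional to background) or
#'   `"uniform"`.
#' @return data.frame `statistic, df, p` (class `chi_square_result`).
#' @export
chi_square_families <- function(hits, abundance,
                                expected = c("abundance", "uniform")) {
  expected <- match.arg(expected)
  common <- intersect(names(hits), names(abundance))
  hits <- hits[common]; abundance <- abundance[common]
  keep <- abundance > 0
  hits <- hits[keep]; abundance <- abundance[keep]
  k <- length(hits)
  if (k < 2L) fail("need >= 2 families with positive abundance")
  total <- sum(hits)
  if (total < 1) fail("need at least one hit")
  prob <- if (expected == "abundance") abundance / sum(abundance) else rep(1 / k, k)
  exp_counts <- total * prob
  if (any(exp_counts == 0)) fail("zero expected count")
  statistic <- sum((hits - exp_counts)^2 / exp_counts)
  out <- data.frame(statistic = statistic, df = k - 1L,
                    p = stats::pchisq(statistic, k - 1L, lower.tail = FALSE))
  class(out) <- c("chi_square_result", "data.frame")
  out
}

#' Full per-family contribution table
#'
#' Convenience wrapper: attribution, background abundance, normalization,
#' age ranking and the heterogeneity test in one call.
#'
#' @param classification a [classify_exons()] result.
#' @param tes repeat annotation (defaults to the one stored in the
#'   classification).
#' @param mode abundance mode, see [genomic_abundance()].
#' @param level attribution level, see [attribute_hits()].
#' @return list with `contribution` (normalized table joined with
#'   `mean_millidiv` and `age_rank`) and `chi_square`.
#' @export
family_contribution <- function(classification, tes = classification$tes,
                                mode = c("elements", "bp"),
                                level = c("exon", "transcript")) {
  hits <- attribute_hits(classification, level = match.arg(level))
  ab <- genomic_abundance(tes, mode = match.arg(mode))
  contrib <- normalize_contribution(hits, ab)
  ranks <- age_rank(tes)
  contrib$mean_millidiv <- ranks$mean_millidiv[match(contrib$family,
                                                     ranks$family)]
  contrib$age_rank <- ranks$age_rank[match(contrib$family, ranks$family)]
  list(contribution = contrib,
       chi_square = chi_square_families(hits, ab))
}
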