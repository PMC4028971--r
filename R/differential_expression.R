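# Two-sample t-test per gene between two conditions, BH-FDR q-values, and
# the intersection with TE-first-exon flags.

#' Classical two-sample pooled-variance t-test
#'
#' Student's t with `df = n_a + n_b - 2` and a two-sided p-value. The
#' degenerate case of zero pooled variance is defined as `t = 0, p = 1`
#' when the group means are equal, and is an error when they differ (the
#' statistic would be infinite).
#'
#' @param x,y numeric replicate values of the two groups, each of length
#'   >= 2.
#' @return data.frame `t, df, p`.
#' @export
t_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) fail("each group needs >= 2 values")
  na <- length(x); nb <- length(y)
  df <- na + nb - 2L
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / df
  if (sp2 == 0) {
    if (mean(x) == mean(y)) {
      return(data.frame(t = 0, df = df, p = 1))
    }
    fail("zero pooled variance with unequal means: t undefined")
  }
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / na + 1 / nb))
  data.frame(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: with sorted p-values, `q_(i) = min_{j >= i}
#' (p_(j) * m / j)` capped at 1, returned in the input order. Delegates to
#' `stats::p.adjust(method = "BH")` after validating the input range.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    fail("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Gene-level expression from a transcript FPKM table
#'
#' Gene expression is the sum of the gene's transcripts' FPKM in each
#' sample.
#'
#' @param fpkm long table `transcript_id, sample, fpkm` (see
#'   [read_fpkm()]).
#' @param tx2gene data.frame `transcript_id, gene_id` mapping every
#'   transcript.
#' @return numeric matrix, genes x samples.
#' @export
gene_expression <- function(fpkm, tx2gene) {
  if (!all(fpkm$transcript_id %in% tx2gene$transcript_id)) {
    fail("some transcripts lack a gene assignment")
  }
  gene <- tx2gene$gene_id[match(fpkm$transcript_id, tx2gene$transcript_id)]
  tab <- tapply(fpkm$fpkm, list(gene, fpkm$sample), sum, default = 0)
  m <- as.matrix(tab)
  m[order(rownames(m)), order(colnames(m)), drop = FALSE]
}

#' Per-gene differential expression between two groups
#'
#' Equal-variance Student's t per gene between the two sample groups, with
#' BH-FDR q-values. Genes are tested only if expressed (mean FPKM > 0 in at
#' least one group). With few replicates per group, FPKM is
#' `log2(x + 1)`-transformed before testing (the default) to stabilize
#' variance; `transform = "none"` tests raw FPKM. `welch = TRUE` switches
#' to the unequal-variance statistic.
#'
#' @param expr genes x samples matrix from [gene_expression()].
#' @param groups list of two character vectors of sample (column) names,
#'   e.g. `list(A = c("A1","A2"), B = c("B1","B2"))`.
#' @param alpha significance level on the q-value (default 0.05).
#' @param transform `"log2p1"` or `"none"`.
#' @param welch use Welch's unequal-variance t instead of the pooled form.
#' @return data.frame `gene_id, mean_a, mean_b, t_stat, p, q, significant`,
#'   ordered by `gene_id`; means are on the raw FPKM scale.
#' @export
de_test <- function(expr, groups, alpha = 0.05,
                    transform = c("log2p1", "none"), welch = FALSE) {
  transform <- match.arg(transform)
  stopifnot(is.list(groups), length(groups) == 2L)
  sa <- groups[[1]]; sb <- groups[[2]]
  if (!all(c(sa, sb) %in% colnames(expr))) {
    fail("group sample names must be columns of the expression matrix")
  }
  a <- expr[, sa, drop = FALSE]; b <- expr[, sb, drop = FALSE]
  expressed <- rowMeans(a) > 0 | rowMeans(b) > 0
  a <- a[expressed, , drop = FALSE]; b <- b[expressed, , drop = FALSE]
  ta <- if (transform == "log2p1") log2(a + 1) else a
  tb <- if (transform == "log2p1") log2(b + 1) else b
  res <- lapply(seq_len(nrow(ta)), function(i) {
    if (welch) {
      ht <- stats::t.test(ta[i, ], tb[i, ], var.equal = FALSE)
      data.frame(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value)
    } else {
      t_test(ta[i, ], tb[i, ])
    }
  })
  res <- do.call(rbind, res)
  out <- data.frame(
    gene_id = rownames(ta),
    mean_a = unname(rowMeans(a)), mean_b = unname(rowMeans(b)),
    t_stat = res$t, p = res$p, q = bh_fdr(res$p),
    stringsAsFactors = FALSE
  )
  out$significant <- out$q < alpha
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Differentially expressed genes with a TE-derived first exon
#'
#' Intersects the DE results with the per-gene TE-first-exon flags: genes
#' with `q < alpha` whose (any) transcript has a TE-derived first exon,
#' sorted by ascending q then gene id.
#'
#' @param de a [de_test()] result.
#' @param te_first_exon named logical vector by `gene_id`, covering every
#'   tested gene.
#' @param alpha q-value threshold (default 0.05).
#' @return subset of `de` rows, with a `te_first_exon` column.
#' @export
de_te_first_exon_genes <- function(de, te_first_exon, alpha = 0.05) {
  if (!all(de$gene_id %in% names(te_first_exon))) {
    fail("TE-first-exon flag missing for some genes")
  }
  de$te_first_exon <- unname(te_first_exon[de$gene_id])
  out <- de[de$q < alpha & de$te_first_exon, , drop = FALSE]
  out <- out[order(out$q, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
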