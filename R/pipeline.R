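# End-to-end orchestration: classify -> compare -> families -> episignal ->
# diffexp from one config, with per-stage TSV outputs and a JSON summary.

#' Pipeline run configuration
#'
#' Collects input paths and analysis parameters. Defaults mirror the
#' pipeline's reporting conventions: 10 bp matching wiggle, 100 expression
#' bins, q < 0.05 significance.
#'
#' @param gtf_a primary assembly GTF (required).
#' @param te repeat annotation file (required).
#' @param out_dir output directory (required).
#' @param te_dialect `"bed"` or `"out"` (see [read_repeatmasker()]).
#' @param gtf_b optional second assembly for cross-assembly matching.
#' @param fpkm optional expression sidecar TSV (see [read_fpkm()]).
#' @param signals optional named character vector: track -> BED path.
#' @param groups optional list of two character vectors of sample names
#'   for differential expression, e.g. `list(A = c("A1","A2"), B =
#'   c("B1","B2"))`.
#' @param wiggle,nbins,alpha,abundance_mode,signal_mode,flank,attribution_level
#'   analysis parameters passed through to the respective stages.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(gtf_a, te, out_dir, te_dialect = "bed",
                            gtf_b = NULL, fpkm = NULL, signals = NULL,
                            groups = NULL, wiggle = 10, nbins = 100,
                            alpha = 0.05, abundance_mode = "elements",
                            signal_mode = "count", flank = 0,
                            attribution_level = "exon") {
  cfg <- list(gtf_a = gtf_a, te = te, out_dir = out_dir,
              te_dialect = te_dialect, gtf_b = gtf_b, fpkm = fpkm,
              signals = signals, groups = groups, wiggle = wiggle,
              nbins = nbins, alpha = alpha,
              abundance_mode = abundance_mode, signal_mode = signal_mode,
              flank = flank, attribution_level = attribution_level)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_pipeline_config <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  paths <- c(config$gtf_a, config$te, config$gtf_b, config$fpkm,
             unname(config$signals))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L) {
    fail("input file(s) not found: %s", paste(missing, collapse = ", "))
  }
  if (!is.null(config$signals) && is.null(names(config$signals))) {
    fail("signals must be a named vector: track = path")
  }
  invisible(config)
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full exonization analysis pipeline
#'
#' Executes the stages in dependency order, writing each stage's TSV
#' outputs into `out_dir` before the next stage starts, then a
#' `summary.json` holding every fraction, venn count, chi-square,
#' correlation and DE count the run produced. Optional stages (compare,
#' episignal, diffexp) run only when their inputs are configured. On a
#' stage failure, a `FAILED` marker naming the stage is left in `out_dir`
#' and the error is re-raised; outputs of completed stages are retained.
#'
#' @param config a [pipeline_config()].
#' @return the summary, invisibly (a nested list mirroring
#'   `summary.json`).
#' @export
run_pipeline <- function(config) {
  validate_pipeline_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  summary <- list(parameters = list(wiggle = config$wiggle,
                                    nbins = config$nbins,
                                    alpha = config$alpha))
  current_stage <- "load"
  on_fail <- function(e) {
    writeLines(sprintf("FAILED at stage: %s\n%s", current_stage,
                       conditionMessage(e)),
               file.path(out, "FAILED"))
    stop(sprintf("pipeline stage '%s' failed: %s", current_stage,
                 conditionMessage(e)), call. = FALSE)
  }
  tryCatch({
    exons_a <- read_gtf(config$gtf_a, assembly = "A")
    tes <- read_repeatmasker(config$te, dialect = config$te_dialect)
    stage_log("load", "%d exons, %d repeats", nrow(exons_a), nrow(tes))

    current_stage <- "classify"
    cls <- classify_exons(exons_a, tes)
    fractions <- rbind(fraction_te_derived(cls, "all_exons"),
                       fraction_te_derived(cls, "first_exons"),
                       fraction_te_derived(cls, "transcripts"))
    write_table(fractions, file.path(out, "fractions.tsv"))
    flags_bed <- data.frame(cls$exons$chrom, cls$exons$start,
                            cls$exons$end, cls$exons$transcript_id,
                            as.integer(cls$exons$te_derived),
                            cls$exons$strand)
    utils::write.table(flags_bed, file.path(out, "exon_flags.bed"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    summary$fractions <- fractions
    stage_log("classify", "all-exon %.1f%%, first-exon %.1f%%",
              fractions$percent[1], fractions$percent[2])

    if (!is.null(config$gtf_b)) {
      current_stage <- "compare"
      exons_b <- read_gtf(config$gtf_b, assembly = "B")
      cls_b <- classify_exons(exons_b, tes)
      sp_a <- transcript_spans(exons_a); sp_b <- transcript_spans(exons_b)
      m_tx <- match_records(sp_a, sp_b, wiggle = config$wiggle)
      te_tx_a <- stats::setNames(cls$transcripts$te_derived,
                                 cls$transcripts$transcript_id)
      te_tx_b <- stats::setNames(cls_b$transcripts$te_derived,
                                 cls_b$transcripts$transcript_id)
      venn_tx <- venn_counts(m_tx, te_tx_a, te_tx_b)
      er_a <- exon_records(cls$exons); er_b <- exon_records(cls_b$exons)
      m_ex <- match_records(er_a, er_b, wiggle = config$wiggle)
      venn_ex <- venn_counts(
        m_ex,
        stats::setNames(cls$exons$te_derived, er_a$id),
        stats::setNames(cls_b$exons$te_derived, er_b$id))
      write_table(m_tx$pairs, file.path(out, "matches_transcripts.tsv"))
      write_table(venn_tx, file.path(out, "venn_transcripts.tsv"))
      write_table(m_ex$pairs, file.path(out, "matches_exons.tsv"))
      write_table(venn_ex, file.path(out, "venn_exons.tsv"))
      summary$venn <- list(transcripts = venn_tx, exons = venn_ex)
      stage_log("compare", "%d shared transcripts, %d shared exons",
                nrow(m_tx$pairs), nrow(m_ex$pairs))
    }

    current_stage <- "families"
    fc <- family_contribution(cls, tes, mode = config$abundance_mode,
                              level = config$attribution_level)
    write_table(fc$contribution, file.path(out, "family_contribution.tsv"))
    write_table(as.data.frame(fc$chi_square),
                file.path(out, "chi_square.tsv"))
    summary$family_contribution <- fc$contribution
    summary$chi_square <- as.data.frame(fc$chi_square)
    stage_log("families", "chi-square %.1f (df %d, p %.3g)",
              fc$chi_square$statistic, fc$chi_square$df, fc$chi_square$p)

    fpkm_tab <- NULL
    if (!is.null(config$fpkm)) fpkm_tab <- read_fpkm(config$fpkm)

    if (!is.null(fpkm_tab) && !is.null(config$signals)) {
      current_stage <- "episignal"
      use_samples <- if (!is.null(config$groups)) config$groups[[1]] else
        unique(fpkm_tab$sample)
      sub <- fpkm_tab[fpkm_tab$sample %in% use_samples, , drop = FALSE]
      tx_mean <- tapply(sub$fpkm, sub$transcript_id, mean)
      te_ex <- cls$exons[cls$exons$te_derived, , drop = FALSE]
      te_ex$fpkm <- as.numeric(tx_mean[te_ex$transcript_id])
      te_ex <- te_ex[!is.na(te_ex$fpkm), , drop = FALSE]
      binned <- bin_by_expression(te_ex, nbins = config$nbins)
      sig_values <- lapply(stats::setNames(nm = names(config$signals)),
                           function(tr) {
        feats <- read_bed_features(config$signals[[tr]], track = tr)
        signal_per_exon(binned, feats, mode = config$signal_mode,
                        flank = config$flank)
      })
      profile <- bin_profile(binned, sig_values)
      corr <- correlate_profile(profile)
      write_table(profile, file.path(out, "bin_profile.tsv"))
      write_table(corr, file.path(out, "correlations.tsv"))
      summary$correlations <- corr
      stage_log("episignal", "%d TE-derived exons in %d bins, %d tracks",
                nrow(binned), config$nbins, length(sig_values))
    }

    if (!is.null(fpkm_tab) && !is.null(config$groups)) {
      current_stage <- "diffexp"
      tx2gene <- unique(exons_a[, c("transcript_id", "gene_id")])
      ge <- gene_expression(fpkm_tab, tx2gene)
      de <- de_test(ge, config$groups, alpha = config$alpha)
      gene_first <- tapply(cls$transcripts$te_first_exon,
                           cls$transcripts$gene_id, any)
      te_de <- de_te_first_exon_genes(
        de, stats::setNames(as.logical(gene_first), names(gene_first)),
        alpha = config$alpha)
      write_table(de, file.path(out, "de_genes.tsv"))
      write_table(te_de, file.path(out, "de_te_first_exon_genes.tsv"))
      summary$de <- list(n_tested = nrow(de),
                         n_significant = sum(de$significant),
                         n_te_first_exon_significant = nrow(te_de))
      stage_log("diffexp", "%d genes tested, %d significant, %d with TE first exon",
                nrow(de), sum(de$significant), nrow(te_de))
    }

    current_stage <- "summary"
    jsonlite::write_json(summary, file.path(out, "summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    summary
  }, error = on_fail) |> invisible()
}
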