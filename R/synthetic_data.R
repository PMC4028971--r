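# Ground-truth-labelled synthetic inputs: TE landscape, transcriptome with
# planted TE-overlap rates, two-condition expression with planted DE genes,
# and signal tracks whose intensity tracks expression. Truth is emitted as
# sidecar tables, never inferable from the data files themselves.

#' Synthetic study configuration
#'
#' All planted parameters for the generator, with defaults at desk scale
#' (two 5-Mb chromosomes, 600 TEs per family, 2000 transcripts) so the
#' whole pipeline runs in seconds. Family millidiv means are ordered
#' Alu < L1 < LTR < DNA < L2 < MIR, the youngest-to-oldest order the age
#' ranking should recover. `rho_first > rho_later` plants the first-exon
#' enrichment; positive track slopes plant the expression-signal trend.
#'
#' @param seed RNG seed; the same seed yields a byte-identical bundle.
#' @param genome named numeric vector of chromosome lengths (bp).
#' @param te_counts named count of elements per family.
#' @param te_length named list of `c(min, max)` element lengths (bp).
#' @param millidiv_mean,millidiv_sd per-family divergence (per-mille)
#'   normal parameters, truncated at 0.
#' @param n_transcripts number of transcripts in assembly A.
#' @param exon_count_lambda,exon_count_max exons per transcript are
#'   `1 + min(Poisson(lambda), max - 1)`.
#' @param exon_length,intron_length `c(min, max)` uniform ranges (bp).
#' @param rho_first,rho_later probability that a first / later exon is
#'   placed overlapping a TE.
#' @param fpkm_meanlog,fpkm_sdlog lognormal baseline gene FPKM.
#' @param rep_sdlog replicate noise sd on the log scale (~ within-group CV).
#' @param n_samples_per_group replicates per condition.
#' @param de_fraction,de_log2fc fraction of genes with a planted expression
#'   shift, and its magnitude in log2 units (random sign per gene).
#' @param tracks named list of per-track `c(a, b, noise)`: expected peak
#'   count per exon is `max(0, a + b * log(FPKM + 1) + N(0, noise))`.
#' @param peak_width signal peak width (bp).
#' @param shared_fraction fraction of assembly-A transcripts duplicated
#'   (with coordinate jitter) into assembly B.
#' @param novel_fraction assembly-B-only transcripts, as a fraction of
#'   `n_transcripts`.
#' @param jitter_bp maximum absolute coordinate jitter applied to shared
#'   records (must stay within the matching wiggle, default 10).
#' @param multi_tx_fraction fraction of transcripts living in two-transcript
#'   genes.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(
    seed = 1L,
    genome = c(chr1 = 5e6, chr2 = 5e6),
    te_counts = c(Alu = 600, L1 = 600, LTR = 600, DNA = 600, L2 = 600,
                  MIR = 600),
    te_length = list(Alu = c(200, 350), L1 = c(400, 3000),
                     LTR = c(300, 1500), DNA = c(200, 1500),
                     L2 = c(300, 1000), MIR = c(150, 300)),
    millidiv_mean = c(Alu = 110, L1 = 160, LTR = 200, DNA = 240, L2 = 280,
                      MIR = 330),
    millidiv_sd = c(Alu = 40, L1 = 50, LTR = 55, DNA = 60, L2 = 60,
                    MIR = 60),
    n_transcripts = 2000,
    exon_count_lambda = 2, exon_count_max = 6,
    exon_length = c(100, 300),
    intron_length = c(200, 2000),
    rho_first = 0.4, rho_later = 0.1,
    fpkm_meanlog = 1, fpkm_sdlog = 1,
    rep_sdlog = 0.1,
    n_samples_per_group = 2,
    de_fraction = 0.05, de_log2fc = 2,
    tracks = list(H3K4me3 = c(a = 0.2, b = 0.8, noise = 0.5),
                  H3K9ac = c(a = 0.2, b = 0.8, noise = 0.5),
                  H3K27ac = c(a = 0.2, b = 0.8, noise = 0.5),
                  H3K36me3 = c(a = 0.2, b = 0.8, noise = 0.5),
                  DHS = c(a = 0.2, b = 0.8, noise = 0.5),
                  CAGE = c(a = 0.2, b = 0.8, noise = 0.5)),
    peak_width = 10,
    shared_fraction = 0.7,
    novel_fraction = 0.3,
    jitter_bp = 10,
    multi_tx_fraction = 0.15) {
  cfg <- list(seed = as.integer(seed), genome = genome,
              te_counts = te_counts, te_length = te_length,
              millidiv_mean = millidiv_mean, millidiv_sd = millidiv_sd,
              n_transcripts = as.integer(n_transcripts),
              exon_count_lambda = exon_count_lambda,
              exon_count_max = as.integer(exon_count_max),
              exon_length = exon_length, intron_length = intron_length,
              rho_first = rho_first, rho_later = rho_later,
              fpkm_meanlog = fpkm_meanlog, fpkm_sdlog = fpkm_sdlog,
              rep_sdlog = rep_sdlog,
              n_samples_per_group = as.integer(n_samples_per_group),
              de_fraction = de_fraction, de_log2fc = de_log2fc,
              tracks = tracks, peak_width = as.integer(peak_width),
              shared_fraction = shared_fraction,
              novel_fraction = novel_fraction,
              jitter_bp = as.integer(jitter_bp),
              multi_tx_fraction = multi_tx_fraction)
  probs <- c(cfg$rho_first, cfg$rho_later, cfg$de_fraction,
             cfg$shared_fraction, cfg$multi_tx_fraction)
  if (any(probs < 0 | probs > 1)) fail("probabilities must lie in [0, 1]")
  if (any(cfg$genome <= 0) || cfg$n_transcripts < 1 ||
      any(cfg$te_counts < 0)) {
    fail("genome lengths, transcript and TE counts must be positive")
  }
  if (is.null(names(cfg$genome))) fail("genome must be a named vector")
  class(cfg) <- "synthetic_config"
  cfg
}

rnorm_trunc0 <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < 0)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

rint <- function(n, lo, hi) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

te_class_map <- c(Alu = "SINE/Alu", L1 = "LINE/L1", LTR = "LTR/ERVL",
                  DNA = "DNA/hAT-Charlie", L2 = "LINE/L2", MIR = "SINE/MIR")

#' Simulate a TE landscape
#'
#' Per family, `count` elements with uniform positions (chromosome chosen
#' proportionally to its length), uniform lengths within the family's
#' range, and millidiv drawn from the family normal truncated at 0.
#' Elements never cross chromosome bounds. Errors if the demanded TE bp
#' exceeds the genome.
#'
#' @param config a [synthetic_config()]. The caller controls the RNG seed
#'   (see [simulate_bundle()], which seeds once for the whole bundle).
#' @return repeat annotation table in the shape of [read_repeatmasker()],
#'   sorted by chromosome and start.
#' @export
simulate_te_landscape <- function(config) {
  fams <- names(config$te_counts)
  rows <- lapply(fams, function(f) {
    n <- config$te_counts[[f]]
    if (n == 0L) return(NULL)
    lens <- rint(n, config$te_length[[f]][1], config$te_length[[f]][2])
    chrom <- sample(names(config$genome), n, replace = TRUE,
                    prob = config$genome)
    start <- vapply(seq_len(n), function(i) {
      rint(1L, 0L, as.integer(config$genome[[chrom[i]]]) - lens[i])
    }, integer(1))
    data.frame(chrom = chrom, start = start, end = start + lens,
               strand = sample(c("+", "-"), n, replace = TRUE),
               name = paste0(f, "Sim", seq_len(n)),
               raw_class = te_class_map[[f]],
               family = f,
               millidiv = rnorm_trunc0(n, config$millidiv_mean[[f]],
                                       config$millidiv_sd[[f]]),
               stringsAsFactors = FALSE)
  })
  te <- do.call(rbind, rows)
  if (is.null(te) || nrow(te) == 0L) fail("no TE elements requested")
  if (sum(te$end - te$start) > sum(config$genome)) {
    fail("total TE bp exceeds genome size")
  }
  te <- te[order(te$chrom, te$start, te$end), , drop = FALSE]
  rownames(te) <- NULL
  te
}

# Per-chromosome TE lookup used during exon placement.
te_lookup <- function(tes, genome) {
  out <- lapply(names(genome), function(ch) {
    sub <- tes[tes$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    list(start = sub$start, end = sub$end,
         maxlen = if (nrow(sub) > 0L) max(sub$end - sub$start) else 0L)
  })
  names(out) <- names(genome)
  out
}

# Count of elements in sorted v that are <= x (binary search; avoids
# findInterval's per-call sortedness scan in the placement hot loop).
bsearch_le <- function(v, x) {
  lo <- 0L; hi <- length(v)
  while (lo < hi) {
    mid <- (lo + hi + 1L) %/% 2L
    if (v[mid] <= x) lo <- mid else hi <- mid - 1L
  }
  lo
}

# Does [s, e) overlap any TE on this chromosome?
overlaps_te <- function(tl, s, e) {
  n <- length(tl$start)
  if (n == 0L) return(FALSE)
  hi <- bsearch_le(tl$start, e - 1L)            # last start < e
  lo <- bsearch_le(tl$start, s - tl$maxlen) + 1L
  if (lo > hi) return(FALSE)
  any(tl$end[lo:hi] > s)
}

# Place one transcript's exons left-to-right on the genome. `planted` are
# genomic-order TE-overlap flags. Returns NULL when placement fails after
# bounded retries.
place_transcript <- function(config, te_by_chrom, planted) {
  k <- length(planted)
  genome <- config$genome
  exl <- config$exon_length; inl <- config$intron_length
  for (attempt in seq_len(20L)) {
    ch <- sample(names(genome), 1L, prob = genome)
    tl <- te_by_chrom[[ch]]
    clen <- as.integer(genome[[ch]])
    lens <- rint(k, exl[1], exl[2])
    anchor <- rint(1L, 0L, max(0L, clen - 100000L))
    pos <- anchor
    starts <- integer(k); ok <- TRUE
    for (j in seq_len(k)) {
      lo <- if (j == 1L) pos else pos + inl[1]
      if (planted[j]) {
        n_te <- length(tl$start)
        i0 <- bsearch_le(tl$start, lo - 1L) + 1L  # first TE start >= lo
        if (i0 > n_te) { ok <- FALSE; break }
        i <- i0 + sample.int(min(3L, n_te - i0 + 1L), 1L) - 1L
        smin <- max(lo, tl$start[i] - lens[j] + 1L)
        smax <- tl$end[i] - 1L
        s <- rint(1L, smin, smax)
        if (s + lens[j] > clen) { ok <- FALSE; break }
      } else {
        placed <- FALSE
        for (r in seq_len(50L)) {
          s <- if (j == 1L) anchor + rint(1L, 0L, 10000L)
               else pos + rint(1L, inl[1], inl[2])
          if (s + lens[j] > clen) next
          if (!overlaps_te(tl, s, s + lens[j])) { placed <- TRUE; break }
        }
        if (!placed) { ok <- FALSE; break }
      }
      starts[j] <- s
      pos <- s + lens[j]
    }
    if (ok) {
      return(list(chrom = ch, start = starts, end = starts + lens))
    }
  }
  NULL
}

# Generate `n` transcripts with planted per-exon TE-overlap flags.
# Returns exon rows (genomic order) and the transcription-order truth.
generate_transcripts <- function(config, te_by_chrom, n, id_prefix,
                                 gene_ids) {
  tid <- sprintf("%s%05d", id_prefix, seq_len(n))
  ks <- integer(n)
  chrom_t <- character(n)
  strand_t <- character(n)
  starts <- vector("list", n); ends <- vector("list", n)
  flags <- vector("list", n)
  for (t in seq_len(n)) {
    k <- 1L + min(stats::rpois(1L, config$exon_count_lambda),
                  config$exon_count_max - 1L)
    strand <- sample(c("+", "-"), 1L)
    flags_tx <- stats::rbinom(k, 1L,
                              c(config$rho_first,
                                rep(config$rho_later, k - 1L))) == 1L
    flags_gen <- if (strand == "+") flags_tx else rev(flags_tx)
    placed <- place_transcript(config, te_by_chrom, flags_gen)
    if (is.null(placed)) {
      fail("could not place transcript %d after bounded retries", t)
    }
    ks[t] <- k
    chrom_t[t] <- placed$chrom
    strand_t[t] <- strand
    starts[[t]] <- placed$start
    ends[[t]] <- placed$end
    flags[[t]] <- flags_tx
  }
  exons <- data.frame(
    chrom = rep.int(chrom_t, ks), start = unlist(starts),
    end = unlist(ends), strand = rep.int(strand_t, ks),
    gene_id = rep.int(gene_ids, ks), transcript_id = rep.int(tid, ks),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    transcript_id = rep.int(tid, ks),
    exon_rank = sequence(ks),
    te_planted = unlist(flags),
    stringsAsFactors = FALSE
  )
  list(exons = exons, truth = truth)
}

# Random gene labels: a multi_tx_fraction of transcripts live in
# two-transcript genes (label-level grouping; loci are independent).
assign_genes <- function(n, multi_fraction, prefix = "g") {
  n2 <- floor(multi_fraction * n / 2)
  n1 <- n - 2L * n2
  idx <- sample(rep.int(seq_len(n1 + n2), times = c(rep(1L, n1),
                                                    rep(2L, n2))))
  sprintf("%s%05d", prefix, idx)
}

#' Simulate two transcriptome assemblies with planted TE overlap
#'
#' Assembly A contains `n_transcripts` transcripts whose first exon
#' (transcription order) overlaps a TE with probability `rho_first` and
#' each later exon with probability `rho_later`; non-planted exons are
#' rejection-sampled to avoid all TEs, so the classification flags recover
#' the planted labels exactly. Assembly B contains a `shared_fraction` of
#' A's transcripts with every exon boundary jittered by at most
#' `jitter_bp`, plus `novel_fraction * n_transcripts` B-only transcripts.
#'
#' @param config a [synthetic_config()].
#' @param tes TE landscape from [simulate_te_landscape()].
#' @return list with `exons_a`, `exons_b` (exon tables in [read_gtf()]
#'   shape), `exon_truth` (`transcript_id, exon_rank, te_planted`), and
#'   `shared` (`id_a, id_b` pairs of duplicated transcripts).
#' @export
simulate_transcriptome <- function(config, tes) {
  te_by_chrom <- te_lookup(tes, config$genome)
  gene_a <- assign_genes(config$n_transcripts, config$multi_tx_fraction, "g")
  a <- generate_transcripts(config, te_by_chrom, config$n_transcripts,
                            "t", gene_a)
  exons_a <- order_exons(cbind(a$exons, assembly = "nonref",
                               fpkm = NA_real_))

  tx_ids <- sprintf("t%05d", seq_len(config$n_transcripts))
  is_shared <- stats::rbinom(config$n_transcripts, 1L,
                             config$shared_fraction) == 1L
  shared_ids <- tx_ids[is_shared]
  sh <- exons_a[exons_a$transcript_id %in% shared_ids, , drop = FALSE]
  sh$exon_rank <- NULL
  j <- config$jitter_bp
  sh$start <- pmax(0L, sh$start + rint(nrow(sh), -j, j))
  sh$end <- sh$end + rint(nrow(sh), -j, j)
  sh$end <- pmax(sh$end, sh$start + 1L)
  b_ids <- paste0("b", sh$transcript_id)
  sh$transcript_id <- b_ids
  sh$gene_id <- paste0("b", sh$gene_id)
  sh$assembly <- "ref"

  n_novel <- as.integer(round(config$novel_fraction * config$n_transcripts))
  if (n_novel > 0L) {
    gene_n <- assign_genes(n_novel, config$multi_tx_fraction, "ng")
    nov <- generate_transcripts(config, te_by_chrom, n_novel, "nt", gene_n)
    nov_ex <- cbind(nov$exons, assembly = "ref", fpkm = NA_real_)
    exons_b <- order_exons(rbind(sh, nov_ex[, names(sh)]))
  } else {
    exons_b <- order_exons(sh)
  }

  list(
    exons_a = exons_a,
    exons_b = exons_b,
    exon_truth = a$truth,
    shared = data.frame(id_a = shared_ids,
                        id_b = paste0("b", shared_ids),
                        stringsAsFactors = FALSE)
  )
}

#' Simulate two-condition expression with planted DE genes
#'
#' Per-gene baseline FPKM is lognormal; a `de_fraction` of genes is shifted
#' by `de_log2fc` log2 units (random sign) in group B; replicates add
#' lognormal noise of sd `rep_sdlog`. A gene's FPKM is split across its
#' transcripts with fixed random weights.
#'
#' @param config a [synthetic_config()].
#' @param exons exon table of assembly A (provides the transcript-to-gene
#'   map).
#' @return list with `fpkm` (long table `transcript_id, sample, fpkm`;
#'   samples `A1..Ak, B1..Bk`) and `de_truth`
#'   (`gene_id, de, log2fc`).
#' @export
simulate_expression <- function(config, exons) {
  tx <- unique(exons[, c("transcript_id", "gene_id")])
  tx <- tx[order(tx$transcript_id), , drop = FALSE]
  genes <- sort(unique(tx$gene_id))
  ng <- length(genes)
  base <- stats::rlnorm(ng, config$fpkm_meanlog, config$fpkm_sdlog)
  de <- stats::rbinom(ng, 1L, config$de_fraction) == 1L
  lfc <- ifelse(de, config$de_log2fc * sample(c(-1, 1), ng, replace = TRUE),
                0)
  ns <- config$n_samples_per_group
  samples <- c(paste0("A", seq_len(ns)), paste0("B", seq_len(ns)))
  is_b <- rep(c(FALSE, TRUE), each = ns)

  w <- stats::runif(nrow(tx))
  w <- w / stats::ave(w, tx$gene_id, FUN = sum)
  gidx <- match(tx$gene_id, genes)

  rows <- lapply(seq_along(samples), function(s) {
    gene_fpkm <- base * 2^(lfc * is_b[s]) *
      exp(stats::rnorm(ng, 0, config$rep_sdlog))
    data.frame(transcript_id = tx$transcript_id, sample = samples[s],
               fpkm = gene_fpkm[gidx] * w, stringsAsFactors = FALSE)
  })
  list(
    fpkm = do.call(rbind, rows),
    de_truth = data.frame(gene_id = genes, de = de, log2fc = lfc,
                          stringsAsFactors = FALSE)
  )
}

#' Simulate epigenetic signal tracks over exons
#'
#' For each exon and track, the expected peak count is
#' `max(0, a + b * log(FPKM + 1) + N(0, noise))`, realized as `round()`
#' peaks of `peak_width` bp placed uniformly inside the exon. `b = 0`
#' yields a null track with no expression relation.
#'
#' @param config a [synthetic_config()].
#' @param exons exon table.
#' @param fpkm numeric vector of per-exon expression aligned to `exons`
#'   rows.
#' @return named list of signal feature tables (one per track, in
#'   [read_bed_features()] shape).
#' @export
simulate_signal_tracks <- function(config, exons, fpkm) {
  stopifnot(length(fpkm) == nrow(exons))
  lapply_named <- function(x, f) stats::setNames(lapply(names(x), f),
                                                 names(x))
  lapply_named(config$tracks, function(tr) {
    pars <- config$tracks[[tr]]
    lambda <- pars[["a"]] + pars[["b"]] * log(fpkm + 1) +
      stats::rnorm(nrow(exons), 0, pars[["noise"]])
    k <- pmax(0L, as.integer(round(lambda)))
    idx <- rep.int(seq_len(nrow(exons)), k)
    if (length(idx) == 0L) {
      return(data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), strand = character(0),
                        name = character(0), score = numeric(0),
                        track = character(0), stringsAsFactors = FALSE))
    }
    w <- pmin(config$peak_width, exons$end[idx] - exons$start[idx])
    smax <- exons$end[idx] - w
    s <- exons$start[idx] +
      floor(stats::runif(length(idx)) * (smax - exons$start[idx] + 1L))
    out <- data.frame(chrom = exons$chrom[idx], start = as.integer(s),
                      end = as.integer(s + w), strand = ".",
                      name = paste0(tr, "_p", seq_along(idx)),
                      score = rint(length(idx), 100L, 1000L),
                      track = tr, stringsAsFactors = FALSE)
    out[order(out$chrom, out$start, out$end), , drop = FALSE]
  })
}

#' Generate and write a complete synthetic bundle
#'
#' Seeds the RNG once from `config$seed` and emits, under `dir`:
#' `te.bed` (rmsk-bed dialect), `assembly_a.gtf`, `assembly_b.gtf`,
#' `fpkm.tsv`, `signals/<track>.bed`, and ground-truth sidecars
#' `truth/exon_labels.tsv`, `truth/de_genes.tsv`, `truth/shared.tsv`.
#' Identical config and seed produce a byte-identical bundle, and every
#' emitted file re-parses through the annotation readers with no records
#' lost.
#'
#' @param config a [synthetic_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the in-memory objects (`tes, exons_a,
#'   exons_b, exon_truth, shared, fpkm, de_truth, signals`) and the file
#'   `paths`.
#' @export
simulate_bundle <- function(config, dir) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  dir.create(file.path(dir, "signals"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), recursive = TRUE,
             showWarnings = FALSE)

  tes <- simulate_te_landscape(config)
  txo <- simulate_transcriptome(config, tes)
  expr <- simulate_expression(config, txo$exons_a)
  # exon expression = group-A mean FPKM of its transcript
  a_samples <- paste0("A", seq_len(config$n_samples_per_group))
  fa <- expr$fpkm[expr$fpkm$sample %in% a_samples, , drop = FALSE]
  tx_mean <- tapply(fa$fpkm, fa$transcript_id, mean)
  exon_fpkm <- as.numeric(tx_mean[txo$exons_a$transcript_id])
  signals <- simulate_signal_tracks(config, txo$exons_a, exon_fpkm)

  paths <- list(
    te = file.path(dir, "te.bed"),
    gtf_a = file.path(dir, "assembly_a.gtf"),
    gtf_b = file.path(dir, "assembly_b.gtf"),
    fpkm = file.path(dir, "fpkm.tsv"),
    signals = stats::setNames(
      file.path(dir, "signals", paste0(names(signals), ".bed")),
      names(signals)),
    exon_labels = file.path(dir, "truth", "exon_labels.tsv"),
    de_genes = file.path(dir, "truth", "de_genes.tsv"),
    shared = file.path(dir, "truth", "shared.tsv")
  )

  te_bed <- data.frame(tes$chrom, tes$start, tes$end, tes$name,
                       tes$millidiv, tes$strand, tes$raw_class)
  utils::write.table(te_bed, paths$te, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_gtf(txo$exons_a, paths$gtf_a)
  write_gtf(txo$exons_b, paths$gtf_b)
  write_table(expr$fpkm, paths$fpkm)
  for (tr in names(signals)) {
    s <- signals[[tr]]
    utils::write.table(
      data.frame(s$chrom, s$start, s$end, s$name, s$score, s$strand),
      paths$signals[[tr]], sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  }
  write_table(txo$exon_truth, paths$exon_labels)
  write_table(expr$de_truth, paths$de_genes)
  write_table(txo$shared, paths$shared)

  invisible(c(list(tes = tes), txo, expr, list(signals = signals,
                                               paths = paths,
                                               config = config)))
}
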