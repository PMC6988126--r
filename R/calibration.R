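# ---- spike-in calibration of count tables ---------------------------------

#' Spike-in subsampling / size factors
#'
#' Raw factors are inversely proportional to each sample's spike-in read
#' total, corrected by the spike/target ratio measured in the matched gDNA
#' sample (which absorbs minor cell-mixing variation), then rescaled so the
#' largest factor is 1 (subsampling semantics): `f_i = g_i / S_i`,
#' `f_i <- f_i / max(f_i)`. gDNA ratios are normalized to their
#' cross-sample mean before use, so factor ratios depend only on relative
#' mixing accuracy.
#'
#' @param samples tibble with `sample`, `spike_total` and `gdna_ratio`
#'   columns (see [simulate_spikein_counts()]).
#' @return The samples tibble with a `factor` column.
#' @export
spikein_factors <- function(samples) {
  samples <- tibble::as_tibble(samples)
  stopifnot(all(samples$spike_total > 0), all(samples$gdna_ratio > 0))
  g <- samples$gdna_ratio / mean(samples$gdna_ratio)
  f <- g / samples$spike_total
  samples$factor <- f / max(f)
  samples
}

#' Apply normalization factors to a count table
#'
#' @param counts long tibble (`gene`, `sample`, `count`).
#' @param factors tibble with `sample` and `factor` (e.g. from
#'   [spikein_factors()]).
#' @return The counts tibble with a `norm_count` column.
#' @export
apply_factors <- function(counts, factors) {
  counts <- tibble::as_tibble(counts)
  f <- factors$factor[match(counts$sample, factors$sample)]
  if (anyNA(f)) stop("missing factor for some samples", call. = FALSE)
  counts$norm_count <- counts$count * f
  counts
}

#' Binomially thin counts to the spike-in factors
#'
#' A stochastic alternative to deterministic scaling with identical
#' expectation (random subsampling in the strict sense).
#'
#' @inheritParams apply_factors
#' @param seed integer seed.
#' @return The counts tibble with a `norm_count` column of thinned counts.
#' @export
thin_counts <- function(counts, factors, seed = 1L) {
  counts <- tibble::as_tibble(counts)
  f <- factors$factor[match(counts$sample, factors$sample)]
  stopifnot(all(f > 0 & f <= 1))
  with_seed(seed, {
    counts$norm_count <- stats::rbinom(nrow(counts), counts$count, f)
  })
  counts
}

#' log2 RPKM expression matrix
#'
#' RPKM from normalized counts and gene lengths, log2-transformed after a
#' pseudocount of 0.01. Replicates of a condition are pooled by summing
#' normalized counts before RPKM when `pool_by` is given.
#'
#' @param counts tibble with `gene`, `sample`, `norm_count` (see
#'   [apply_factors()]).
#' @param gene_lengths tibble with `gene` and `length_bp`.
#' @param pseudocount added to RPKM before log2.
#' @param pool_by optional column name (e.g. `"condition"`) to pool
#'   replicates by summation before RPKM.
#' @return A tibble `gene` x unit with `rpkm` and `log2_rpkm`.
#' @export
normalized_expression <- function(counts, gene_lengths, pseudocount = 0.01,
                                  pool_by = NULL) {
  counts <- tibble::as_tibble(counts)
  unit <- if (is.null(pool_by)) "sample" else pool_by
  pooled <- counts |>
    dplyr::group_by(.data$gene, dplyr::across(dplyr::all_of(unit))) |>
    dplyr::summarise(norm_count = sum(.data$norm_count), .groups = "drop")
  pooled$length_bp <- gene_lengths$length_bp[match(pooled$gene, gene_lengths$gene)]
  if (anyNA(pooled$length_bp)) stop("missing gene length", call. = FALSE)
  pooled |>
    dplyr::group_by(dplyr::across(dplyr::all_of(unit))) |>
    dplyr::mutate(
      rpkm = .data$norm_count / (.data$length_bp / 1e3) /
        (sum(.data$norm_count) / 1e6),
      log2_rpkm = log2(.data$rpkm + pseudocount)
    ) |>
    dplyr::ungroup()
}

#' ChIP read quantitation in a peak set
#'
#' Counts reads per peak in union-overlap mode (reads overlapping more than
#' one peak are discarded), adds a pseudocount of 8, and log10-transforms.
#'
#' @param reads tibble with `chrom`, `start`, `end` (0-based half-open) and
#'   a `sample` column.
#' @param peaks interval tibble with `chrom`, `start`, `end`.
#' @param pseudocount added before log10.
#' @return A tibble `peak` x `sample` with `count` and `log10_count`.
#' @export
chip_quantitation <- function(reads, peaks, pseudocount = 8) {
  reads <- tibble::as_tibble(reads)
  peaks <- tibble::as_tibble(peaks)
  if (!"sample" %in% names(reads)) reads$sample <- "pooled"
  peak_id <- seq_len(nrow(peaks))
  hits <- purrr::map(seq_len(nrow(reads)), function(k) {
    which(peaks$chrom == reads$chrom[k] & peaks$start < reads$end[k] &
          peaks$end > reads$start[k])
  })
  n_hits <- lengths(hits)
  keep <- n_hits == 1L                       # union mode
  assigned <- unlist(hits[keep])
  tab <- tibble::tibble(peak = assigned, sample = reads$sample[keep]) |>
    dplyr::count(.data$peak, .data$sample, name = "count")
  tidyr::expand_grid(peak = peak_id, sample = unique(reads$sample)) |>
    dplyr::left_join(tab, by = c("peak", "sample")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L),
                  log10_count = log10(.data$count + pseudocount))
}

#' Differential expression thresholding contract
#'
#' Applies a pluggable two-condition test per gene on normalized counts and
#' flags genes `up`/`down`/`ns` by the thresholds `padj < padj_max` and
#' `fold change > min_fold`. The default test is a Welch t-test on log2
#' normalized counts with Benjamini-Hochberg correction -- a deliberately
#' simple stand-in; any per-gene test with the same signature can be
#' plugged in.
#'
#' @param counts tibble with `gene`, `sample`, `condition`, `norm_count`
#'   (two conditions).
#' @param test function `(x, y) -> p-value` comparing the two conditions'
#'   log2 normalized counts for one gene; default Welch t-test.
#' @param padj_max adjusted p-value threshold (strict `<`).
#' @param min_fold fold-change threshold (strict `>`).
#' @param ref reference (control) condition; log2FC is other vs `ref`.
#' @return A tibble per gene with `log2fc`, `p`, `padj`, `flag`.
#' @export
de_contract <- function(counts, test = NULL, padj_max = 0.05,
                        min_fold = 1.5, ref = "control") {
  counts <- tibble::as_tibble(counts)
  conds <- unique(counts$condition)
  stopifnot(length(conds) == 2, ref %in% conds)
  other <- setdiff(conds, ref)
  if (is.null(test)) {
    test <- function(x, y) {
      if (stats::sd(c(x, y)) == 0) return(1)
      tryCatch(stats::t.test(y, x)$p.value, error = function(e) 1)
    }
  }
  wide <- counts |>
    dplyr::mutate(l2 = log2(.data$norm_count + 0.5)) |>
    dplyr::group_by(.data$gene)
  res <- wide |>
    dplyr::summarise(
      log2fc = log2((mean(.data$norm_count[.data$condition == other]) + 0.5) /
                    (mean(.data$norm_count[.data$condition == ref]) + 0.5)),
      p = test(.data$l2[.data$condition == ref],
               .data$l2[.data$condition == other]),
      .groups = "drop"
    )
  res$padj <- stats::p.adjust(res$p, "BH")
  res$flag <- dplyr::case_when(
    res$padj < padj_max & res$log2fc > log2(min_fold) ~ "up",
    res$padj < padj_max & res$log2fc < -log2(min_fold) ~ "down",
    TRUE ~ "ns"
  )
  res
}

#' Promoter binding enrichment among flagged genes
#'
#' Observed fraction of flagged genes with a binding peak within
#' `tss_flank` of the TSS, and an empirical p-value from `n_random`
#' same-size random gene draws (fraction of draws reaching at least the
#' observed fraction).
#'
#' @param flagged_genes character vector of gene ids.
#' @param genes tibble with `gene`, `chrom`, `tss`.
#' @param peaks tibble with `chrom`, `start`, `end`.
#' @param tss_flank window around the TSS in bp.
#' @param n_random number of random draws.
#' @param seed integer seed.
#' @return A list with `fraction`, `p_empirical`, `n_flagged`, `n_bound`.
#' @export
promoter_overlap_enrichment <- function(flagged_genes, genes, peaks,
                                        tss_flank = 1000, n_random = 10000,
                                        seed = 1L) {
  genes <- tibble::as_tibble(genes)
  bound <- vapply(seq_len(nrow(genes)), function(k) {
    any(peaks$chrom == genes$chrom[k] &
        peaks$start < genes$tss[k] + tss_flank &
        peaks$end > genes$tss[k] - tss_flank)
  }, logical(1))
  names(bound) <- genes$gene
  sel <- flagged_genes[flagged_genes %in% genes$gene]
  n_flagged <- length(sel)
  if (n_flagged == 0) stop("no flagged genes found in the gene table", call. = FALSE)
  obs <- mean(bound[sel])
  with_seed(seed, {
    rnd <- vapply(seq_len(n_random), function(k) {
      mean(bound[sample.int(nrow(genes), n_flagged)])
    }, numeric(1))
  })
  list(fraction = obs, p_empirical = mean(rnd >= obs),
       n_flagged = n_flagged, n_bound = sum(bound[sel]))
}
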