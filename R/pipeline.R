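# ---- end-to-end pipeline driver ------------------------------------------

#' Pipeline configuration
#'
#' Collects every threshold of the analysis with its reference default:
#' 10 kb analysis / 100 kb calling / 500 kb compartment resolutions, bin
#' mask fraction 0.10, MAPQ 30, 5 kb site distance, donut fold 2.25, donut
#' FDR 0.05, other FDR 0.1, minimum 29 observed contacts, interaction
#' score 5, 10-fragment peak merge, 250 kb minimum separation, 500 kb APA
#' window with 100 shifts, five distance quantiles, p-adj 0.05 with
#' 1.5-fold change, FISH threshold `mean + 3 SD`. The seed is mandatory:
#' there is no implicit global randomness.
#'
#' @param seed integer seed driving every random stage.
#' @param chrom_length synthetic chromosome length (bp).
#' @param depth expected total contact count per condition.
#' @param ... overrides for any default listed above (see
#'   `formals(pipeline_config)`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed,
                            chrom_length = 2e7,
                            depth = 2e6,
                            bin_size_analysis = 10000,
                            bin_size_calling = 100000,
                            bin_size_compartments = 500000,
                            mask_frac = 0.10,
                            min_mapq = 30,
                            max_site_dist = 5000,
                            donut_fold = 2.25,
                            donut_fdr = 0.05,
                            other_fdr = 0.1,
                            min_obs = 29,
                            score_min = 5,
                            merge_frags = 10,
                            min_sep = 250000,
                            apa_window = 500000,
                            n_shifts = 100,
                            n_quantiles = 5,
                            padj_max = 0.05,
                            min_fold = 1.5,
                            fish_k = 3,
                            ...) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  cfg <- as.list(environment())
  extra <- list(...)
  cfg[names(extra)] <- extra
  structure(cfg, class = "pipeline_config")
}

#' Expand a binned matrix back into a pairs table
#'
#' Emits one valid-pair record per contact (upper triangle; same-bin
#' contacts once), with 5' positions drawn uniformly within each bin,
#' fragments assigned from the restriction map, random strands and MAPQ
#' 60. Deterministic given the seed.
#'
#' @param m a raw [contact_matrix()].
#' @param rmap restriction map covering `m$chrom`.
#' @param seed integer seed.
#' @return A pairs tibble (see [read_pairs()] for the dialect).
#' @export
matrix_to_pairs <- function(m, rmap, seed = 1L) {
  px <- tidy.contact_matrix(m, upper_only = TRUE, drop_zero = TRUE)
  bs <- m$bin_size
  rm_c <- dplyr::filter(rmap, .data$chrom == m$chrom)
  with_seed(seed, {
    n <- sum(px$count)
    b1 <- rep(px$bin1, px$count); b2 <- rep(px$bin2, px$count)
    pos1 <- (b1 - 1) * bs + sample.int(bs, n, replace = TRUE)
    pos2 <- (b2 - 1) * bs + sample.int(bs, n, replace = TRUE)
    swap <- pos1 > pos2
    tmp <- pos1[swap]; pos1[swap] <- pos2[swap]; pos2[swap] <- tmp
    frag_of <- function(pos) rm_c$frag[findInterval(pos - 1, rm_c$start)]
    tibble::tibble(
      chrom1 = m$chrom, pos1 = pos1,
      strand1 = sample(c("+", "-"), n, replace = TRUE), frag1 = frag_of(pos1),
      chrom2 = m$chrom, pos2 = pos2,
      strand2 = sample(c("+", "-"), n, replace = TRUE), frag2 = frag_of(pos2),
      mapq1 = 60, mapq2 = 60)
  })
}

# planted structures for the two conditions: the depleted condition loses
# the TAD boost and gains stronger distal loops
pipeline_truths <- function(cfg) {
  n10 <- as.integer(ceiling(cfg$chrom_length / cfg$bin_size_analysis))
  # aperiodic compartment blocks (0.5 - 2.5 Mb), alternating sign: a strictly
  # periodic pattern would make the correlation matrix near-circulant and its
  # leading eigenpair degenerate
  cb <- as.integer(cfg$bin_size_compartments / cfg$bin_size_analysis)
  comp <- with_seed(cfg$seed, {
    lens <- sample(1:5, ceiling(n10 / cb) + 1, replace = TRUE) * cb
    rep(rep(c(1, -1), length.out = length(lens)), times = lens)[1:n10]
  })
  tad_len <- as.integer(8e5 / cfg$bin_size_analysis)   # 800 kb TADs
  tad_starts <- seq(2L * tad_len, n10 - 3L * tad_len, by = 3L * tad_len)
  tads <- tibble::tibble(start_bin = tad_starts, end_bin = tad_starts + tad_len - 1L)
  cal_f <- as.integer(cfg$bin_size_calling / cfg$bin_size_analysis)
  # loop anchors on the 100 kb grid so calling-resolution pixels line up
  anchor_sep <- c(6, 8, 11, 14, 18, 24) * cal_f         # 0.6 - 2.4 Mb
  a1 <- as.integer(seq(10 * cal_f, n10 - 30 * cal_f, length.out = length(anchor_sep)))
  a1 <- (a1 %/% cal_f) * cal_f + cal_f %/% 2L
  loops <- tibble::tibble(bin1 = a1, bin2 = a1 + anchor_sep)
  distal <- loops$bin2 - loops$bin1 > 10L * cal_f       # > 1 Mb
  ctrl <- planted_structure(
    n10, compartment_vector = comp, comp_strength = 0.3,
    tad_intervals = tads, tad_boost = 2,
    loop_anchors = dplyr::mutate(loops, fold = ifelse(distal, 4, 6)),
    loop_width = cal_f - 1L, decay_exponent = -1, depth = cfg$depth)
  depl <- planted_structure(
    n10, compartment_vector = comp, comp_strength = 0.3,
    tad_intervals = tads[0, ], tad_boost = 1,
    loop_anchors = dplyr::mutate(loops, fold = ifelse(distal, 10, 6)),
    loop_width = cal_f - 1L, decay_exponent = -1, depth = cfg$depth)
  list(control = ctrl, depleted = depl, loops = loops, distal = distal)
}

#' Run the end-to-end synthetic analysis
#'
#' Simulates a control and a depleted condition (the depleted condition
#' loses its TAD blocks and strengthens distal loops), then runs the full
#' chain: pairs expansion, valid-pair filtering, binning, bin masking, KR
#' balancing, O/E transform, compartment quantification at coarse
#' resolution, loop calling on the depleted matrix at calling resolution,
#' APA on both conditions over distance quantiles. Deterministic under
#' `config$seed`; any stage failure aborts with a stage-tagged message.
#'
#' @param config a [pipeline_config()].
#' @param report_path optional path; when given the report is also written
#'   as JSON.
#' @return A named list report (JSON-serializable) with per-stage filter
#'   counts, compartment strengths and sign agreement, loop-call summary,
#'   and per-quantile APA center scores for both conditions.
#' @export
run_pipeline <- function(config, report_path = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  cfg <- config
  truths <- pipeline_truths(cfg)
  report <- list(seed = cfg$seed)
  conds <- c("control", "depleted")
  mats10 <- list(); oes <- list(); raw100 <- list()
  for (ci in seq_along(conds)) {
    cond <- conds[ci]
    sim <- stage("simulate", {
      spec <- synthetic_genome_spec(cfg$chrom_length, cfg$bin_size_analysis,
                                    chrom = "chrS", seed = cfg$seed + ci)
      simulate_contact_matrix(spec, truths[[cond]])
    })
    rmap <- stage("restriction_map", {
      simulate_restriction_map(c(chrS = cfg$chrom_length), 400, seed = cfg$seed)
    })
    flt <- stage("filter", {
      pr <- matrix_to_pairs(sim$matrix, rmap, seed = cfg$seed + 10L + ci)
      filter_pairs(pr, rmap, min_mapq = cfg$min_mapq,
                   max_site_dist = cfg$max_site_dist)
    })
    m10 <- stage("bin", {
      bin_pairs(flt$pairs, c(chrS = cfg$chrom_length),
                bin_size = cfg$bin_size_analysis)$cis$chrS
    })
    m10 <- stage("mask", mask_bins(m10, rmap, frac = cfg$mask_frac))
    bal <- stage("balance", suppressWarnings(balance_kr(m10)))
    oes[[cond]] <- stage("oe", oe_transform(bal))
    mats10[[cond]] <- m10
    raw100[[cond]] <- stage("rebin", {
      mask_bins(rebin(m10, cfg$bin_size_calling), rmap, frac = cfg$mask_frac)
    })
    report[[paste0("filter_", cond)]] <- stats::setNames(
      as.list(flt$report$removed), flt$report$stage)
    report[[paste0("n_valid_pairs_", cond)]] <- attr(flt$report, "n_out")
  }
  comp <- stage("compartments", {
    lapply(conds, function(cond) {
      m500 <- mask_bins(rebin(mats10[[cond]], cfg$bin_size_compartments),
                        on = "coverage")
      oe500 <- oe_transform(suppressWarnings(balance_kr(m500)))
      f <- as.integer(cfg$bin_size_compartments / cfg$bin_size_analysis)
      gc10 <- truths[[cond]]$gc_track %||% rep(0.41, truths[[cond]]$n_bins)
      gc500 <- as.numeric(tapply(gc10, ((seq_along(gc10) - 1) %/% f), mean))
      cv <- compartment_vector(oe500, gc500[seq_len(n_bins(oe500))])
      truth_sign <- sign(as.numeric(
        tapply(truths[[cond]]$compartment_vector,
               ((seq_len(truths[[cond]]$n_bins) - 1) %/% f), mean)))
      okb <- !is.na(cv$eigenvector)
      list(strength = compartmentalization_strength(oe500),
           sign_agreement = max(mean(sign(cv$eigenvector[okb]) == truth_sign[okb]),
                                mean(sign(cv$eigenvector[okb]) == -truth_sign[okb])))
    }) |> stats::setNames(conds)
  })
  report$compartment_strength <- lapply(comp, `[[`, "strength")
  report$compartment_sign_agreement <- lapply(comp, `[[`, "sign_agreement")
  calls <- stage("call_peaks", {
    call_peaks(raw100$depleted, donut_fold = cfg$donut_fold,
               donut_fdr = cfg$donut_fdr, other_fdr = cfg$other_fdr,
               min_obs = cfg$min_obs)
  })
  cal_f <- as.integer(cfg$bin_size_calling / cfg$bin_size_analysis)
  truth100 <- tibble::tibble(bin1 = (truths$loops$bin1 - 1L) %/% cal_f + 1L,
                             bin2 = (truths$loops$bin2 - 1L) %/% cal_f + 1L)
  hit <- vapply(seq_len(nrow(truth100)), function(k) {
    any(abs(calls$bin1 - truth100$bin1[k]) <= 1 &
        abs(calls$bin2 - truth100$bin2[k]) <= 1)
  }, logical(1))
  report$loop_calls <- list(n_calls = nrow(calls),
                            n_truth = nrow(truth100),
                            recall = mean(hit))
  apa_res <- stage("apa", {
    pairs <- tibble::tibble(
      bin1 = truths$loops$bin1, bin2 = truths$loops$bin2,
      separation = (truths$loops$bin2 - truths$loops$bin1) * cfg$bin_size_analysis)
    pairs <- distance_quantiles(pairs, k = min(cfg$n_quantiles, nrow(pairs)))
    lapply(conds, function(cond) {
      vapply(sort(unique(pairs$quantile)), function(q) {
        apa(mats10[[cond]], dplyr::filter(pairs, .data$quantile == q),
            window = cfg$apa_window, n_shifts = cfg$n_shifts,
            min_sep = cfg$min_sep, seed = cfg$seed + 100L)$center_score
      }, numeric(1))
    }) |> stats::setNames(conds)
  })
  report$apa_center_scores <- apa_res
  nq <- length(apa_res$control)
  report$apa_distal_ratio <- apa_res$depleted[nq] / apa_res$control[nq]
  if (!is.null(report_path)) {
    jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  report
}
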