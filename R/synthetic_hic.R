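#' Specify a synthetic chromosome
#'
#' Defines the bin grid and GC track of one synthetic chromosome. The GC
#' track is the covariate used to orient the A/B compartment eigenvector
#' (gene-dense A compartment chromatin is GC-richer); when omitted it is
#' generated later from the planted compartment signal by
#' [simulate_contact_matrix()].
#'
#' @param length_bp chromosome length in bp (> 0).
#' @param bin_size bin width in bp.
#' @param chrom chromosome name.
#' @param gc_track optional per-bin GC fraction in `[0, 1]`, length
#'   `ceiling(length_bp / bin_size)`.
#' @param seed integer seed controlling all randomness downstream.
#' @return A `synthetic_genome_spec` list.
#' @export
synthetic_genome_spec <- function(length_bp, bin_size = 10000L, chrom = "chrS",
                                  gc_track = NULL, seed = 1L) {
  stopifnot(length_bp > 0, bin_size > 0)
  n_bins <- as.integer(ceiling(length_bp / bin_size))
  if (!is.null(gc_track)) {
    stopifnot(length(gc_track) == n_bins, all(gc_track >= 0 & gc_track <= 1))
  }
  structure(
    list(chrom = chrom, length_bp = as.numeric(length_bp),
         bin_size = as.integer(bin_size), n_bins = n_bins,
         gc_track = gc_track, seed = as.integer(seed)),
    class = "synthetic_genome_spec"
  )
}

#' Plant compartments, TADs and loops
#'
#' Ground truth for a simulated contact matrix. Expected counts for an
#' off-diagonal pixel `(i, j)` are
#' `C * |i-j|^decay * (1 + rho*e_i*e_j) * tad_boost(i,j) * loop_fold(i,j)`,
#' with `C` set so the total expected count equals `depth`.
#'
#' @param n_bins number of bins (must match the genome spec).
#' @param compartment_vector per-bin real in `[-1, 1]`; sign encodes A/B.
#'   Default 0 (no compartments).
#' @param comp_strength compartment coupling `rho` in `[0, 1)`.
#' @param tad_intervals tibble/data frame with columns `start_bin`,
#'   `end_bin` (1-based, inclusive), non-overlapping.
#' @param tad_boost constant multiplier for pixels with both bins inside
#'   the same TAD.
#' @param loop_anchors tibble with columns `bin1 < bin2` and `fold >= 1`.
#' @param loop_width odd number of bins over which each loop's fold
#'   applies, centered on the anchor pixel (1 = a single pixel; 5 at 10 kb
#'   emulates the ~50 kb footprint of a focal enrichment).
#' @param decay_exponent power-law distance-decay exponent (< 0).
#' @param depth expected total contact count (sum over pixels `i < j`).
#' @return A `planted_structure` list.
#' @export
planted_structure <- function(n_bins,
                              compartment_vector = rep(0, n_bins),
                              comp_strength = 0,
                              tad_intervals = NULL,
                              tad_boost = 2,
                              loop_anchors = NULL,
                              loop_width = 1L,
                              decay_exponent = -1,
                              depth = 1e6) {
  stopifnot(loop_width >= 1, loop_width %% 2 == 1)
  stopifnot(length(compartment_vector) == n_bins,
            all(abs(compartment_vector) <= 1),
            comp_strength >= 0, comp_strength < 1,
            decay_exponent < 0, depth > 0, tad_boost >= 1)
  if (is.null(tad_intervals)) {
    tad_intervals <- tibble::tibble(start_bin = integer(), end_bin = integer())
  }
  tad_intervals <- tibble::as_tibble(tad_intervals)
  if (nrow(tad_intervals) > 0) {
    stopifnot(all(tad_intervals$start_bin >= 1),
              all(tad_intervals$end_bin <= n_bins),
              all(tad_intervals$start_bin <= tad_intervals$end_bin))
    o <- order(tad_intervals$start_bin)
    ti <- tad_intervals[o, ]
    if (nrow(ti) > 1 && any(ti$start_bin[-1] <= ti$end_bin[-nrow(ti)])) {
      stop("TAD intervals must be non-overlapping", call. = FALSE)
    }
  }
  if (is.null(loop_anchors)) {
    loop_anchors <- tibble::tibble(bin1 = integer(), bin2 = integer(), fold = numeric())
  }
  loop_anchors <- tibble::as_tibble(loop_anchors)
  if (nrow(loop_anchors) > 0) {
    stopifnot(all(loop_anchors$bin1 < loop_anchors$bin2),
              all(loop_anchors$bin1 >= 1), all(loop_anchors$bin2 <= n_bins))
    if (any(loop_anchors$fold < 1)) {
      stop("loop folds must be >= 1", call. = FALSE)
    }
  }
  structure(
    list(n_bins = as.integer(n_bins),
         compartment_vector = as.numeric(compartment_vector),
         comp_strength = comp_strength,
         tad_intervals = tad_intervals, tad_boost = tad_boost,
         loop_anchors = loop_anchors, loop_width = as.integer(loop_width),
         decay_exponent = decay_exponent, depth = depth),
    class = "planted_structure"
  )
}

# per-bin TAD id (0 = outside any TAD)
tad_membership <- function(truth) {
  id <- integer(truth$n_bins)
  ti <- truth$tad_intervals
  if (nrow(ti) > 0) {
    for (k in seq_len(nrow(ti))) id[ti$start_bin[k]:ti$end_bin[k]] <- k
  }
  id
}

# expected-count matrix lambda (diagonal NA; off-diagonal > 0)
expected_lambda <- function(spec, truth) {
  n <- truth$n_bins
  d <- abs(outer(seq_len(n), seq_len(n), `-`))
  lam <- ifelse(d == 0, NA_real_, d^truth$decay_exponent)
  if (truth$comp_strength > 0) {
    e <- truth$compartment_vector
    lam <- lam * (1 + truth$comp_strength * outer(e, e))
  }
  tid <- tad_membership(truth)
  if (any(tid > 0)) {
    same <- outer(tid, tid, `==`) & outer(tid > 0, tid > 0, `&`)
    lam[same] <- lam[same] * truth$tad_boost
  }
  la <- truth$loop_anchors
  if (nrow(la) > 0) {
    h <- ((truth$loop_width %||% 1L) - 1L) %/% 2L
    for (k in seq_len(nrow(la))) {
      ii <- max(1, la$bin1[k] - h):min(n, la$bin1[k] + h)
      jj <- max(1, la$bin2[k] - h):min(n, la$bin2[k] + h)
      lam[ii, jj] <- lam[ii, jj] * la$fold[k]
      lam[jj, ii] <- lam[jj, ii] * la$fold[k]
    }
  }
  tot <- sum(lam[upper.tri(lam)], na.rm = TRUE)
  lam * (truth$depth / tot)
}

#' Simulate a contact matrix with planted structure
#'
#' Draws Poisson counts around a power-law distance decay modulated by the
#' planted compartments, TAD blocks and focal loops, then symmetrizes.
#' Diagonal pixels are excluded (zero); the generator is a pure function of
#' `(spec, truth, spec$seed)`.
#'
#' @param spec a [synthetic_genome_spec()].
#' @param truth a [planted_structure()] on the same bin grid.
#' @return A list with elements `matrix` (a [contact_matrix()]), `truth`
#'   (the planted structure, with the realized GC track attached as
#'   `gc_track`), and `lambda_total` (the planted total expected count).
#' @export
simulate_contact_matrix <- function(spec, truth) {
  stopifnot(inherits(spec, "synthetic_genome_spec"),
            inherits(truth, "planted_structure"))
  if (spec$n_bins != truth$n_bins) {
    stop("bin grid mismatch between genome spec and planted structure", call. = FALSE)
  }
  if (spec$n_bins < 2) stop("empty or single-bin genome", call. = FALSE)
  lam <- expected_lambda(spec, truth)
  n <- spec$n_bins
  with_seed(spec$seed, {
    up <- which(upper.tri(lam))
    counts <- matrix(0, n, n)
    counts[up] <- stats::rpois(length(up), lam[up])
    counts <- counts + t(counts)
    gc <- spec$gc_track
    if (is.null(gc)) {
      # monotone in compartment sign plus noise so orientation is decidable
      gc <- 0.41 + 0.03 * truth$compartment_vector + stats::rnorm(n, 0, 0.005)
      gc <- pmin(pmax(gc, 0), 1)
    }
    truth$gc_track <- gc
    list(
      matrix = contact_matrix(counts, chrom = spec$chrom, bin_size = spec$bin_size),
      truth = truth,
      lambda_total = truth$depth
    )
  })
}

#' Simulate a Capture-C viewpoint profile
#'
#' Per-restriction-fragment counts decaying with fragment distance from the
#' viewpoint, with planted distal peaks of known fold enrichment.
#'
#' @param viewpoint_frag viewpoint fragment index (1-based).
#' @param n_frags number of fragments.
#' @param planted_peaks tibble with columns `frag`, `fold` (`fold >= 1`).
#' @param depth expected total count.
#' @param decay_exponent power-law exponent over `1 + |frag - viewpoint|`.
#' @param seed integer seed.
#' @return A list with `profile` (tibble: `frag`, `count`, `expected`,
#'   `fold`) and `truth` (the planted peaks).
#' @export
simulate_capture_profile <- function(viewpoint_frag, n_frags,
                                     planted_peaks = NULL, depth = 1e5,
                                     decay_exponent = -1, seed = 1L) {
  stopifnot(n_frags >= 2, decay_exponent < 0, depth > 0)
  if (viewpoint_frag < 1 || viewpoint_frag > n_frags) {
    stop("viewpoint fragment outside range", call. = FALSE)
  }
  if (is.null(planted_peaks)) {
    planted_peaks <- tibble::tibble(frag = integer(), fold = numeric())
  }
  planted_peaks <- tibble::as_tibble(planted_peaks)
  if (nrow(planted_peaks) > 0) {
    stopifnot(all(planted_peaks$frag >= 1), all(planted_peaks$frag <= n_frags),
              all(planted_peaks$fold >= 1))
  }
  frag <- seq_len(n_frags)
  fold <- rep(1, n_frags)
  fold[planted_peaks$frag] <- planted_peaks$fold
  fold[viewpoint_frag] <- 0           # the viewpoint itself carries no signal
  base <- (1 + abs(frag - viewpoint_frag))^decay_exponent * fold
  lam <- base * depth / sum(base)
  with_seed(seed, {
    tibble::tibble(frag = frag, count = stats::rpois(n_frags, lam),
                   expected = lam, fold = fold)
  }) -> profile
  list(profile = profile, truth = planted_peaks, viewpoint = viewpoint_frag)
}

#' Specify a FISH distance simulation
#'
#' A two-component mixture of inter-probe 3D distances: a `contact`
#' component (folded normal around 0, scale `contact_scale_nm`) and a
#' `background` component (truncated normal), plus an independent
#' calibration distribution emulating two-color measurements of the same
#' probe (colocalization precision error).
#'
#' @param n_alleles number of allele pairs measured.
#' @param contact_fraction probability an allele pair is in contact.
#' @param contact_scale_nm scale (nm) of the folded-normal contact
#'   component.
#' @param background_mean_nm,background_sd_nm truncated-normal background.
#' @param calib_mean_nm,calib_sd_nm calibration distribution (defaults
#'   emulate a 73 +/- 38 nm two-color precision error).
#' @param n_calib number of calibration measurements.
#' @param seed integer seed.
#' @return A `fish_sim_spec` list.
#' @export
fish_sim_spec <- function(n_alleles = 400, contact_fraction = 0.056,
                          contact_scale_nm = 50,
                          background_mean_nm = 700, background_sd_nm = 150,
                          calib_mean_nm = 73, calib_sd_nm = 38,
                          n_calib = 200, seed = 1L) {
  stopifnot(contact_fraction >= 0, contact_fraction <= 1,
            contact_scale_nm > 0, background_mean_nm > 0, background_sd_nm > 0,
            calib_mean_nm > 0, calib_sd_nm >= 0, n_alleles >= 1)
  structure(
    list(n_alleles = as.integer(n_alleles), contact_fraction = contact_fraction,
         contact_scale_nm = contact_scale_nm,
         background_mean_nm = background_mean_nm,
         background_sd_nm = background_sd_nm,
         calib_mean_nm = calib_mean_nm, calib_sd_nm = calib_sd_nm,
         n_calib = as.integer(n_calib), seed = as.integer(seed)),
    class = "fish_sim_spec"
  )
}

#' Simulate FISH inter-probe distances
#'
#' @param spec a [fish_sim_spec()].
#' @return A list with `distances` (tibble: `allele`, `distance_nm`,
#'   `is_contact` truth label) and `calibration` (tibble: `distance_nm`).
#' @export
simulate_fish_distances <- function(spec) {
  stopifnot(inherits(spec, "fish_sim_spec"))
  with_seed(spec$seed, {
    contact <- stats::runif(spec$n_alleles) < spec$contact_fraction
    d <- numeric(spec$n_alleles)
    d[contact] <- abs(stats::rnorm(sum(contact), 0, spec$contact_scale_nm))
    d[!contact] <- rnorm_pos(sum(!contact), spec$background_mean_nm,
                             spec$background_sd_nm)
    calib <- rnorm_pos(spec$n_calib, spec$calib_mean_nm, spec$calib_sd_nm)
    list(
      distances = tibble::tibble(allele = seq_len(spec$n_alleles),
                                 distance_nm = d, is_contact = contact),
      calibration = tibble::tibble(distance_nm = calib)
    )
  })
}

#' Simulate spike-in calibrated count tables
#'
#' Two conditions sequenced to a fixed per-sample depth, where target-genome
#' and spike-in material compete for reads. A planted global depletion in
#' the treated condition therefore inflates the spike-in read share while
#' leaving the target read total roughly constant -- the situation spike-in
#' calibration exists to resolve.
#'
#' @param n_genes number of target genes.
#' @param true_log2fc per-gene log2 fold change (treated vs control);
#'   recycled if length 1.
#' @param mix_ratio spike-in material per sample relative to the control
#'   target total (named or unnamed vector, one per sample; recycled).
#' @param depth sequencing depth per sample (total reads).
#' @param n_reps replicates per condition.
#' @param gdna_noise_sd lognormal sd of measurement noise on the gDNA
#'   mixing ratio (0 = exact).
#' @param seed integer seed.
#' @return A list with `counts` (long tibble: `gene`, `sample`,
#'   `condition`, `count`), `samples` (tibble: `sample`, `condition`,
#'   `spike_total`, `gdna_ratio`, `depth`), `genes` (tibble: `gene`,
#'   `length_bp`, `true_log2fc`).
#' @export
simulate_spikein_counts <- function(n_genes = 2000, true_log2fc = 0,
                                    mix_ratio = 0.05, depth = 1e6,
                                    n_reps = 2, gdna_noise_sd = 0,
                                    seed = 1L) {
  stopifnot(n_genes >= 1, all(mix_ratio > 0), depth > 0, n_reps >= 1)
  true_log2fc <- rep_len(true_log2fc, n_genes)
  n_samples <- 2L * n_reps
  mix_ratio <- rep_len(mix_ratio, n_samples)
  condition <- rep(c("control", "treated"), each = n_reps)
  sample_id <- paste0(condition, "_", rep(seq_len(n_reps), 2))
  with_seed(seed, {
    base <- stats::rlnorm(n_genes, meanlog = 4, sdlog = 1)
    length_bp <- round(stats::rlnorm(n_genes, meanlog = 8, sdlog = 0.5)) + 200
    W0 <- sum(base)
    counts <- vector("list", n_samples)
    spike_total <- numeric(n_samples)
    gdna_ratio <- numeric(n_samples)
    for (s in seq_len(n_samples)) {
      w <- if (condition[s] == "treated") base * 2^true_log2fc else base
      sw <- mix_ratio[s] * W0
      tot <- sum(w) + sw
      counts[[s]] <- stats::rpois(n_genes, depth * w / tot)
      spike_total[s] <- stats::rpois(1, depth * sw / tot)
      g <- mix_ratio[s]
      if (gdna_noise_sd > 0) g <- g * stats::rlnorm(1, 0, gdna_noise_sd)
      gdna_ratio[s] <- g
    }
    list(
      counts = tibble::tibble(
        gene = rep(paste0("g", seq_len(n_genes)), times = n_samples),
        sample = rep(sample_id, each = n_genes),
        condition = rep(condition, each = n_genes),
        count = unlist(counts)
      ),
      samples = tibble::tibble(sample = sample_id, condition = condition,
                               spike_total = spike_total,
                               gdna_ratio = gdna_ratio, depth = depth),
      genes = tibble::tibble(gene = paste0("g", seq_len(n_genes)),
                             length_bp = as.numeric(length_bp),
                             true_log2fc = true_log2fc)
    )
  })
}
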