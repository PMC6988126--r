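test_that("APA is centered at 1 on structureless matrices and scale-free", {
  m <- sim_null_matrix(500, depth = 5e6, bin_size = 1e4, seed = 61)
  set.seed(62)
  pairs <- tibble::tibble(bin1 = sample(100:200, 25), bin2 = sample(300:400, 25))
  r <- apa(m, pairs, seed = 63)
  expect_lt(abs(r$center_score - 1), 0.1)
  # ratio statistic: doubling counts leaves the score unchanged
  m2 <- contact_matrix(m$counts * 2, chrom = m$chrom, bin_size = m$bin_size)
  r2 <- apa(m2, pairs, seed = 63)
  expect_equal(r2$center_score, r$center_score)
})

test_that("APA recovers the planted loop fold at pair anchors", {
  la <- tibble::tibble(bin1 = c(150L, 260L), bin2 = c(420L, 530L), fold = 3)
  tr <- planted_structure(600, loop_anchors = la, loop_width = 5, depth = 8e6)
  sim <- simulate_contact_matrix(synthetic_genome_spec(6e6, 1e4, seed = 64), tr)
  r <- apa(sim$matrix, la, seed = 65)
  expect_lt(abs(r$center_score - 3) / 3, 0.2)
})

test_that("every shifted control preserves pair separation and skips are counted", {
  m <- sim_null_matrix(400, depth = 1e6, bin_size = 1e4, seed = 66)
  pairs <- tibble::tibble(bin1 = c(100L, 150L, 5L), bin2 = c(200L, 260L, 395L))
  r <- apa(m, pairs, n_shifts = 30, seed = 67, record_controls = TRUE)
  expect_equal(r$controls$ctrl2 - r$controls$ctrl1,
               r$controls$bin2 - r$controls$bin1)
  # shifted windows never overlap the true window
  expect_true(all(abs(r$controls$ctrl1 - r$controls$bin1) > 50))
  expect_equal(r$n_skipped, 1L)   # third pair's window leaves the matrix
})

test_that("distance quantiles split by the stated remainder rule", {
  p10 <- tibble::tibble(separation = (1:10) * 1e5)
  q10 <- distance_quantiles(p10, k = 5)
  expect_equal(as.integer(table(q10$quantile)), rep(2L, 5))
  expect_equal(q10$separation, sort(p10$separation))
  p11 <- tibble::tibble(separation = (1:11) * 1e5)
  expect_equal(as.integer(table(distance_quantiles(p11, k = 5)$quantile)),
               c(3L, 2L, 2L, 2L, 2L))
  expect_equal(distance_quantiles(p10, k = 1)$separation, p10$separation)
})

test_that("aggregate TAD analysis rescales and recovers the planted boost", {
  # identical synthetic TADs: the aggregate equals a single-TAD extraction
  n <- 120
  oe_vals <- matrix(1, n, n)
  tads <- tibble::tibble(start_bin = c(21L, 81L), end_bin = c(40L, 100L))
  for (k in 1:2) {
    idx <- tads$start_bin[k]:tads$end_bin[k]
    oe_vals[idx, idx] <- 2
  }
  oe <- contact_matrix(oe_vals, bin_size = 1e4)
  agg <- aggregate_tads(oe, tads, out_size = 60)
  single <- aggregate_tads(oe, tads[1, ], out_size = 60)
  expect_equal(agg$aggregate, single$aggregate)
  body <- agg$body_idx
  flank <- setdiff(seq_len(60), body)
  expect_equal(mean(agg$aggregate[body, body]) /
                 mean(agg$aggregate[flank, flank]), 2)
  # order invariance
  agg_rev <- aggregate_tads(oe, tads[2:1, ], out_size = 60)
  expect_equal(agg_rev$aggregate, agg$aggregate)
  # nearest-neighbor resampling of a constant matrix is constant
  const <- aggregate_tads(contact_matrix(matrix(3, n, n), bin_size = 1e4),
                          tads, out_size = 45)
  expect_true(all(const$aggregate == 3))
})

test_that("planted TAD boost is visible in simulated aggregate TADs", {
  tads <- tibble::tibble(start_bin = c(61L, 181L, 301L),
                         end_bin = c(100L, 220L, 340L))
  tr <- planted_structure(400, tad_intervals = tads, tad_boost = 2, depth = 4e6)
  sim <- simulate_contact_matrix(synthetic_genome_spec(4e6, 1e4, seed = 68), tr)
  oe <- oe_transform(sim$matrix)
  agg <- aggregate_tads(oe, tads, out_size = 60)
  body <- agg$body_idx
  flank_rows <- 1:15
  ratio <- mean(agg$aggregate[body, body], na.rm = TRUE) /
    mean(agg$aggregate[flank_rows, flank_rows], na.rm = TRUE)
  expect_gt(ratio, 1.5)
  expect_lt(abs(ratio - 2) / 2, 0.25)
})

test_that("matched random pairs preserve chromosome and separation", {
  pairs <- tibble::tibble(chrom = c("chr1", "chr2"),
                          start1 = c(1e6, 2e6), end1 = c(1.01e6, 2.01e6),
                          start2 = c(3e6, 5e6), end2 = c(3.01e6, 5.01e6))
  set.seed(70)
  universe <- tibble::tibble(
    chrom = rep(c("chr1", "chr2"), each = 400),
    start = round(c(runif(400, 0, 8e6), runif(400, 0, 8e6)) / 1e4) * 1e4)
  universe$end <- universe$start + 1e4
  rnd <- matched_random_pairs(pairs, universe, n = 200, bin_size = 1e4, seed = 71)
  expect_true(all(rnd$chrom[rnd$pair_id == 1] == "chr1"))
  expect_true(all(rnd$chrom[rnd$pair_id == 2] == "chr2"))
  sep_obs <- abs((pairs$start2 + pairs$end2) - (pairs$start1 + pairs$end1)) / 2
  sep_rnd <- abs((rnd$start2 + rnd$end2) - (rnd$start1 + rnd$end1)) / 2
  expect_true(all(abs(sep_rnd - sep_obs[rnd$pair_id]) <= 1e4))
  rnd2 <- matched_random_pairs(pairs, universe, n = 200, bin_size = 1e4, seed = 71)
  expect_identical(rnd, rnd2)
})

test_that("signal fold enrichment is 1 for uniform tracks and tracks planted doubling", {
  pairs <- tibble::tibble(chrom = "chr1", start1 = 1e6, end1 = 1.01e6,
                          start2 = 4e6, end2 = 4.01e6)
  universe <- tibble::tibble(chrom = "chr1", start = 0:799 * 1e4,
                             end = 1:800 * 1e4)
  rnd <- matched_random_pairs(pairs, universe, n = 300, bin_size = 1e4, seed = 72)
  flat <- tibble::tibble(chrom = "chr1", start = 0:799 * 1e4, end = 1:800 * 1e4,
                         value = 5)
  r1 <- signal_fold_enrichment(flat, pairs, rnd)
  expect_equal(r1$fold, 1)
  boosted <- flat
  boosted$value[boosted$start %in% c(1e6, 4e6)] <- 10
  r2 <- signal_fold_enrichment(boosted, pairs, rnd)
  expect_lt(abs(r2$fold - 2), 0.1)
  # invariant to global track scaling
  scaled <- dplyr::mutate(boosted, value = value * 13)
  expect_equal(signal_fold_enrichment(scaled, pairs, rnd)$fold, r2$fold)
})
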