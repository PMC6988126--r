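# hand-built restriction map: one chromosome, 10 fragments of 1 kb
toy_rmap <- function() {
  tibble::tibble(chrom = "chr1", start = 0:9 * 1000, end = 1:10 * 1000,
                 frag = 1:10)
}

toy_pair <- function(pos1, pos2, frag1, frag2, strand1 = "+", strand2 = "-",
                     mapq1 = 60, mapq2 = 60) {
  tibble::tibble(chrom1 = "chr1", pos1 = pos1, strand1 = strand1, frag1 = frag1,
                 chrom2 = "chr1", pos2 = pos2, strand2 = strand2, frag2 = frag2,
                 mapq1 = mapq1, mapq2 = mapq2)
}

test_that("valid-pair filters apply the hand-derived rules in order", {
  # fragment 1 is 20 kb wide so a read can sit > 5 kb from both of its sites
  big_rmap <- tibble::tibble(chrom = "chr1",
                             start = c(0, seq(20000, 90000, by = 10000)),
                             end = c(seq(20000, 90000, by = 10000), 100000),
                             frag = 1:9)
  pairs <- dplyr::bind_rows(
    toy_pair(1001, 90500, 1, 9),                # keep
    toy_pair(2001, 85000, 1, 8),                # keep
    toy_pair(21000, 95000, 2, 9),               # keep
    toy_pair(31000, 72000, 3, 7),               # keep
    toy_pair(41000, 62000, 4, 6),               # keep
    toy_pair(1001, 90500, 1, 9, mapq1 = 10),    # low mapq mate 1
    toy_pair(2001, 85000, 1, 8, mapq2 = 5),     # low mapq mate 2
    toy_pair(1001, 90500, 1, 9),                # duplicate of pair 1
    toy_pair(3000, 7000, 1, 1),                 # self-ligation
    toy_pair(10000, 95000, 1, 9)                # ~10 kb from the nearest site
  )
  res <- filter_pairs(pairs, big_rmap)
  expect_equal(nrow(res$pairs), 5)
  expect_equal(res$report$removed, c(2L, 1L, 1L, 1L, 0L))
  # categories sum to input - output
  expect_equal(sum(res$report$removed), nrow(pairs) - nrow(res$pairs))
})

test_that("self-ligated and religation pairs are removed, dedup keeps one copy", {
  rmap <- toy_rmap()
  pairs <- dplyr::bind_rows(
    toy_pair(1500, 1800, 2, 2),                       # self
    toy_pair(1500, 2500, 2, 3, "+", "-"),             # adjacent, opposite strands
    toy_pair(1500, 2500, 2, 3, "+", "+"),             # adjacent, same strand: kept
    toy_pair(500, 8500, 1, 9),
    toy_pair(500, 8500, 1, 9)                         # duplicate
  )
  res <- filter_pairs(pairs, rmap)
  expect_equal(nrow(res$pairs), 2)
  expect_equal(res$report$removed[res$report$stage == "self_ligation"], 1L)
  expect_equal(res$report$removed[res$report$stage == "religation"], 1L)
  expect_equal(res$report$removed[res$report$stage == "duplicate"], 1L)
  expect_error(filter_pairs(toy_pair(500, 900, 1, 99), rmap), "out of range")
})

test_that("binning counts pairs symmetrically and rebinning is block summation", {
  cs <- c(chr1 = 1e5)
  one <- toy_pair(15000, 75000, 2, 8)
  m <- bin_pairs(one, cs, bin_size = 1e4)$cis$chr1
  expect_equal(sum(m$counts), 2)          # off-diagonal pair counted twice
  expect_equal(m$counts[2, 8], 1)
  same_bin <- toy_pair(15000, 16000, 2, 2, strand2 = "+")
  m2 <- bin_pairs(same_bin, cs, bin_size = 1e4)$cis$chr1
  expect_equal(sum(m2$counts), 1)         # same-bin pair counted once
  empty <- bin_pairs(one[0, ], cs, bin_size = 1e4)$cis$chr1
  expect_equal(sum(empty$counts), 0)
  # rebinning 10 kb -> 40 kb by 4x4 block sums equals direct 40 kb binning
  set.seed(5)
  many <- tibble::tibble(
    chrom1 = "chr1", pos1 = sample(1e5, 500, TRUE), strand1 = "+", frag1 = 1,
    chrom2 = "chr1", pos2 = sample(1e5, 500, TRUE), strand2 = "-", frag2 = 2,
    mapq1 = 60, mapq2 = 60)
  canon <- dplyr::mutate(many, p1 = pmin(pos1, pos2), p2 = pmax(pos1, pos2),
                         pos1 = p1, pos2 = p2)
  fine <- bin_pairs(canon, cs, bin_size = 1e4)$cis$chr1
  direct <- bin_pairs(canon, cs, bin_size = 4e4)$cis$chr1
  expect_equal(rebin(fine, 4e4)$counts, direct$counts)
})

test_that("bins below 10% of the median fragment count are masked (strict <)", {
  # fragment counts per 1 kb bin: 100, 100, 100, 5 -> median 100, cutoff 10
  frag_counts <- c(100, 100, 100, 5)
  rmap <- purrr::imap_dfr(frag_counts, function(k, bin) {
    tibble::tibble(chrom = "chrT",
                   start = (bin - 1) * 1000 + seq(0, 999, length.out = k + 1)[-(k + 1)],
                   end = (bin - 1) * 1000 + seq(0, 999, length.out = k + 1)[-1])
  })
  rmap$frag <- seq_len(nrow(rmap))
  m <- contact_matrix(matrix(1, 4, 4) - diag(4), chrom = "chrT", bin_size = 1000)
  masked <- mask_bins(m, rmap)
  expect_equal(masked$mask, c(FALSE, FALSE, FALSE, TRUE))
  # all-equal fragment counts: nothing masked
  rmap_eq <- tibble::tibble(chrom = "chrT", start = seq(0, 3900, by = 100),
                            end = seq(100, 4000, by = 100), frag = 1:40)
  expect_equal(sum(mask_bins(m, rmap_eq)$mask), 0)
  # a bin at exactly 10% of the median is kept
  frag_counts3 <- c(100, 100, 100, 10)
  rmap3 <- purrr::imap_dfr(frag_counts3, function(k, bin) {
    tibble::tibble(chrom = "chrT",
                   start = (bin - 1) * 1000 + seq(0, 999, length.out = k + 1)[-(k + 1)],
                   end = (bin - 1) * 1000 + seq(0, 999, length.out = k + 1)[-1])
  })
  rmap3$frag <- seq_len(nrow(rmap3))
  expect_equal(sum(mask_bins(m, rmap3)$mask), 0)
})

test_that("KR balancing equalizes row sums and matches the Sinkhorn oracle", {
  a <- random_symmetric(6, seed = 21)
  m <- contact_matrix(a, bin_size = 1e4)
  bal <- balance_kr(m)
  rs <- rowSums(bal$counts)
  expect_lt(sd(rs) / mean(rs), 1e-6)
  target <- mean(rowSums(a))
  x_oracle <- oracle_sinkhorn(a / target)
  w_oracle <- x_oracle / sqrt(target)
  expect_lt(max(abs(bal$weights / bal$weights[1] - w_oracle / w_oracle[1])), 1e-6)
  # an already doubly-balanced matrix gets equal weights
  ones <- matrix(1, 5, 5) - diag(5)
  w <- balance_kr(contact_matrix(ones, bin_size = 1e4))$weights
  expect_lt(diff(range(w)), 1e-8)
})

test_that("balancing commutes with bin permutation and auto-masks empty rows", {
  a <- random_symmetric(8, seed = 3)
  m <- contact_matrix(a, bin_size = 1e4)
  perm <- c(3, 1, 4, 2, 8, 6, 5, 7)
  bal1 <- balance_kr(m)
  bal2 <- balance_kr(contact_matrix(a[perm, perm], bin_size = 1e4))
  expect_equal(bal2$weights, bal1$weights[perm], tolerance = 1e-6)
  a0 <- a; a0[4, ] <- 0; a0[, 4] <- 0
  expect_warning(bal0 <- balance_kr(contact_matrix(a0, bin_size = 1e4)),
                 "auto-masking")
  expect_true(bal0$mask[4])
  expect_equal(bal0$weights[4], 0)
})

test_that("O/E transform matches brute-force per-diagonal means", {
  a <- random_symmetric(5, seed = 12)
  m <- contact_matrix(a, bin_size = 1e4)
  oe <- oe_transform(m)
  emat <- oracle_expected_matrix(a)
  ref <- a / ifelse(emat == 0, NA, emat)
  expect_equal(oe$counts[upper.tri(a)], ref[upper.tri(a)])
  # mean of O/E over each off-diagonal equals 1 by construction
  for (d in 1:4) {
    dd <- abs(outer(1:5, 1:5, `-`)) == d
    expect_equal(mean(oe$counts[dd], na.rm = TRUE), 1)
  }
  # translation-invariant matrix -> O/E identically 1 off the diagonal
  ti <- outer(1:10, 1:10, function(i, j) 100 / (1 + abs(i - j)))
  diag(ti) <- 0
  oe_ti <- oe_transform(contact_matrix(ti, bin_size = 1e4))
  offd <- upper.tri(ti)
  expect_true(all(abs(oe_ti$counts[offd] - 1) < 1e-12))
})

test_that("P(s) curve is flat for a flat matrix and depth-invariant", {
  flat <- matrix(10, 30, 30); diag(flat) <- 0
  ps <- contact_probability_curve(contact_matrix(flat, bin_size = 1e4))
  expect_lt(diff(range(ps$density)), 1e-12)
  m <- sim_null_matrix(100, depth = 5e5, seed = 6)
  m2 <- contact_matrix(m$counts * 7, bin_size = m$bin_size)
  expect_equal(contact_probability_curve(m)$prob,
               contact_probability_curve(m2)$prob)
})

test_that("balanced structureless matrices have O/E near 1 everywhere", {
  m <- sim_null_matrix(150, depth = 1e6, seed = 17)
  oe <- oe_transform(balance_kr(m))
  vals <- oe$counts[upper.tri(oe$counts)]
  expect_lt(abs(mean(vals, na.rm = TRUE) - 1), 0.02)
})
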