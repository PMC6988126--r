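# Independent oracles and small fixture builders, coded separately from the
# package implementation paths they check.

# plain Sinkhorn iteration: x with diag(x) A diag(x) doubly stochastic
oracle_sinkhorn <- function(a, tol = 1e-12, max_iter = 50000L) {
  x <- rep(1, nrow(a))
  for (it in seq_len(max_iter)) {
    r <- as.vector(a %*% x) * x
    if (max(abs(r - 1)) < tol) break
    x <- x / sqrt(r)
  }
  x
}

# brute-force neighborhood expected value by explicit region enumeration:
# membership is evaluated for every cell of the matrix from the geometric
# definition of each region
oracle_region_member <- function(n, i, j, p, w, region) {
  dx <- outer(seq_len(n) - i, rep(1, n))
  dy <- outer(rep(1, n), seq_len(n) - j)
  cheb <- pmax(abs(dx), abs(dy))
  switch(region,
    donut = cheb <= w & cheb > p & dx != 0 & dy != 0,
    horizontal = abs(dx) <= 1 & abs(dy) > p & abs(dy) <= w,
    vertical = abs(dy) <= 1 & abs(dx) > p & abs(dx) <= w,
    lower_left = dx >= 1 & dx <= w & -dy >= 1 & -dy <= w &
      !(dx <= p & -dy <= p))
}

oracle_region_expected <- function(counts, exp_mat, i, j, p, w, region) {
  mem <- oracle_region_member(nrow(counts), i, j, p, w, region)
  sum(counts[mem]) / sum(exp_mat[mem]) * exp_mat[i, j]
}

# distance-expected matrix computed by direct per-diagonal means
oracle_expected_matrix <- function(counts) {
  n <- nrow(counts)
  d <- abs(outer(seq_len(n), seq_len(n), `-`))
  ev <- vapply(0:(n - 1), function(k) mean(counts[d == k]), numeric(1))
  out <- matrix(ev[d + 1], n, n)
  diag(out) <- 0
  out
}

# random symmetric positive matrix with zero diagonal
random_symmetric <- function(n, seed, lambda = 30) {
  set.seed(seed)
  a <- matrix(rpois(n * n, lambda) + 1, n)
  a <- a + t(a)
  diag(a) <- 0
  a
}

# quick structureless (decay-only) simulated matrix
sim_null_matrix <- function(n_bins, depth, bin_size = 1e5, seed = 1) {
  simulate_contact_matrix(
    synthetic_genome_spec(n_bins * bin_size, bin_size, seed = seed),
    planted_structure(n_bins, decay_exponent = -1, depth = depth)
  )$matrix
}
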