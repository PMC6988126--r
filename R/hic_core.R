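#' Build a restriction fragment map
#'
#' Fragments tile each chromosome without gaps or overlaps (0-based
#' half-open). `simulate_restriction_map()` draws fragment lengths around a
#' target mean to emulate a 4-cutter digest.
#'
#' @param chrom_sizes named numeric vector, chromosome -> length bp.
#' @param mean_frag_bp mean fragment length (MboI/DpnII-like ~ 400 bp).
#' @param enzyme enzyme label.
#' @param seed integer seed.
#' @return A tibble with `chrom`, `start`, `end`, `frag` (1-based global
#'   fragment index), plus attribute `enzyme`.
#' @export
simulate_restriction_map <- function(chrom_sizes, mean_frag_bp = 400,
                                     enzyme = "MboI", seed = 1L) {
  stopifnot(all(chrom_sizes > 0), mean_frag_bp > 0)
  with_seed(seed, {
    maps <- purrr::imap(as.list(chrom_sizes), function(len, chrom) {
      n_guess <- ceiling(len / mean_frag_bp) * 2 + 10
      lens <- pmax(1, stats::rpois(n_guess, mean_frag_bp))
      ends <- cumsum(lens)
      ends <- c(ends[ends < len], len)
      tibble::tibble(chrom = chrom, start = c(0, utils::head(ends, -1)), end = ends)
    })
    rmap <- dplyr::bind_rows(maps)
    rmap$frag <- seq_len(nrow(rmap))
    attr(rmap, "enzyme") <- enzyme
    rmap
  })
}

# validate that fragment indices refer to rows of the map
check_frags <- function(frags, rmap) {
  if (any(frags < 1 | frags > nrow(rmap), na.rm = TRUE)) {
    stop("fragment index out of range of the restriction map", call. = FALSE)
  }
}

#' Filter Hi-C read pairs
#'
#' Applies, in order, the standard valid-pair filters, counting removals at
#' each stage: mate mapping quality, PCR duplicates (identical 5' positions
#' and strands of both mates), self-ligated fragments (both mates on one
#' fragment), reads mapping too far from the nearest restriction site of
#' their fragment, and uninformative religation products (adjacent-fragment
#' pairs with religation-compatible opposite strand orientation).
#'
#' @param pairs tibble with columns `chrom1`, `pos1` (1-based 5' position),
#'   `strand1`, `frag1`, `chrom2`, `pos2`, `strand2`, `frag2`, `mapq1`,
#'   `mapq2`; mate order canonicalized so `(chrom1, pos1) <= (chrom2, pos2)`.
#' @param rmap restriction map tibble (see [simulate_restriction_map()]).
#' @param min_mapq minimum mapping quality on both mates.
#' @param max_site_dist maximum distance (bp) from a read 5' end to the
#'   nearest restriction site of its fragment.
#' @return A list with `pairs` (the surviving records) and `report` (tibble
#'   `stage`, `removed`, plus input/output totals as attributes).
#' @export
filter_pairs <- function(pairs, rmap, min_mapq = 30, max_site_dist = 5000) {
  pairs <- tibble::as_tibble(pairs)
  check_frags(c(pairs$frag1, pairs$frag2), rmap)
  n_in <- nrow(pairs)
  removed <- c(low_mapq = 0L, duplicate = 0L, self_ligation = 0L,
               far_from_site = 0L, religation = 0L)

  keep <- pairs$mapq1 >= min_mapq & pairs$mapq2 >= min_mapq
  removed["low_mapq"] <- sum(!keep)
  pairs <- pairs[keep, ]

  key <- paste(pairs$chrom1, pairs$pos1, pairs$strand1,
               pairs$chrom2, pairs$pos2, pairs$strand2)
  dup <- duplicated(key)
  removed["duplicate"] <- sum(dup)
  pairs <- pairs[!dup, ]

  self <- pairs$frag1 == pairs$frag2
  removed["self_ligation"] <- sum(self)
  pairs <- pairs[!self, ]

  site_dist <- function(pos, frag) {
    # distance from 1-based 5' position to the nearer fragment boundary
    s <- rmap$start[frag]; e <- rmap$end[frag]
    pmin(pos - 1 - s, e - (pos - 1))
  }
  far <- site_dist(pairs$pos1, pairs$frag1) > max_site_dist |
         site_dist(pairs$pos2, pairs$frag2) > max_site_dist
  removed["far_from_site"] <- sum(far)
  pairs <- pairs[!far, ]

  relig <- pairs$chrom1 == pairs$chrom2 &
           abs(pairs$frag2 - pairs$frag1) == 1 &
           pairs$strand1 != pairs$strand2
  removed["religation"] <- sum(relig)
  pairs <- pairs[!relig, ]

  report <- tibble::tibble(stage = names(removed), removed = as.integer(removed))
  attr(report, "n_in") <- n_in
  attr(report, "n_out") <- nrow(pairs)
  list(pairs = pairs, report = report)
}

#' Bin valid pairs into contact matrices
#'
#' Counts cis pairs per bin pair, symmetrized; trans pairs are routed to
#' per-chromosome-pair rectangular matrices (stored, unused by downstream
#' statistics).
#'
#' @param pairs tibble of valid pair records (1-based positions).
#' @param chrom_sizes named numeric vector, chromosome -> length bp.
#' @param bin_size bin width in bp.
#' @return A list with `cis` (named list of [contact_matrix()] per
#'   chromosome) and `trans` (named list of rectangular matrices keyed
#'   `"chromA|chromB"`).
#' @export
bin_pairs <- function(pairs, chrom_sizes, bin_size = 10000L) {
  stopifnot(all(chrom_sizes > 0), bin_size > 0)
  nb <- as.integer(ceiling(chrom_sizes / bin_size))
  names(nb) <- names(chrom_sizes)
  b1 <- (pairs$pos1 - 1) %/% bin_size + 1
  b2 <- (pairs$pos2 - 1) %/% bin_size + 1
  cis <- purrr::imap(as.list(nb), function(n, chrom) {
    sel <- which(pairs$chrom1 == chrom & pairs$chrom2 == chrom)
    up <- matrix(0, n, n)
    if (length(sel) > 0) {
      i <- pmin(b1[sel], b2[sel]); j <- pmax(b1[sel], b2[sel])
      agg <- dplyr::count(tibble::tibble(i = i, j = j), .data$i, .data$j)
      up[cbind(agg$i, agg$j)] <- agg$n
    }
    m <- up + t(up)
    diag(m) <- diag(up)            # same-bin pairs counted once
    contact_matrix(m, chrom = chrom, bin_size = bin_size)
  })
  trans <- list()
  tsel <- which(pairs$chrom1 != pairs$chrom2)
  if (length(tsel) > 0) {
    keys <- paste(pairs$chrom1[tsel], pairs$chrom2[tsel], sep = "|")
    for (key in unique(keys)) {
      cc <- strsplit(key, "|", fixed = TRUE)[[1]]
      m <- matrix(0, nb[[cc[1]]], nb[[cc[2]]])
      ksel <- tsel[keys == key]
      agg <- dplyr::count(tibble::tibble(i = b1[ksel], j = b2[ksel]),
                          .data$i, .data$j)
      m[cbind(agg$i, agg$j)] <- agg$n
      trans[[key]] <- m
    }
  }
  list(cis = cis, trans = trans)
}

#' Rebin a contact matrix to a coarser resolution
#'
#' Block-sums counts; a bin of the coarse grid is masked if all underlying
#' fine bins were masked.
#'
#' @param m a [contact_matrix()] (raw counts).
#' @param new_bin_size must be a multiple of `m$bin_size`.
#' @return A [contact_matrix()] at the new resolution.
#' @export
rebin <- function(m, new_bin_size) {
  f <- new_bin_size / m$bin_size
  if (f != round(f) || f < 1) {
    stop("new bin size must be a positive multiple of the current one", call. = FALSE)
  }
  f <- as.integer(f)
  n <- n_bins(m)
  grp <- (seq_len(n) - 1L) %/% f + 1L
  nn <- max(grp)
  agg <- rowsum(m$counts, grp)
  agg <- t(rowsum(t(agg), grp))
  # fine off-diagonal pixels falling into one coarse bin are stored twice
  # (symmetric storage) but represent one pair each: keep diagonal counts
  # on the pairs-counted-once convention
  diag_fine <- as.numeric(rowsum(diag(m$counts), grp))
  diag(agg) <- (diag(agg) + diag_fine) / 2
  mask <- as.logical(tapply(m$mask, grp, all))
  contact_matrix(agg, chrom = m$chrom, bin_size = as.integer(new_bin_size),
                 mask = mask)
}

#' Mask sparse bins
#'
#' Masks bins whose restriction fragment count is below 10% of the median
#' fragment count over bins containing at least one fragment (strict `<`).
#' Fragments are assigned to bins by midpoint. With
#' `on = "coverage"` the same rule is applied to per-bin read coverage
#' (row sums) instead.
#'
#' @param m a [contact_matrix()].
#' @param rmap restriction map tibble (required for `on = "fragments"`).
#' @param frac mask threshold as a fraction of the median.
#' @param on mask on per-bin `"fragments"` (default) or `"coverage"`.
#' @return The matrix with an updated `mask`.
#' @export
mask_bins <- function(m, rmap = NULL, frac = 0.10, on = c("fragments", "coverage")) {
  on <- match.arg(on)
  n <- n_bins(m)
  if (on == "fragments") {
    stopifnot(!is.null(rmap))
    rm_c <- dplyr::filter(rmap, .data$chrom == m$chrom)
    mid <- (rm_c$start + rm_c$end) / 2
    bin <- pmin(floor(mid / m$bin_size) + 1, n)
    stat <- tabulate(bin, nbins = n)
  } else {
    stat <- rowSums(m$counts)
  }
  med <- stats::median(stat[stat > 0])
  m$mask <- m$mask | (stat < frac * med)
  m
}

# independent of balance_kr's Newton path: plain Sinkhorn / iterative
# proportional fitting on the unmasked submatrix
sinkhorn_scale <- function(a, tol = 1e-10, max_iter = 10000L) {
  x <- rep(1, nrow(a))
  for (it in seq_len(max_iter)) {
    r <- as.vector(a %*% x) * x
    if (max(abs(r - 1)) < tol) break
    x <- x / sqrt(r)
  }
  x
}

# Knight-Ruiz balancing: inner conjugate-gradient Newton iteration.
# Returns x with diag(x) %*% a %*% diag(x) doubly stochastic, or NULL on
# failure to converge.
kr_scale <- function(a, tol = 1e-6, max_outer = 200L) {
  n <- nrow(a)
  e <- rep(1, n)
  x <- e
  delta <- 0.1; Delta <- 3
  g <- 0.9; etamax <- 0.1
  eta <- etamax
  stop_tol <- tol * 0.5
  rt <- tol^2
  v <- x * as.vector(a %*% x)
  rk <- 1 - v
  rho_km1 <- sum(rk * rk)
  rout <- rho_km1; rold <- rout
  n_outer <- 0L
  while (rout > rt) {
    n_outer <- n_outer + 1L
    if (n_outer > max_outer) return(NULL)
    k <- 0L
    y <- e
    innertol <- max(eta^2 * rout, rt)
    rho_km2 <- rho_km1
    Z <- p <- NULL
    while (rho_km1 > innertol) {
      k <- k + 1L
      if (k == 1L) {
        Z <- rk / v
        p <- Z
        rho_km1 <- sum(rk * Z)
      } else {
        beta <- rho_km1 / rho_km2
        p <- Z + beta * p
      }
      w <- x * as.vector(a %*% (x * p)) + v * p
      alpha <- rho_km1 / sum(p * w)
      ap <- alpha * p
      ynew <- y + ap
      if (min(ynew) <= delta) {
        ind <- which(ap < 0)
        gamma <- min((delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      if (max(ynew) >= Delta) {
        ind <- which(ynew > Delta)
        gamma <- min((Delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      y <- ynew
      rk <- rk - alpha * w
      rho_km2 <- rho_km1
      Z <- rk / v
      rho_km1 <- sum(rk * Z)
      if (k > 10L * n) break
    }
    x <- x * y
    v <- x * as.vector(a %*% x)
    rk <- 1 - v
    rho_km1 <- sum(rk * rk)
    rout <- rho_km1
    rat <- rout / rold
    rold <- rout
    res_norm <- sqrt(rout)
    eta_o <- eta
    eta <- g * rat
    if (g * eta_o^2 > 0.1) eta <- max(eta, g * eta_o^2)
    eta <- max(min(eta, etamax), stop_tol / res_norm)
  }
  x
}

#' Knight-Ruiz matrix balancing
#'
#' Computes per-bin weights `w` (0 for masked bins) such that
#' `diag(w) %*% A %*% diag(w)` has all unmasked row sums equal to the mean
#' unmasked raw row sum, within `tol` (coefficient of variation). Unmasked
#' all-zero rows are auto-masked with a warning. If the Newton iteration
#' fails to converge, the method falls back to Sinkhorn-style iterative
#' proportional fitting (recorded in the `method` field).
#'
#' @param m a masked [contact_matrix()].
#' @param tol convergence tolerance on row-sum uniformity.
#' @param max_iter maximum outer Newton iterations.
#' @return A balanced [contact_matrix()] with `weights` set and
#'   `normalized = TRUE`; the balancing route is in `m$balance_method`.
#' @export
balance_kr <- function(m, tol = 1e-6, max_iter = 200L) {
  zero_rows <- !m$mask & rowSums(m$counts) == 0
  if (any(zero_rows)) {
    warning(sprintf("auto-masking %d unmasked all-zero bins", sum(zero_rows)))
    m$mask <- m$mask | zero_rows
  }
  keep <- which(!m$mask)
  if (length(keep) == 0) stop("no unmasked bins to balance", call. = FALSE)
  a <- m$counts[keep, keep, drop = FALSE]
  target <- mean(rowSums(a))
  # pre-scale so the doubly-stochastic problem is well conditioned
  a_s <- a / target
  x <- kr_scale(a_s, tol = tol, max_outer = max_iter)
  method <- "kr"
  cv_of <- function(x) {
    rs <- x * as.vector(a_s %*% x)
    stats::sd(rs) / mean(rs)
  }
  if (is.null(x) || !all(is.finite(x)) || cv_of(x) > tol) {
    x <- sinkhorn_scale(a_s, tol = tol * 1e-3)
    method <- "sinkhorn_fallback"
    message("KR iteration did not converge; fell back to iterative proportional fitting")
  }
  w <- numeric(n_bins(m))
  # diag(x) a_s diag(x) rows sum to 1  =>  rows of diag(w) a diag(w) sum to target
  w[keep] <- x / sqrt(target)
  bal <- m$counts * outer(w, w)
  out <- contact_matrix(bal, chrom = m$chrom, bin_size = m$bin_size,
                        mask = m$mask, weights = w, normalized = TRUE)
  out$balance_method <- method
  out
}

#' Expected contact counts by distance
#'
#' Mean over unmasked pixels at each bin distance `d = |i - j|`.
#'
#' @param m a [contact_matrix()].
#' @return A tibble with `distance` (bins), `distance_bp`, `expected`
#'   (mean pixel value) and `n_pixels`.
#' @export
expected_by_distance <- function(m) {
  a <- masked_counts(m)
  n <- nrow(a)
  d <- abs(outer(seq_len(n), seq_len(n), `-`))
  ok <- !is.na(a)
  tibble::tibble(
    distance = 0:(n - 1),
    expected = as.numeric(tapply(a[ok], d[ok], mean)[as.character(0:(n - 1))]),
    n_pixels = as.integer(tapply(ok[ok], d[ok], length)[as.character(0:(n - 1))])
  ) |>
    dplyr::mutate(distance_bp = .data$distance * m$bin_size, .after = "distance")
}

#' Observed / expected transform
#'
#' Divides each pixel by the mean value at its distance. Pixels whose
#' expected value is 0 (or that are masked) become `NA` and are excluded
#' downstream. The mean of O/E over each diagonal with nonzero expected is
#' 1 by construction.
#'
#' @param m a [contact_matrix()] (typically balanced).
#' @param expected optional precomputed table from [expected_by_distance()].
#' @return A [contact_matrix()] of O/E values (element `oe = TRUE`).
#' @export
oe_transform <- function(m, expected = NULL) {
  if (is.null(expected)) expected <- expected_by_distance(m)
  a <- masked_counts(m)
  n <- nrow(a)
  d <- abs(outer(seq_len(n), seq_len(n), `-`))
  ev <- expected$expected[d + 1L]
  ev[ev == 0] <- NA_real_
  oe <- a / ev
  out <- contact_matrix(oe, chrom = m$chrom, bin_size = m$bin_size,
                        mask = m$mask, weights = m$weights,
                        normalized = m$normalized)
  out$oe <- TRUE
  out
}

#' Contact probability P(s) curve
#'
#' Mean contact frequency per log-spaced distance bin, normalized so the
#' per-bin probabilities sum to 1 over the cis range (distance >= 1 bin).
#' `density` (probability per unit bin distance) is the quantity whose
#' log-log slope estimates the distance-decay exponent.
#'
#' @param m a [contact_matrix()].
#' @param n_log_bins number of log-spaced distance bins.
#' @return A tibble with `dist_lo`, `dist_hi` (bins), `dist_mid_bp`,
#'   `prob`, `density` and `mean_count`.
#' @export
contact_probability_curve <- function(m, n_log_bins = 20) {
  ebd <- dplyr::filter(expected_by_distance(m), .data$distance >= 1,
                       !is.na(.data$expected))
  n <- n_bins(m)
  edges <- unique(round(exp(seq(log(1), log(n - 1), length.out = n_log_bins + 1))))
  if (length(edges) < 2) edges <- c(1, n - 1)
  bin <- cut(ebd$distance, breaks = c(edges[-length(edges)] - 0.5,
                                      edges[length(edges)] + 0.5),
             labels = FALSE)
  out <- ebd |>
    dplyr::mutate(lbin = bin) |>
    dplyr::filter(!is.na(.data$lbin)) |>
    dplyr::group_by(.data$lbin) |>
    dplyr::summarise(
      dist_lo = min(.data$distance), dist_hi = max(.data$distance),
      mean_count = mean(.data$expected),
      total = sum(.data$expected * .data$n_pixels),
      n_dist = dplyr::n(), .groups = "drop"
    )
  out |>
    dplyr::mutate(
      dist_mid_bp = exp((log(.data$dist_lo) + log(.data$dist_hi)) / 2) * m$bin_size,
      prob = .data$total / sum(.data$total),
      # normalized mean contact frequency per unit distance:
      # sum(density * n_dist) == 1, so its log-log slope is the decay exponent
      density = .data$mean_count / sum(.data$mean_count * .data$n_dist)
    ) |>
    dplyr::select("dist_lo", "dist_hi", "dist_mid_bp", "prob", "density",
                  "mean_count")
}
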