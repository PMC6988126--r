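# ---- local-background (donut filter) loop calling -------------------------
#
# Neighborhood geometries around a pixel (i, j), in offsets (dx, dy) with
# dx = x - i, dy = y - j, inner radius p, outer radius w:
#   donut       : max(|dx|,|dy|) <= w, max(|dx|,|dy|) > p, dx != 0, dy != 0
#   horizontal  : |dx| <= 1, p < |dy| <= w
#   vertical    : |dy| <= 1, p < |dx| <= w
#   lower_left  : 1 <= dx <= w, 1 <= -dy <= w, not (dx <= p and -dy <= p)
# All region sums decompose into axis-aligned box sums, computed through a
# summed-area table so every pixel is scored in O(1).

# summed-area table with a zero top row / left column for easy indexing
sat <- function(x) {
  n <- nrow(x); m <- ncol(x)
  s <- matrix(0, n + 1, m + 1)
  s[-1, -1] <- apply(apply(x, 2, cumsum), 1, cumsum) |> t()
  s
}

# vectorized box sum over rows r1..r2, cols c1..c2 (1-based, inclusive)
box_sum <- function(s, r1, r2, c1, c2) {
  s[cbind(r2 + 1, c2 + 1)] - s[cbind(r1, c2 + 1)] -
    s[cbind(r2 + 1, c1)] + s[cbind(r1, c1)]
}

neighborhoods <- c("donut", "horizontal", "vertical", "lower_left")

# region sums for pixel vectors i, j on SAT s (regions assumed in-bounds)
region_sums <- function(s, i, j, p, w) {
  donut <- box_sum(s, i - w, i + w, j - w, j + w) -
    box_sum(s, i - p, i + p, j - p, j + p) -
    (box_sum(s, i, i, j - w, j + w) - box_sum(s, i, i, j - p, j + p)) -
    (box_sum(s, i - w, i + w, j, j) - box_sum(s, i - p, i + p, j, j))
  horizontal <- box_sum(s, i - 1, i + 1, j - w, j + w) -
    box_sum(s, i - 1, i + 1, j - p, j + p)
  vertical <- box_sum(s, i - w, i + w, j - 1, j + 1) -
    box_sum(s, i - p, i + p, j - 1, j + 1)
  lower_left <- box_sum(s, i + 1, i + w, j - w, j - 1) -
    box_sum(s, i + 1, i + p, j - p, j - 1)
  list(donut = donut, horizontal = horizontal, vertical = vertical,
       lower_left = lower_left)
}

# observed and distance-expected matrices with masked bins and the diagonal
# zeroed, so they drop out of both numerator and denominator sums
loop_matrices <- function(m, expected = NULL) {
  if (is.null(expected)) expected <- expected_by_distance(m)
  n <- n_bins(m)
  x <- m$counts
  d <- abs(outer(seq_len(n), seq_len(n), `-`))
  ev <- matrix(expected$expected[d + 1L], n, n)
  ev[is.na(ev)] <- 0
  if (any(m$mask)) {
    x[m$mask, ] <- 0; x[, m$mask] <- 0
    ev[m$mask, ] <- 0; ev[, m$mask] <- 0
  }
  diag(x) <- 0; diag(ev) <- 0
  list(x = x, ev = ev, exp_tab = expected)
}

#' Local-background statistics for all eligible pixels
#'
#' For each upper-triangle pixel at least `w + 1` bins off the diagonal and
#' `w` bins inside the matrix edges, computes the local expected count for
#' the four neighborhood geometries (donut annulus excluding the center
#' cross, horizontal and vertical stripes, lower-left quadrant):
#' `expected = (sum observed in region / sum distance-expected in region) *
#' distance-expected(i, j)`. Statistics are computed on raw counts; masked
#' bins are excluded from all regions. Pixels whose region is fully masked
#' get `NA` expected and are counted in the `n_skipped` attribute.
#'
#' @param m a raw [contact_matrix()].
#' @param p inner (peak) radius in bins.
#' @param w outer (window) radius in bins.
#' @param pixels optional tibble with `bin1`, `bin2` restricting the pixels
#'   scored (must all be eligible).
#' @return A tibble with `bin1`, `bin2`, `observed`,
#'   `expected_<neighborhood>` and `enrichment_<neighborhood>` columns.
#' @export
neighborhood_stats <- function(m, p = 1, w = 5, pixels = NULL) {
  stopifnot(p >= 1, w > p)
  n <- n_bins(m)
  lm <- loop_matrices(m)
  if (is.null(pixels)) {
    eligible <- which(upper.tri(lm$x), arr.ind = TRUE)
    i <- eligible[, 1]; j <- eligible[, 2]
    ok <- (j - i) > w & i - w >= 1 & j + w <= n & i + w <= n & j - w >= 1 &
      !m$mask[i] & !m$mask[j]
    i <- i[ok]; j <- j[ok]
  } else {
    i <- pixels$bin1; j <- pixels$bin2
    if (any((j - i) <= w | i - w < 1 | j + w > n)) {
      stop("pixel not eligible: must be > w bins off-diagonal and w bins inside the matrix",
           call. = FALSE)
    }
  }
  sx <- sat(lm$x); se <- sat(lm$ev)
  obs_r <- region_sums(sx, i, j, p, w)
  exp_r <- region_sums(se, i, j, p, w)
  d <- j - i
  e_ij <- lm$exp_tab$expected[d + 1L]
  out <- tibble::tibble(bin1 = i, bin2 = j, observed = lm$x[cbind(i, j)])
  n_skipped <- 0L
  for (nb in neighborhoods) {
    el <- ifelse(exp_r[[nb]] > 0, obs_r[[nb]] / exp_r[[nb]] * e_ij, NA_real_)
    n_skipped <- max(n_skipped, sum(is.na(el)))
    out[[paste0("expected_", nb)]] <- el
    out[[paste0("enrichment_", nb)]] <- out$observed / el
  }
  attr(out, "n_skipped") <- n_skipped
  attr(out, "p") <- p
  attr(out, "w") <- w
  out
}

#' Local-background statistics for one pixel
#'
#' @inheritParams neighborhood_stats
#' @param i,j pixel bin indices (`i < j`).
#' @return A one-row tibble (see [neighborhood_stats()]).
#' @export
neighborhood_expected <- function(m, i, j, p = 1, w = 5) {
  neighborhood_stats(m, p = p, w = w,
                     pixels = tibble::tibble(bin1 = i, bin2 = j))
}

# lambda chunk index: k with lambda in [2^(k/3), 2^((k+1)/3))
lambda_chunk <- function(lambda) floor(3 * log2(pmax(lambda, 1)))

#' Per-pixel Poisson FDR
#'
#' For each neighborhood, p-values are upper-tail Poisson probabilities
#' `P(X >= observed | lambda = expected_local)`; Benjamini-Hochberg
#' correction is applied within lambda chunks
#' (`lambda in [2^(k/3), 2^((k+1)/3))`; all `lambda <= 1` form one chunk),
#' or globally with `lambda_chunking = FALSE`.
#'
#' @param stats tibble from [neighborhood_stats()].
#' @param lambda_chunking chunk the BH correction by local expected value.
#' @return `stats` with `p_<neighborhood>` and `fdr_<neighborhood>`
#'   columns appended.
#' @export
pixel_fdr <- function(stats, lambda_chunking = TRUE) {
  for (nb in neighborhoods) {
    lam <- stats[[paste0("expected_", nb)]]
    pv <- stats::ppois(stats$observed - 1, lam, lower.tail = FALSE)
    fdr <- rep(NA_real_, length(pv))
    ok <- which(!is.na(pv))
    if (length(ok) > 0) {
      if (lambda_chunking) {
        chunks <- split(ok, lambda_chunk(lam[ok]))
        for (idx in chunks) fdr[idx] <- stats::p.adjust(pv[idx], "BH")
      } else {
        fdr[ok] <- stats::p.adjust(pv[ok], "BH")
      }
    }
    stats[[paste0("p_", nb)]] <- pv
    stats[[paste0("fdr_", nb)]] <- fdr
  }
  stats
}

# 8-connected components of a set of pixels; returns integer labels
connected_components_8 <- function(i, j) {
  n <- length(i)
  lab <- integer(n)
  if (n == 0) return(lab)
  key <- paste(i, j)
  index <- stats::setNames(seq_len(n), key)
  cur <- 0L
  for (s in seq_len(n)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue) > 0) {
      q <- queue[1]; queue <- queue[-1]
      for (dx in -1:1) for (dy in -1:1) {
        if (dx == 0 && dy == 0) next
        nk <- paste(i[q] + dx, j[q] + dy)
        t <- index[nk]
        if (!is.na(t) && lab[t] == 0L) {
          lab[t] <- cur
          queue <- c(queue, t)
        }
      }
    }
  }
  lab
}

#' Call punctate interaction peaks (loops)
#'
#' Emits pixels that (i) are enriched at least `donut_fold` over the donut
#' neighborhood, (ii) have donut FDR at most `donut_fdr`, (iii) have FDR at
#' most `other_fdr` in the horizontal, vertical and lower-left
#' neighborhoods, and (iv) carry at least `min_obs` observed contacts.
#' Passing pixels within 8-connected adjacency are merged into one call
#' whose summit is the maximum-observed pixel. Criterion (iv) is a raw
#' count threshold, so calls are depth-dependent by design; statistics are
#' computed on raw (unbalanced) counts.
#'
#' @param m a raw [contact_matrix()] (the thresholds were designed for
#'   100 kb resolution).
#' @param p,w inner and outer neighborhood radii (bins).
#' @param donut_fold minimum donut enrichment.
#' @param donut_fdr maximum donut FDR.
#' @param other_fdr maximum FDR in the remaining neighborhoods.
#' @param min_obs minimum observed contacts at the peak center.
#' @param lambda_chunking see [pixel_fdr()].
#' @return A tibble of calls (`bin1`, `bin2`, genomic intervals, observed,
#'   enrichments, FDRs, `cluster_size`), with the full scored pixel table
#'   as attribute `pixel_stats`.
#' @export
call_peaks <- function(m, p = 1, w = 5, donut_fold = 2.25, donut_fdr = 0.05,
                       other_fdr = 0.1, min_obs = 29, lambda_chunking = TRUE) {
  stats <- pixel_fdr(neighborhood_stats(m, p = p, w = w),
                     lambda_chunking = lambda_chunking)
  pass <- with(stats,
    !is.na(enrichment_donut) & enrichment_donut >= donut_fold &
    !is.na(fdr_donut) & fdr_donut <= donut_fdr &
    !is.na(fdr_horizontal) & fdr_horizontal <= other_fdr &
    !is.na(fdr_vertical) & fdr_vertical <= other_fdr &
    !is.na(fdr_lower_left) & fdr_lower_left <= other_fdr &
    observed >= min_obs)
  sig <- stats[pass, ]
  if (nrow(sig) == 0) {
    calls <- sig
    calls$cluster_size <- integer(0)
  } else {
    lab <- connected_components_8(sig$bin1, sig$bin2)
    calls <- sig |>
      dplyr::mutate(.cluster = lab) |>
      dplyr::group_by(.data$.cluster) |>
      dplyr::arrange(dplyr::desc(.data$observed), .data$bin1, .data$bin2,
                     .by_group = TRUE) |>
      dplyr::mutate(cluster_size = dplyr::n()) |>
      dplyr::slice(1) |>
      dplyr::ungroup() |>
      dplyr::select(-".cluster")
  }
  bs <- m$bin_size
  calls <- dplyr::mutate(calls,
    chrom = m$chrom,
    start1 = (.data$bin1 - 1) * bs, end1 = .data$bin1 * bs,
    start2 = (.data$bin2 - 1) * bs, end2 = .data$bin2 * bs,
    .after = "bin2")
  attr(calls, "pixel_stats") <- stats
  calls
}
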