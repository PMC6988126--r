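# ---- aggregate peak / TAD analysis ---------------------------------------

# midpoint bin (1-based) of a genomic interval on the matrix grid
mid_bin <- function(start, end, bin_size, n) {
  pmin(pmax(floor(((start + end) / 2) / bin_size) + 1L, 1L), n)
}

#' Aggregate peak analysis with shifted-region controls
#'
#' For each cis anchor pair, extracts the observed window around the pixel
#' of the two anchor midpoints and divides it elementwise by the mean of
#' `n_shifts` control windows, obtained by shifting both anchors by the
#' same random offset (preserving separation and chromosome, never
#' overlapping the true window). The per-pair enrichment windows are
#' averaged into the aggregated matrix; the center score is the trimmed
#' mean of the central 5x5 pixels (50 kb at 10 kb resolution). The score is
#' a ratio statistic: doubling the matrix leaves it unchanged.
#'
#' @param m a raw [contact_matrix()] (10 kb resolution in the reference
#'   analysis).
#' @param pairs tibble of cis pairs with columns `start1`, `end1`,
#'   `start2`, `end2` (bp, source before sink) or `bin1`, `bin2`.
#' @param window window size in bp (501 kb window = 51 x 51 pixels at
#'   10 kb; an odd pixel count is enforced).
#' @param n_shifts number of shifted control windows per pair.
#' @param min_sep minimum anchor separation in bp.
#' @param shift_range offsets are drawn uniformly from
#'   `+/- [shift_range[1], shift_range[2]]` bp, rejecting overlaps with the
#'   true window.
#' @param trim fraction trimmed from each tail of the center pixels.
#' @param seed integer seed for the control shifts.
#' @param record_controls also return the control window centers (for
#'   auditing that every control preserves the pair separation).
#' @return An `apa_result` list: `aggregate` (matrix), `center_score`,
#'   `per_pair` (tibble of per-pair center scores), `n_used`, `n_skipped`,
#'   and (with `record_controls`) a `controls` tibble.
#' @export
apa <- function(m, pairs, window = 500000, n_shifts = 100, min_sep = 250000,
                shift_range = c(100000, 1000000), trim = 0.1, seed = 1L,
                record_controls = FALSE) {
  bs <- m$bin_size
  n <- n_bins(m)
  hw <- floor(window / bs / 2)          # half-width in bins
  pairs <- tibble::as_tibble(pairs)
  if (!all(c("bin1", "bin2") %in% names(pairs))) {
    pairs$bin1 <- mid_bin(pairs$start1, pairs$end1, bs, n)
    pairs$bin2 <- mid_bin(pairs$start2, pairs$end2, bs, n)
  }
  swap <- pairs$bin1 > pairs$bin2
  if (any(swap)) {
    tmp <- pairs$bin1[swap]
    pairs$bin1[swap] <- pairs$bin2[swap]
    pairs$bin2[swap] <- tmp
  }
  pairs <- dplyr::filter(pairs, (.data$bin2 - .data$bin1) * bs >= min_sep)
  x <- m$counts
  if (any(m$mask)) { x[m$mask, ] <- NA; x[, m$mask] <- NA }
  lo_s <- max(1L, floor(shift_range[1] / bs))
  hi_s <- max(lo_s, floor(shift_range[2] / bs))
  win_len <- 2L * hw + 1L
  acc <- matrix(0, win_len, win_len)
  npx <- matrix(0, win_len, win_len)
  per_pair <- numeric(0)
  controls <- list()
  n_used <- 0L; n_skipped <- 0L
  ctr <- (hw + 1L) + (-2:2)             # central 5x5
  with_seed(seed, {
    for (k in seq_len(nrow(pairs))) {
      i <- pairs$bin1[k]; j <- pairs$bin2[k]
      if (i - hw < 1 || j + hw > n || i + hw > n || j - hw < 1) {
        n_skipped <- n_skipped + 1L; next
      }
      obs <- x[(i - hw):(i + hw), (j - hw):(j + hw)]
      if (mean(is.na(obs)) > 0.5) { n_skipped <- n_skipped + 1L; next }
      ctrl <- matrix(0, win_len, win_len)
      n_ok <- 0L
      tries <- 0L
      while (n_ok < n_shifts && tries < 50L * n_shifts) {
        tries <- tries + 1L
        d <- sample(c(-(hi_s:lo_s), lo_s:hi_s), 1L)
        if (abs(d) <= 2L * hw) next     # would overlap the true window
        ii <- i + d; jj <- j + d
        if (ii - hw < 1 || jj + hw > n) next
        cw <- x[(ii - hw):(ii + hw), (jj - hw):(jj + hw)]
        cw[is.na(cw)] <- 0
        ctrl <- ctrl + cw
        n_ok <- n_ok + 1L
        if (record_controls) {
          controls[[length(controls) + 1L]] <-
            c(pair = k, bin1 = i, bin2 = j, ctrl1 = ii, ctrl2 = jj)
        }
      }
      if (n_ok == 0L) { n_skipped <- n_skipped + 1L; next }
      ctrl <- ctrl / n_ok
      enr <- obs / ctrl
      enr[!is.finite(enr)] <- NA
      ok <- !is.na(enr)
      acc[ok] <- acc[ok] + enr[ok]
      npx <- npx + ok
      n_used <- n_used + 1L
      per_pair <- c(per_pair, mean(enr[ctr, ctr], trim = trim, na.rm = TRUE))
    }
  })
  if (n_used == 0L) stop("no usable pairs for APA", call. = FALSE)
  agg <- acc / npx
  agg[npx == 0] <- NA
  structure(
    list(aggregate = agg,
         center_score = mean(agg[ctr, ctr], trim = trim, na.rm = TRUE),
         per_pair = tibble::tibble(pair = seq_along(per_pair),
                                   center_score = per_pair),
         n_used = n_used, n_skipped = n_skipped,
         bin_size = bs, window_bins = win_len, trim = trim,
         controls = if (record_controls) {
           tibble::as_tibble(do.call(rbind, controls))
         }),
    class = "apa_result"
  )
}

#' @export
print.apa_result <- function(x, ...) {
  cat(sprintf("<apa_result> %dx%d window, %d pairs used (%d skipped), center score %.3f\n",
              x$window_bins, x$window_bins, x$n_used, x$n_skipped, x$center_score))
  invisible(x)
}

#' @export
tidy.apa_result <- function(x, ...) {
  hw <- (x$window_bins - 1) / 2
  off <- (-hw:hw) * x$bin_size
  expand.grid(offset1 = off, offset2 = off) |>
    tibble::as_tibble() |>
    dplyr::mutate(enrichment = as.vector(x$aggregate))
}

#' @export
glance.apa_result <- function(x, ...) {
  tibble::tibble(center_score = x$center_score, n_used = x$n_used,
                 n_skipped = x$n_skipped, window_bins = x$window_bins)
}

#' @export
autoplot.apa_result <- function(object, ...) {
  df <- tidy.apa_result(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset2 / 1000,
                                   y = .data$offset1 / 1000,
                                   fill = .data$enrichment)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(midpoint = 1, low = "navy", mid = "white",
                                  high = "firebrick") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "offset (kb)", y = "offset (kb)",
                  title = sprintf("APA center score %.2f", object$center_score)) +
    ggplot2::theme_minimal()
}

#' Split pairs into distance quantiles
#'
#' Sorts pairs by separation and splits them into `k` equal-sized groups
#' (remainder assigned to the proximal groups); group 1 holds the most
#' proximal, group `k` the most distal interactions.
#'
#' @param pairs tibble with a `separation` column, or `start1/start2`
#'   (midpoint separation is computed), or `bin1/bin2` plus attribute-free
#'   `bin_size` argument.
#' @param k number of quantile groups.
#' @param bin_size bin size in bp when separation must be derived from
#'   `bin1`/`bin2`.
#' @return The pairs tibble with a `quantile` column, sorted by separation.
#' @export
distance_quantiles <- function(pairs, k = 5, bin_size = NULL) {
  pairs <- tibble::as_tibble(pairs)
  if (!"separation" %in% names(pairs)) {
    if (all(c("start1", "end1", "start2", "end2") %in% names(pairs))) {
      pairs$separation <- abs((pairs$start2 + pairs$end2) -
                              (pairs$start1 + pairs$end1)) / 2
    } else if (all(c("bin1", "bin2") %in% names(pairs))) {
      stopifnot(!is.null(bin_size))
      pairs$separation <- abs(pairs$bin2 - pairs$bin1) * bin_size
    } else {
      stop("pairs need `separation`, interval or bin columns", call. = FALSE)
    }
  }
  pairs <- dplyr::arrange(pairs, .data$separation)
  n <- nrow(pairs)
  k <- min(k, max(n, 1L))
  base <- n %/% k
  rem <- n %% k
  sizes <- rep(base, k) + c(rep(1L, rem), rep(0L, k - rem))
  pairs$quantile <- rep(seq_len(k), times = sizes)
  pairs
}

# nearest-neighbor resize of a matrix to out x out
resize_nearest <- function(a, out) {
  idx_r <- floor((seq_len(out) - 0.5) * nrow(a) / out) + 1L
  idx_c <- floor((seq_len(out) - 0.5) * ncol(a) / out) + 1L
  a[idx_r, idx_c, drop = FALSE]
}

#' Aggregate TAD analysis
#'
#' For each TAD, extracts the O/E submatrix spanning the TAD plus flanks of
#' one TAD length on each side, rescales it to `out_size` x `out_size` by
#' nearest-neighbor resampling, and averages across TADs. The central third
#' of the output corresponds to the TAD body.
#'
#' @param oe an O/E [contact_matrix()].
#' @param tad_intervals tibble with `start_bin`, `end_bin` (1-based,
#'   inclusive) or `start`, `end` (bp).
#' @param out_size output matrix size (a multiple of 3 keeps the TAD body
#'   exactly central).
#' @return A list with `aggregate` (matrix), `n_used`, `n_skipped` and
#'   `body_idx` (the output rows/cols covering the TAD body).
#' @export
aggregate_tads <- function(oe, tad_intervals, out_size = 90) {
  n <- n_bins(oe)
  ti <- tibble::as_tibble(tad_intervals)
  if (!all(c("start_bin", "end_bin") %in% names(ti))) {
    ti$start_bin <- floor(ti$start / oe$bin_size) + 1L
    ti$end_bin <- pmin(ceiling(ti$end / oe$bin_size), n)
  }
  a <- masked_counts(oe)
  acc <- matrix(0, out_size, out_size)
  cnt <- matrix(0, out_size, out_size)
  n_used <- 0L; n_skipped <- 0L
  for (k in seq_len(nrow(ti))) {
    s <- ti$start_bin[k]; e <- ti$end_bin[k]
    len <- e - s + 1L
    lo <- s - len; hi <- e + len
    if (lo < 1 || hi > n) { n_skipped <- n_skipped + 1L; next }
    sub <- resize_nearest(a[lo:hi, lo:hi], out_size)
    ok <- !is.na(sub)
    acc[ok] <- acc[ok] + sub[ok]
    cnt <- cnt + ok
    n_used <- n_used + 1L
  }
  if (n_used == 0L) stop("no usable TADs", call. = FALSE)
  agg <- acc / cnt
  agg[cnt == 0] <- NA
  third <- out_size / 3
  list(aggregate = agg, n_used = n_used, n_skipped = n_skipped,
       body_idx = (floor(third) + 1L):ceiling(2 * third))
}

#' Distance- and chromosome-matched random pairs
#'
#' For each observed pair, draws `n` random anchor pairs on the same
#' chromosome with the same separation (to within one bin), anchors sampled
#' uniformly from a candidate universe.
#'
#' @param pairs tibble with `chrom`, `start1`, `end1`, `start2`, `end2`.
#' @param universe candidate anchor intervals (`chrom`, `start`, `end`).
#' @param n random pairs per observed pair.
#' @param bin_size matching tolerance on separation (bp).
#' @param seed integer seed.
#' @return A tibble of random pairs with `pair_id` linking to the row of
#'   the observed pair.
#' @export
matched_random_pairs <- function(pairs, universe, n = 1000,
                                 bin_size = 10000, seed = 1L) {
  pairs <- tibble::as_tibble(pairs)
  universe <- tibble::as_tibble(universe)
  umid <- (universe$start + universe$end) / 2
  with_seed(seed, {
    out <- purrr::map(seq_len(nrow(pairs)), function(k) {
      ch <- pairs$chrom[k]
      sep <- abs((pairs$start2[k] + pairs$end2[k]) -
                 (pairs$start1[k] + pairs$end1[k])) / 2
      cand <- which(universe$chrom == ch)
      if (length(cand) < 2) return(NULL)
      src <- sample(cand, n, replace = TRUE)
      # sink at the matched separation, snapped to the candidate whose
      # midpoint is closest; accept within one bin
      snk <- vapply(src, function(s) {
        tgt <- umid[s] + sample(c(-1, 1), 1) * sep
        d <- abs(umid[cand] - tgt)
        cand[which.min(d)]
      }, integer(1))
      keep <- abs(abs(umid[snk] - umid[src]) - sep) <= bin_size
      tibble::tibble(pair_id = k, chrom = ch,
                     start1 = universe$start[src][keep],
                     end1 = universe$end[src][keep],
                     start2 = universe$start[snk][keep],
                     end2 = universe$end[snk][keep])
    })
    dplyr::bind_rows(out)
  })
}

#' Signal fold enrichment at paired anchors
#'
#' Mean of the signal at source and sink, divided by the mean of the same
#' statistic over the matched random pairs; invariant to global scaling of
#' the track.
#'
#' @param signal tibble with `chrom`, `start`, `end`, `value` (bedGraph
#'   semantics; mean value over the anchor interval is used).
#' @param pairs observed pairs (`chrom`, `start1`, `end1`, `start2`,
#'   `end2`).
#' @param random_pairs output of [matched_random_pairs()].
#' @return The pairs tibble with `signal_obs`, `signal_random` and `fold`
#'   columns.
#' @export
signal_fold_enrichment <- function(signal, pairs, random_pairs) {
  sig_at <- function(chrom, start, end) {
    vapply(seq_along(chrom), function(k) {
      sel <- signal$chrom == chrom[k] & signal$start < end[k] &
             signal$end > start[k]
      if (!any(sel)) return(0)
      ov <- pmin(signal$end[sel], end[k]) - pmax(signal$start[sel], start[k])
      sum(signal$value[sel] * ov) / sum(ov)
    }, numeric(1))
  }
  pairs <- tibble::as_tibble(pairs)
  pairs$signal_obs <- (sig_at(pairs$chrom, pairs$start1, pairs$end1) +
                       sig_at(pairs$chrom, pairs$start2, pairs$end2)) / 2
  rnd <- tibble::as_tibble(random_pairs)
  rnd$sig <- (sig_at(rnd$chrom, rnd$start1, rnd$end1) +
              sig_at(rnd$chrom, rnd$start2, rnd$end2)) / 2
  rmean <- rnd |>
    dplyr::group_by(.data$pair_id) |>
    dplyr::summarise(signal_random = mean(.data$sig), .groups = "drop")
  pairs$signal_random <- rmean$signal_random[match(seq_len(nrow(pairs)),
                                                   rmean$pair_id)]
  pairs$fold <- pairs$signal_obs / pairs$signal_random
  pairs
}
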