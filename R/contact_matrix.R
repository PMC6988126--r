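#' Contact matrix container
#'
#' A per-chromosome binned, symmetric contact-count matrix with a per-bin
#' mask and (after balancing) per-bin weights. Bins are 0-based half-open
#' `[k*bin_size, (k+1)*bin_size)`.
#'
#' @param counts symmetric, non-negative numeric matrix of contact counts.
#' @param chrom chromosome name.
#' @param bin_size bin width in bp.
#' @param mask logical per-bin vector; `TRUE` marks a masked (excluded) bin.
#' @param weights per-bin positive balancing weights, or `NULL` when the
#'   matrix is raw. Masked bins carry weight 0.
#' @param normalized logical; `TRUE` iff `counts` holds balanced values.
#'
#' @return An object of class `contact_matrix`.
#' @export
contact_matrix <- function(counts, chrom = "chrS", bin_size = 10000L,
                           mask = NULL, weights = NULL, normalized = FALSE) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) {
    stop("contact matrix must be square", call. = FALSE)
  }
  if (any(counts < 0, na.rm = TRUE)) {
    stop("contact counts must be non-negative", call. = FALSE)
  }
  if (max(abs(counts - t(counts)), na.rm = TRUE) > 1e-8 * (1 + max(abs(counts), na.rm = TRUE))) {
    stop("contact matrix must be symmetric", call. = FALSE)
  }
  n <- nrow(counts)
  if (is.null(mask)) mask <- rep(FALSE, n)
  stopifnot(length(mask) == n)
  if (!is.null(weights)) stopifnot(length(weights) == n)
  structure(
    list(counts = unname(counts), chrom = chrom, bin_size = as.integer(bin_size),
         mask = mask, weights = weights, normalized = isTRUE(normalized)),
    class = "contact_matrix"
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  n <- nrow(x$counts)
  cat(sprintf("<contact_matrix> %s: %d bins @ %d bp, %s, %d masked, total %.4g\n",
              x$chrom, n, x$bin_size,
              if (x$normalized) "balanced" else "raw",
              sum(x$mask), sum(x$counts, na.rm = TRUE)))
  invisible(x)
}

#' @export
dim.contact_matrix <- function(x) dim(x$counts)

n_bins <- function(m) nrow(m$counts)

#' Tidy a contact matrix into a long pixel table
#'
#' @param x a `contact_matrix`.
#' @param upper_only keep only pixels with `bin1 <= bin2`.
#' @param drop_zero drop zero-count pixels.
#' @param ... unused.
#' @return A tibble with `bin1`, `bin2` (1-based bin indices), `start1`,
#'   `start2` (0-based bp), and `count`.
#' @export
tidy.contact_matrix <- function(x, upper_only = TRUE, drop_zero = TRUE, ...) {
  n <- n_bins(x)
  idx <- which(!is.na(x$counts), arr.ind = TRUE)
  out <- tibble::tibble(
    bin1 = idx[, 1], bin2 = idx[, 2],
    count = x$counts[idx]
  )
  if (upper_only) out <- dplyr::filter(out, .data$bin1 <= .data$bin2)
  if (drop_zero) out <- dplyr::filter(out, .data$count != 0)
  dplyr::mutate(out,
    start1 = (.data$bin1 - 1L) * x$bin_size,
    start2 = (.data$bin2 - 1L) * x$bin_size,
    .before = "count"
  )
}

#' One-row summary of a contact matrix
#'
#' @param x a `contact_matrix`.
#' @param ... unused.
#' @return A one-row tibble with bin count, total contacts, masked bins and
#'   balancing state.
#' @export
glance.contact_matrix <- function(x, ...) {
  tibble::tibble(
    chrom = x$chrom, n_bins = n_bins(x), bin_size = x$bin_size,
    total = sum(x$counts[!is.na(x$counts)]),
    n_masked = sum(x$mask), normalized = x$normalized
  )
}

#' Heatmap of a contact matrix
#'
#' @param object a `contact_matrix`.
#' @param log1p plot `log1p(count)` instead of raw counts.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.contact_matrix <- function(object, log1p = TRUE, ...) {
  df <- tidy.contact_matrix(object, upper_only = FALSE, drop_zero = FALSE)
  if (log1p) df$count <- log1p(df$count)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin2, y = .data$bin1, fill = .data$count)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkred",
                                 name = if (log1p) "log1p(count)" else "count") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "bin", y = "bin",
                  title = sprintf("%s @ %g kb", object$chrom, object$bin_size / 1000)) +
    ggplot2::theme_minimal()
}

# effective (analysis-ready) counts: masked rows/cols set NA
masked_counts <- function(m) {
  a <- m$counts
  if (any(m$mask)) {
    a[m$mask, ] <- NA_real_
    a[, m$mask] <- NA_real_
  }
  a
}
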