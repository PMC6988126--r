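#' A/B compartment eigenvector
#'
#' Transforms an O/E matrix into a Pearson correlation matrix (each row's
#' own diagonal entry excluded from the correlation) and extracts the
#' leading eigenvector (largest algebraic eigenvalue). The sign is oriented
#' with GC content as a proxy for activity: if the mean GC of
#' negative-entry bins exceeds that of positive-entry bins, the vector is
#' inverted, so positive values mark the (GC-richer, active) A compartment.
#'
#' @param oe an O/E [contact_matrix()] (typically at 500 kb).
#' @param gc_track per-bin GC fraction, length `n_bins(oe)`.
#' @return A tibble with `bin`, `start`, `eigenvector` (`NA` for masked or
#'   zero-variance bins), `compartment` (`"A"`/`"B"`) and `gc`; attributes
#'   `sign_oriented`, `excluded_bins`.
#' @export
compartment_vector <- function(oe, gc_track) {
  n <- n_bins(oe)
  stopifnot(length(gc_track) == n)
  a <- masked_counts(oe)
  diag(a) <- NA_real_            # self-correlation inflates structure
  keep <- which(!oe$mask)
  if (length(keep) < 3) stop("need at least 3 unmasked bins", call. = FALSE)
  sub <- a[keep, keep, drop = FALSE]
  # constant (zero-variance) rows cannot enter a correlation
  v <- apply(sub, 1, stats::var, na.rm = TRUE)
  const <- !is.finite(v) | v == 0
  excluded <- keep[const]
  keep <- keep[!const]
  if (length(keep) < 3) stop("fewer than 3 variable unmasked bins", call. = FALSE)
  sub <- a[keep, keep, drop = FALSE]
  cm <- suppressWarnings(stats::cor(sub, use = "pairwise.complete.obs"))
  cm[!is.finite(cm)] <- 0
  diag(cm) <- 1
  es <- eigen(cm, symmetric = TRUE)
  ev <- es$vectors[, which.max(es$values)]
  full <- rep(NA_real_, n)
  full[keep] <- ev
  pos <- which(full > 0); neg <- which(full < 0)
  oriented <- FALSE
  if (length(pos) > 0 && length(neg) > 0 &&
      mean(gc_track[neg]) > mean(gc_track[pos])) {
    full <- -full
    oriented <- TRUE
  }
  out <- tibble::tibble(
    bin = seq_len(n),
    start = (seq_len(n) - 1) * oe$bin_size,
    eigenvector = full,
    compartment = dplyr::case_when(full > 0 ~ "A", full < 0 ~ "B",
                                   TRUE ~ NA_character_),
    gc = gc_track
  )
  attr(out, "sign_oriented") <- oriented
  attr(out, "excluded_bins") <- excluded
  out
}

#' Compartmentalization strength
#'
#' Mean absolute Pearson correlation over unmasked off-diagonal entries of
#' the O/E correlation matrix; in `[0, 1]`, 1 for a perfect checkerboard.
#'
#' @param oe an O/E [contact_matrix()].
#' @return A single number.
#' @export
compartmentalization_strength <- function(oe) {
  a <- masked_counts(oe)
  diag(a) <- NA_real_
  keep <- which(!oe$mask)
  sub <- a[keep, keep, drop = FALSE]
  v <- apply(sub, 1, stats::var, na.rm = TRUE)
  sub <- sub[is.finite(v) & v > 0, is.finite(v) & v > 0, drop = FALSE]
  cm <- suppressWarnings(stats::cor(sub, use = "pairwise.complete.obs"))
  mean(abs(cm[upper.tri(cm)]), na.rm = TRUE)
}

#' Plot a compartment track
#'
#' @param object a tibble from [compartment_vector()].
#' @param ... unused.
#' @return A ggplot bar chart of the signed eigenvector.
#' @export
plot_compartments <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object, !is.na(.data$eigenvector)),
                  ggplot2::aes(x = .data$start / 1e6, y = .data$eigenvector,
                               fill = .data$compartment)) +
    ggplot2::geom_col(width = diff(range(object$start)) / nrow(object) / 1e6) +
    ggplot2::scale_fill_manual(values = c(A = "firebrick", B = "steelblue")) +
    ggplot2::labs(x = "position (Mb)", y = "eigenvector") +
    ggplot2::theme_minimal()
}
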