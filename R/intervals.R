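# ---- interval sets (BED semantics, 0-based half-open) ---------------------
#
# IRanges stands behind the merge/overlap/union semantics; the surface is a
# plain tibble (chrom, start, end, ...) sorted by (chrom, start).

as_iranges_by_chrom <- function(x) {
  split(IRanges::IRanges(start = x$start + 1L, end = x$end), x$chrom)
}

sort_intervals <- function(x) dplyr::arrange(x, .data$chrom, .data$start)

check_intervals <- function(x) {
  x <- tibble::as_tibble(x)
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  if (any(x$start >= x$end)) stop("intervals must satisfy start < end", call. = FALSE)
  sort_intervals(x)
}

#' Merge intervals closer than a gap
#'
#' Intervals on the same chromosome whose gap is strictly less than
#' `max_gap` are unioned (a gap of exactly `max_gap` is kept separate).
#' Idempotent.
#'
#' @param x interval tibble (`chrom`, `start`, `end`, 0-based half-open).
#' @param max_gap merge threshold in bp (strict `<`).
#' @return A merged, sorted interval tibble.
#' @export
merge_within <- function(x, max_gap = 0) {
  x <- check_intervals(x)
  irl <- as_iranges_by_chrom(x)
  red <- lapply(irl, IRanges::reduce, min.gapwidth = max(max_gap, 1))
  purrr::imap(red, function(ir, chrom) {
    tibble::tibble(chrom = chrom, start = IRanges::start(ir) - 1L,
                   end = IRanges::end(ir))
  }) |>
    dplyr::bind_rows() |>
    sort_intervals()
}

#' Keep intervals overlapping another set
#'
#' @param a,b interval tibbles.
#' @return Rows of `a` overlapping at least one interval of `b`.
#' @export
overlap_filter <- function(a, b) {
  a <- check_intervals(a); b <- check_intervals(b)
  keep <- vapply(seq_len(nrow(a)), function(k) {
    any(b$chrom == a$chrom[k] & b$start < a$end[k] & b$end > a$start[k])
  }, logical(1))
  a[keep, ]
}

#' Keep intervals strictly larger than a minimum size
#'
#' @param x interval tibble.
#' @param min_size size threshold in bp (strict `>`; an interval of exactly
#'   `min_size` is removed).
#' @return The filtered tibble.
#' @export
size_filter <- function(x, min_size) {
  x <- check_intervals(x)
  x[(x$end - x$start) > min_size, ]
}

#' Union-reduce two interval sets
#'
#' Combines overlapping ranges of both sets into single ranges.
#'
#' @param a,b interval tibbles.
#' @return The merged union, sorted.
#' @export
union_reduce <- function(a, b) {
  merge_within(dplyr::bind_rows(check_intervals(a)[c("chrom", "start", "end")],
                                check_intervals(b)[c("chrom", "start", "end")]),
               max_gap = 0)
}

#' Build a cis pair universe from domains
#'
#' All unordered cis pairs of domain midpoints separated by at least
#' `min_sep` bp.
#'
#' @param domains interval tibble.
#' @param min_sep minimum midpoint separation in bp (`>=`).
#' @param exclude_chroms chromosomes dropped before pairing (sex and
#'   mitochondrial chromosomes by default).
#' @return A tibble of pairs: `chrom`, `start1`, `end1`, `start2`, `end2`,
#'   `separation` (midpoint distance; source midpoint before sink).
#' @export
build_pair_universe <- function(domains, min_sep = 250000,
                                exclude_chroms = c("chrX", "chrY", "chrM", "chrMT")) {
  domains <- check_intervals(domains)
  domains <- domains[!domains$chrom %in% exclude_chroms, ]
  out <- purrr::map(split(domains, domains$chrom), function(d) {
    n <- nrow(d)
    if (n < 2) return(NULL)
    idx <- utils::combn(n, 2)
    mid <- (d$start + d$end) / 2
    sep <- abs(mid[idx[2, ]] - mid[idx[1, ]])
    keep <- sep >= min_sep
    tibble::tibble(chrom = d$chrom[1],
                   start1 = d$start[idx[1, keep]], end1 = d$end[idx[1, keep]],
                   start2 = d$start[idx[2, keep]], end2 = d$end[idx[2, keep]],
                   separation = sep[keep])
  })
  dplyr::bind_rows(out)
}

#' Annotate anchor overlap with a mark set
#'
#' Labels each pair `"both"`, `"one"` or `"neither"` by whether its anchor
#' intervals overlap the mark set.
#'
#' @param pairs pair tibble (`chrom`, `start1`, `end1`, `start2`, `end2`).
#' @param marks interval tibble.
#' @return The pairs tibble with an `anchor_overlap` column.
#' @export
annotate_anchor_overlap <- function(pairs, marks) {
  pairs <- tibble::as_tibble(pairs)
  hit <- function(chrom, start, end) {
    vapply(seq_along(chrom), function(k) {
      any(marks$chrom == chrom[k] & marks$start < end[k] & marks$end > start[k])
    }, logical(1))
  }
  if (nrow(marks) == 0) {
    pairs$anchor_overlap <- rep("neither", nrow(pairs))
    return(pairs)
  }
  h1 <- hit(pairs$chrom, pairs$start1, pairs$end1)
  h2 <- hit(pairs$chrom, pairs$start2, pairs$end2)
  pairs$anchor_overlap <- dplyr::case_when(h1 & h2 ~ "both",
                                           h1 | h2 ~ "one",
                                           TRUE ~ "neither")
  pairs
}
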