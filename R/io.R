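# ---- plain-text genomic I/O ----------------------------------------------
#
# Conventions (written into file headers where the format allows comments):
# BED / BEDPE / bedGraph coordinates are 0-based half-open; pairs-table
# positions are 1-based.

#' Read / write a pairs table
#'
#' TSV with columns `chrom1, pos1, strand1, frag1, chrom2, pos2, strand2,
#' frag2, mapq1, mapq2`; positions are 1-based (stated in the header
#' comment line).
#'
#' @param path file path.
#' @return `read_pairs()`: a tibble.
#' @export
read_pairs <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(
                    chrom1 = "c", strand1 = "c", chrom2 = "c", strand2 = "c",
                    .default = readr::col_double()))
}

#' @rdname read_pairs
#' @param pairs pairs tibble.
#' @export
write_pairs <- function(pairs, path) {
  writeLines("# pairs table; positions are 1-based", path)
  readr::write_tsv(pairs, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read / write BED intervals
#'
#' 0-based half-open; 3-6 columns (`chrom`, `start`, `end`, `name`,
#' `score`, `strand`).
#'
#' @param path file path.
#' @return `read_bed()`: a tibble.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    bad <- which(keep)[which(nf < 3)[1]]
    stop(sprintf("malformed BED line %d: fewer than 3 fields", bad), call. = FALSE)
  }
  ncol <- min(nf)
  cols <- c("chrom", "start", "end", "name", "score", "strand")[seq_len(min(ncol, 6))]
  out <- tibble::as_tibble(stats::setNames(
    as.data.frame(do.call(rbind, lapply(fields, `[`, seq_along(cols))),
                  stringsAsFactors = FALSE), cols))
  out$start <- suppressWarnings(as.numeric(out$start))
  out$end <- suppressWarnings(as.numeric(out$end))
  if (anyNA(out$start) || anyNA(out$end)) {
    bad <- which(keep)[which(is.na(out$start) | is.na(out$end))[1]]
    stop(sprintf("malformed BED line %d: non-numeric coordinates", bad), call. = FALSE)
  }
  if ("score" %in% names(out)) out$score <- as.numeric(out$score)
  out
}

#' @rdname read_bed
#' @param x interval tibble.
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"), names(x))
  writeLines(c("# BED: 0-based half-open",
               apply(as.data.frame(x[cols]), 1,
                     function(r) paste(trimws(r), collapse = "\t"))), path)
  invisible(path)
}

#' Read / write BEDPE pairs
#'
#' @param path file path.
#' @return `read_bedpe()`: a tibble with `chrom1, start1, end1, chrom2,
#'   start2, end2` and any extra columns.
#' @export
read_bedpe <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}

#' @rdname read_bedpe
#' @param x pairs tibble.
#' @export
write_bedpe <- function(x, path) {
  writeLines("# BEDPE: 0-based half-open", path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read / write bedGraph tracks
#'
#' @param path file path.
#' @return `read_bedgraph()`: tibble `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  readr::read_tsv(path, comment = "#",
                  col_names = c("chrom", "start", "end", "value"),
                  show_col_types = FALSE)
}

#' @rdname read_bedgraph
#' @param x tibble with `chrom`, `start`, `end`, `value`.
#' @export
write_bedgraph <- function(x, path) {
  writeLines("# bedGraph: 0-based half-open", path)
  readr::write_tsv(x[c("chrom", "start", "end", "value")], path,
                   append = TRUE, col_names = FALSE)
  invisible(path)
}

#' Read / write a dense contact matrix as TSV
#'
#' Header comments carry chromosome, bin size, mask and weights so the
#' round trip restores the full object.
#'
#' @param path file path.
#' @return `read_matrix_tsv()`: a [contact_matrix()].
#' @export
read_matrix_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(paste0("^# ", key, "="), "", grep(paste0("^# ", key, "="), hdr, value = TRUE))
  counts <- as.matrix(utils::read.table(text = lines[!grepl("^#", lines)], sep = "\t"))
  dimnames(counts) <- NULL
  mask <- as.logical(strsplit(get("mask"), ",")[[1]])
  wtxt <- get("weights")
  weights <- if (length(wtxt) && nzchar(wtxt)) as.numeric(strsplit(wtxt, ",")[[1]]) else NULL
  contact_matrix(counts, chrom = get("chrom"), bin_size = as.integer(get("bin_size")),
                 mask = mask, weights = weights,
                 normalized = as.logical(get("normalized")))
}

#' @rdname read_matrix_tsv
#' @param m a [contact_matrix()].
#' @export
write_matrix_tsv <- function(m, path) {
  hdr <- c(sprintf("# chrom=%s", m$chrom),
           sprintf("# bin_size=%d", m$bin_size),
           sprintf("# normalized=%s", m$normalized),
           sprintf("# mask=%s", paste(m$mask, collapse = ",")),
           sprintf("# weights=%s",
                   if (is.null(m$weights)) "" else
                     paste(format(m$weights, digits = 17), collapse = ",")))
  writeLines(hdr, path)
  utils::write.table(m$counts, path, append = TRUE, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a cooler-style binned text container
#'
#' Two TSV tables in one directory: `bins.tsv` (`chrom`, `start`, `end`,
#' `weight`) and `pixels.tsv` (`bin1_id`, `bin2_id`, `count`; upper
#' triangle, 0-based bin ids), mirroring the canonical binned-contact
#' schema.
#'
#' @param m a [contact_matrix()].
#' @param dir output directory (created).
#' @return `read_cooler_text()`: a [contact_matrix()].
#' @export
write_cooler_text <- function(m, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- n_bins(m)
  bins <- tibble::tibble(
    chrom = m$chrom, start = (seq_len(n) - 1) * m$bin_size,
    end = pmin(seq_len(n) * m$bin_size, n * m$bin_size),
    weight = if (is.null(m$weights)) NA_real_ else m$weights)
  readr::write_tsv(bins, file.path(dir, "bins.tsv"))
  px <- tidy.contact_matrix(m, upper_only = TRUE, drop_zero = TRUE)
  readr::write_tsv(tibble::tibble(bin1_id = px$bin1 - 1L, bin2_id = px$bin2 - 1L,
                                  count = px$count),
                   file.path(dir, "pixels.tsv"))
  invisible(dir)
}

#' @rdname write_cooler_text
#' @export
read_cooler_text <- function(dir) {
  bins <- readr::read_tsv(file.path(dir, "bins.tsv"), show_col_types = FALSE)
  px <- readr::read_tsv(file.path(dir, "pixels.tsv"), show_col_types = FALSE)
  n <- nrow(bins)
  counts <- matrix(0, n, n)
  counts[cbind(px$bin1_id + 1L, px$bin2_id + 1L)] <- px$count
  counts[cbind(px$bin2_id + 1L, px$bin1_id + 1L)] <- px$count
  w <- bins$weight
  has_w <- !all(is.na(w))
  contact_matrix(counts, chrom = bins$chrom[1],
                 bin_size = as.integer(bins$end[1] - bins$start[1]),
                 mask = if (has_w) w == 0 else rep(FALSE, n),
                 weights = if (has_w) w else NULL,
                 normalized = has_w)
}

#' Read / write a spot sub-volume as long-format TSV
#'
#' Plain-text voxel grid: columns `x`, `y`, `z` (1-based voxel indices) and
#' `intensity`, with voxel sizes in a JSON sidecar (`<path>.json`).
#'
#' @param path TSV path.
#' @return `read_spot_volume()`: a list with `vol` (3D array), `voxel_xy`,
#'   `voxel_z`.
#' @export
read_spot_volume <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  vol <- array(0, dim = c(max(df$x), max(df$y), max(df$z)))
  vol[cbind(df$x, df$y, df$z)] <- df$intensity
  list(vol = vol, voxel_xy = meta$voxel_xy, voxel_z = meta$voxel_z)
}

#' @rdname read_spot_volume
#' @param vol 3D array.
#' @param voxel_xy,voxel_z voxel sizes (nm).
#' @export
write_spot_volume <- function(vol, path, voxel_xy = 64.5, voxel_z = 150) {
  idx <- which(!is.na(vol), arr.ind = TRUE)
  readr::write_tsv(tibble::tibble(x = idx[, 1], y = idx[, 2], z = idx[, 3],
                                  intensity = vol[idx]), path)
  jsonlite::write_json(list(voxel_xy = voxel_xy, voxel_z = voxel_z),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
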