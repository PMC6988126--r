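# ---- 3D DNA-FISH spot analysis -------------------------------------------

#' Estimate and apply chromatic offsets
#'
#' `estimate_chromatic_offset()` measures the constant apparent 3D offset
#' between two color channels from multicolor calibration beads (mean
#' displacement); `chromatic_correct()` subtracts a per-channel offset from
#' spot coordinates. A zero offset is the identity.
#'
#' @param beads tibble with bead coordinates in both channels:
#'   `x_a, y_a, z_a, x_b, y_b, z_b` (nm).
#' @return A named numeric offset `c(x, y, z)` (channel b minus channel a).
#' @export
estimate_chromatic_offset <- function(beads) {
  beads <- tibble::as_tibble(beads)
  c(x = mean(beads$x_b - beads$x_a),
    y = mean(beads$y_b - beads$y_a),
    z = mean(beads$z_b - beads$z_a))
}

#' @rdname estimate_chromatic_offset
#' @param points tibble with `x`, `y`, `z` columns (nm).
#' @param offset numeric `c(x, y, z)` offset to subtract.
#' @return `points` with the offset subtracted.
#' @export
chromatic_correct <- function(points, offset) {
  points <- tibble::as_tibble(points)
  points$x <- points$x - offset[["x"]]
  points$y <- points$y - offset[["y"]]
  points$z <- points$z - offset[["z"]]
  points
}

#' Segment a spot sub-volume and compute its centroid
#'
#' Intensities are saturated beyond 96.5% of the sub-volume's maximum
#' intensity level (suppressing isolated noisy voxels), the mask is all
#' voxels at or above 90% of the maximum of the processed volume, and the
#' centroid is the intensity-weighted mean voxel position converted to nm
#' (voxel centers at `(index - 0.5) * voxel_size`). The maximum voxel
#' always passes, so the mask is never empty; the centroid is invariant to
#' intensity scaling and to uniform background below threshold.
#'
#' @param vol 3D numeric array of non-negative voxel intensities (x, y, z).
#' @param voxel_xy,voxel_z voxel size in nm (lateral, axial); anisotropic
#'   voxels (e.g. 64.5 x 64.5 x 150 nm) are the norm.
#' @param saturate_frac saturation level as a fraction of the maximum
#'   intensity.
#' @param threshold_frac mask threshold as a fraction of the processed
#'   maximum.
#' @param weighted intensity-weighted centroid (default) or plain mask
#'   centroid.
#' @return Named numeric centroid `c(x, y, z)` in nm.
#' @export
segment_centroid <- function(vol, voxel_xy = 64.5, voxel_z = 150,
                             saturate_frac = 0.965, threshold_frac = 0.9,
                             weighted = TRUE) {
  stopifnot(length(dim(vol)) == 3, all(vol >= 0))
  if (max(vol) == 0) stop("all-zero sub-volume: no spot to segment", call. = FALSE)
  clip <- saturate_frac * max(vol)
  v <- pmin(vol, clip)
  dim(v) <- dim(vol)
  thr <- threshold_frac * max(v)
  mask <- v >= thr
  idx <- which(mask, arr.ind = TRUE)
  wt <- if (weighted) v[mask] else rep(1, nrow(idx))
  ctr <- colSums(idx * wt) / sum(wt)
  c(x = (ctr[[1]] - 0.5) * voxel_xy,
    y = (ctr[[2]] - 0.5) * voxel_xy,
    z = (ctr[[3]] - 0.5) * voxel_z)
}

#' Inter-centroid 3D distances
#'
#' @param a,b tibbles of corrected centroids with `x`, `y`, `z` (nm), one
#'   row per spot pair.
#' @return A tibble with `pair` and `distance_nm` (Euclidean norm).
#' @export
pair_distances <- function(a, b) {
  stopifnot(nrow(a) == nrow(b))
  tibble::tibble(
    pair = seq_len(nrow(a)),
    distance_nm = sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
  )
}

#' Contact distance threshold from a calibration distribution
#'
#' `threshold = mean + k * SD` of the two-color colocalization precision
#' distances (same probe in two colors). With the reference calibration
#' (73 +/- 38 nm) and `k = 3` the threshold is 187 nm, below which two
#' probes are taken to colocalize.
#'
#' @param calib_distances numeric vector of calibration distances (nm), or
#'   a tibble with a `distance_nm` column.
#' @param k number of SDs above the mean.
#' @return Threshold in nm.
#' @export
contact_threshold <- function(calib_distances, k = 3) {
  if (is.data.frame(calib_distances)) {
    calib_distances <- calib_distances$distance_nm
  }
  m <- mean(calib_distances)
  s <- stats::sd(calib_distances)
  if (is.na(s)) s <- 0
  m + k * s
}

#' Contact probability with Wilson confidence interval
#'
#' Fraction of allele pairs whose inter-probe distance is strictly below
#' the threshold, with a Wilson 95% binomial CI. Monotone non-decreasing in
#' the threshold.
#'
#' @param distances numeric vector of distances (nm), or a tibble with a
#'   `distance_nm` column.
#' @param threshold contact threshold in nm (strict `<`).
#' @param conf CI confidence level.
#' @return A one-row tibble with `n`, `n_contact`, `probability`,
#'   `ci_lower`, `ci_upper`, `threshold_nm`.
#' @export
contact_probability <- function(distances, threshold, conf = 0.95) {
  if (is.data.frame(distances)) distances <- distances$distance_nm
  n <- length(distances)
  x <- sum(distances < threshold)
  ci <- wilson_ci(x, n, conf)
  tibble::tibble(n = n, n_contact = x, probability = x / n,
                 ci_lower = ci[["lower"]], ci_upper = ci[["upper"]],
                 threshold_nm = threshold)
}

#' Simulate a Gaussian spot sub-volume
#'
#' Test/demo helper: a 3D Gaussian intensity spot with Poisson shot noise
#' and uniform background on an anisotropic voxel grid.
#'
#' @param center_nm spot center `c(x, y, z)` in nm.
#' @param sigma_nm isotropic Gaussian sigma in nm.
#' @param dims voxel grid dimensions `c(nx, ny, nz)`.
#' @param voxel_xy,voxel_z voxel sizes (nm).
#' @param amplitude peak expected intensity.
#' @param background uniform expected background level.
#' @param noise add Poisson noise.
#' @param seed integer seed.
#' @return A 3D array.
#' @export
simulate_spot_volume <- function(center_nm, sigma_nm = 120,
                                 dims = c(20, 20, 10),
                                 voxel_xy = 64.5, voxel_z = 150,
                                 amplitude = 1000, background = 20,
                                 noise = TRUE, seed = 1L) {
  cx <- (seq_len(dims[1]) - 0.5) * voxel_xy
  cy <- (seq_len(dims[2]) - 0.5) * voxel_xy
  cz <- (seq_len(dims[3]) - 0.5) * voxel_z
  g <- outer(outer(stats::dnorm(cx, center_nm[1], sigma_nm),
                   stats::dnorm(cy, center_nm[2], sigma_nm)),
             stats::dnorm(cz, center_nm[3], sigma_nm))
  g <- g / max(g) * amplitude + background
  if (noise) {
    with_seed(seed, {
      v <- array(stats::rpois(length(g), g), dim = dims)
    })
    v
  } else {
    array(g, dim = dims)
  }
}
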