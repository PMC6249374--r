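# Occurrence-map construction: per-subject Gaussian smoothing, voxelwise
# averaging across subjects, and fraction thresholding into blobs.

FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

gaussian_kernel_1d <- function(sigma_vox) {
  # sampled Gaussian, renormalized to unit sum so interior mass is conserved
  half <- max(1L, ceiling(4 * sigma_vox))
  x <- seq(-half, half)
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# 1D convolution along one array axis with zero padding, via shifted-slice
# accumulation (vectorized; no per-voxel loop)
convolve_axis <- function(arr, kernel, axis) {
  half <- (length(kernel) - 1L) %/% 2L
  dims <- dim(arr)
  out <- array(0, dims)
  n <- dims[axis]
  idx_all <- list(seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]))
  for (j in seq_along(kernel)) {
    off <- j - half - 1L   # source = target + off
    src <- idx_all; dst <- idx_all
    lo <- max(1L, 1L - off); hi <- min(n, n - off)
    if (lo > hi) next
    dst[[axis]] <- lo:hi
    src[[axis]] <- (lo + off):(hi + off)
    out[dst[[1]], dst[[2]], dst[[3]]] <-
      out[dst[[1]], dst[[2]], dst[[3]]] +
      kernel[j] * arr[src[[1]], src[[2]], src[[3]]]
  }
  out
}

#' Gaussian-smooth a volume
#'
#' Separable Gaussian convolution with the kernel width given as full width
#' at half maximum in millimetres (sigma = FWHM / (2 sqrt(2 ln 2))),
#' converted to voxels per axis. Boundaries use zero padding; total mass is
#' conserved provided the structure lies at least 2 FWHM inside the grid
#' (checked: a relative mass loss above `mass_tol` raises an error).
#' `fwhm = 0` returns the input unchanged.
#'
#' @param volume A `labeled_volume` or `subject_mask`.
#' @param fwhm Kernel full width at half maximum, mm (>= 0).
#' @param mass_tol Maximum tolerated relative mass loss at the boundary.
#' @return A `labeled_volume` with the smoothed data.
#' @export
smooth_volume <- function(volume, fwhm, mass_tol = 1e-6) {
  if (inherits(volume, "subject_mask")) volume <- volume$volume
  if (fwhm < 0) stop("'fwhm' must be >= 0")
  if (fwhm == 0) return(volume)
  sigma_vox <- fwhm * FWHM_TO_SIGMA / volume$voxel_size
  mass0 <- sum(volume$data)

  # crop to the occupied bounding box padded by the kernel half-width: the
  # convolution is zero outside it, and this keeps smoothing cheap on large
  # grids holding small structures
  dims <- dim(volume$data)
  nz <- which(volume$data != 0, arr.ind = TRUE)
  if (nrow(nz) == 0L) return(volume)
  halves <- vapply(sigma_vox, function(s) max(1, ceiling(4 * s)), numeric(1))
  lo <- pmax(1L, apply(nz, 2, min) - halves)
  hi <- pmin(dims, apply(nz, 2, max) + halves)
  sub <- volume$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  for (axis in 1:3)
    sub <- convolve_axis(sub, gaussian_kernel_1d(sigma_vox[axis]), axis)
  out <- array(0, dims)
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sub

  if (mass0 > 0 && abs(sum(out) - mass0) / mass0 > mass_tol)
    stop(sprintf(paste0("smoothing lost %.3g%% of mask mass at the grid ",
                        "boundary; the structure must lie >= 2*FWHM from ",
                        "the grid edge"),
                 100 * (mass0 - sum(out)) / mass0))
  labeled_volume(out, volume$affine)
}

#' @rdname smooth_volume
#' @export
smooth_mask <- smooth_volume

#' Build a probabilistic (occurrence) map from per-subject volumes
#'
#' Each subject's volume is optionally smoothed, then the voxelwise
#' arithmetic mean across subjects is taken. Without smoothing the map's
#' values are occurrence fractions k/N: the proportion of subjects whose
#' mask contains the voxel, from 0 (absent in all) to 1 (present in all).
#'
#' @param masks List of `subject_mask` or `labeled_volume` objects sharing
#'   one grid and affine.
#' @param smoothing_fwhm Per-subject Gaussian FWHM in mm (0 = none).
#' @param structure,hemisphere Optional labels carried on the result.
#' @return An object of class `probability_map`: a `labeled_volume` in
#'   `$volume` plus `n_subjects`, `smoothing_fwhm`, `structure`,
#'   `hemisphere`.
#' @export
build_probability_map <- function(masks, smoothing_fwhm = 0,
                                  structure = NA_character_,
                                  hemisphere = NA_character_) {
  if (length(masks) < 1L) stop("need at least one mask")
  vols <- lapply(masks, function(m)
    if (inherits(m, "subject_mask")) m$volume else m)
  ref <- vols[[1]]
  bad <- which(!vapply(vols, same_grid, logical(1), b = ref))
  if (length(bad))
    stop("masks on mismatched grids at positions: ",
         paste(bad, collapse = ", "))
  acc <- array(0, dim(ref$data))
  for (v in vols) {
    if (smoothing_fwhm > 0) v <- smooth_volume(v, smoothing_fwhm)
    acc <- acc + v$data
  }
  structure(list(volume = labeled_volume(acc / length(vols), ref$affine),
                 n_subjects = length(vols),
                 smoothing_fwhm = smoothing_fwhm,
                 structure = structure, hemisphere = hemisphere),
            class = "probability_map")
}

#' @export
print.probability_map <- function(x, ...) {
  cat(sprintf("<probability_map> %s/%s: %d subjects, FWHM %g mm, max %0.3f\n",
              x$structure, x$hemisphere, x$n_subjects, x$smoothing_fwhm,
              max(x$volume$data)))
  invisible(x)
}

#' Threshold a probability map into a blob
#'
#' Keeps voxels whose occurrence value is greater than or equal to
#' `fraction` (inclusive, reading "present in at least a fraction f of
#' subjects").
#'
#' @param map A `probability_map` (or `labeled_volume` of values in [0,1]).
#' @param fraction Threshold fraction in (0, 1].
#' @return An object of class `blob`: `voxel_indices` (n x 3, 0-based),
#'   `affine`, `threshold`, `dims`.
#' @export
threshold_map <- function(map, fraction) {
  if (fraction <= 0 || fraction > 1)
    stop("'fraction' must be in (0, 1]")
  vol <- if (inherits(map, "probability_map")) map$volume else map
  keep <- which(vol$data >= fraction, arr.ind = TRUE)
  if (nrow(keep) == 0L)
    stop(sprintf("blob empty at threshold %g", fraction))
  structure(list(voxel_indices = unname(keep) - 1L, affine = vol$affine,
                 threshold = fraction, dims = dim(vol$data)),
            class = "blob")
}

#' @export
print.blob <- function(x, ...) {
  cat(sprintf("<blob> %d voxels at threshold %g\n",
              nrow(x$voxel_indices), x$threshold))
  invisible(x)
}

#' World coordinates (mm) of a blob's member voxel centers
#' @param blob A `blob`.
#' @return n x 3 matrix of world coordinates.
#' @export
blob_world_coords <- function(blob) {
  cbind(blob$voxel_indices, 1) %*% t(blob$affine)[, 1:3, drop = FALSE]
}

#' Convert a blob back to a binary labeled_volume
#' @param blob A `blob`.
#' @return A binary `labeled_volume` on the blob's source grid.
#' @export
blob_to_volume <- function(blob) {
  arr <- array(0, blob$dims)
  arr[blob$voxel_indices + 1L] <- 1
  labeled_volume(arr, blob$affine)
}
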