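# Shared fixture builders: tiny grids, masks from explicit voxel lists, and
# the compact single-hemisphere simulation configuration used by the
# calibration/power suites.

# binary labeled_volume with 1s at the given 0-based voxel indices
volume_from_voxels <- function(voxels, shape = c(10, 10, 10),
                               origin = c(0, 0, 0), spacing = 1) {
  g <- make_grid(shape, origin, spacing)
  arr <- g$data
  arr[as.matrix(voxels) + 1L] <- 1
  labeled_volume(arr, g$affine)
}

mask_from_voxels <- function(voxels, shape = c(10, 10, 10),
                             origin = c(0, 0, 0), subject_id = "S001",
                             hemisphere = "R", structure = "RS",
                             conformation_type = NA_integer_) {
  subject_mask(subject_id, hemisphere, structure,
               volume_from_voxels(voxels, shape, origin),
               conformation_type)
}

# compact 1 mm grid holding one jittered right rhinal sulcus with room for
# 3 mm smoothing; used by the replicate-cohort simulation suites
sim_rs_config <- function(seed, n_subjects = 30,
                          grid_shape = c(48, 56, 48),
                          grid_origin = c(-2, -42, -52), ...) {
  cohort_config(n_subjects = n_subjects, seed = seed, hemispheres = "R",
                structures = "RS", balanced_types = TRUE, p_type1 = 0.5,
                grid_shape = grid_shape, grid_origin = grid_origin, ...)
}

# random binary volume; `margin` keeps voxels that far from every grid
# edge (needed when the volume will be smoothed)
random_blob_volume <- function(n_vox = 50, shape = c(12, 12, 12),
                               origin = c(-4, -6, -2), margin = 0L) {
  inner <- shape - 2L * margin
  lin <- sample(prod(inner), n_vox)
  idx <- sweep(arrayInd(lin, inner) - 1L, 2, -margin)
  volume_from_voxels(unique(idx), shape, origin)
}
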