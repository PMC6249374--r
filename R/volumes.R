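#' Labeled volume: a 3D grid with a voxel-to-world affine
#'
#' The basic carrier for binary masks and probability maps. `data` is a 3D
#' numeric array; `affine` is the 4x4 matrix mapping 0-based voxel indices
#' (at voxel centers) to world coordinates in millimetres, following NIfTI
#' semantics.
#'
#' @param data 3D numeric array.
#' @param affine 4x4 numeric matrix, invertible; last row (0,0,0,1).
#' @return An object of class `labeled_volume` with elements `data`,
#'   `affine` and `voxel_size` (mm per axis, derived from the affine).
#' @export
labeled_volume <- function(data, affine = diag(4)) {
  if (length(dim(data)) != 3L)
    stop("'data' must be a 3D array")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("'affine' must be a 4x4 matrix")
  det_a <- det(affine)
  if (!is.finite(det_a) || abs(det_a) < .Machine$double.eps)
    stop("'affine' must be invertible")
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(vs <= 0)) stop("voxel sizes must be strictly positive")
  structure(list(data = data, affine = affine, voxel_size = vs),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  cat("<labeled_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, voxel size ", paste(signif(x$voxel_size, 4), collapse = " x "),
      " mm\n", sep = "")
  cat("  value range: [", paste(signif(range(x$data), 6), collapse = ", "),
      "]\n", sep = "")
  invisible(x)
}

#' Convert 0-based voxel indices to world millimetre coordinates
#'
#' @param volume A `labeled_volume`.
#' @param index Integer triple (0-based) or an n x 3 matrix of triples.
#' @return A numeric triple, or an n x 3 matrix of world coordinates (mm).
#' @export
voxel_to_world <- function(volume, index) {
  idx <- rbind(index)
  storage.mode(idx) <- "double"
  if (ncol(idx) != 3L) stop("'index' must have 3 columns")
  dims <- dim(volume$data)
  if (any(idx < 0) || any(idx > matrix(dims - 1L, nrow(idx), 3, byrow = TRUE)))
    stop("voxel index out of bounds")
  out <- cbind(idx, 1) %*% t(volume$affine)
  out <- out[, 1:3, drop = FALSE]
  if (is.null(dim(index)) && length(index) == 3L) drop(out) else out
}

#' Convert world millimetre coordinates to continuous 0-based voxel indices
#'
#' Inverse of [voxel_to_world()]; returns continuous indices (not rounded).
#'
#' @param volume A `labeled_volume`.
#' @param world Numeric triple or n x 3 matrix of world coordinates (mm).
#' @return Continuous voxel indices (0-based), same shape convention as input.
#' @export
world_to_voxel <- function(volume, world) {
  w <- rbind(world)
  if (ncol(w) != 3L) stop("'world' must have 3 columns")
  out <- cbind(w, 1) %*% t(solve(volume$affine))
  out <- out[, 1:3, drop = FALSE]
  if (is.null(dim(world)) && length(world) == 3L) drop(out) else out
}

#' World coordinates of all nonzero voxels
#'
#' @param volume A `labeled_volume`.
#' @return An n x 3 matrix of world coordinates (mm) of voxel centers with
#'   nonzero value, in array order.
#' @export
nonzero_world_coords <- function(volume) {
  idx <- which(volume$data != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(matrix(numeric(0), 0, 3))
  voxel_to_world(volume, idx - 1L)
}

#' Read a NIfTI volume as a labeled_volume
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A `labeled_volume`; the affine is taken from the image xform.
#' @export
read_volume <- function(path) {
  im <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(im))
  attributes(aff) <- list(dim = c(4L, 4L))
  arr <- as.array(im)
  attributes(arr) <- list(dim = dim(arr))
  labeled_volume(arr, aff)
}

#' Write a labeled_volume to NIfTI
#'
#' Data are stored as float32; the affine is written to both sform and qform.
#'
#' @param volume A `labeled_volume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  im <- RNifti::asNifti(volume$data)
  RNifti::sform(im) <- structure(volume$affine, code = 2L)
  RNifti::qform(im) <- structure(volume$affine, code = 2L)
  RNifti::writeNifti(im, path, datatype = "float")
  invisible(path)
}

STRUCTURES <- c("RS", "CSproper", "CSpost", "ERC", "PRC", "PHC", "TPC",
                "HH", "HB", "HT")
SULCI <- c("RS", "CSproper", "CSpost")

#' Subject mask: one subject x hemisphere x structure binary volume
#'
#' @param subject_id Subject identifier string.
#' @param hemisphere `"L"` or `"R"`.
#' @param structure One of `r paste(STRUCTURES, collapse = ", ")`.
#' @param volume A binary `labeled_volume` (values 0/1, at least one 1).
#' @param conformation_type 1, 2, or `NA` (unknown).
#' @return An object of class `subject_mask`.
#' @export
subject_mask <- function(subject_id, hemisphere, structure, volume,
                         conformation_type = NA_integer_) {
  hemisphere <- match.arg(hemisphere, c("L", "R"))
  structure_lbl <- match.arg(structure, STRUCTURES)
  stopifnot(inherits(volume, "labeled_volume"))
  check_binary(volume$data)
  if (!any(volume$data != 0)) stop("empty mask: no nonzero voxel")
  if (!is.na(conformation_type) && !conformation_type %in% c(1L, 2L))
    stop("conformation_type must be 1, 2 or NA")
  structure(list(subject_id = as.character(subject_id),
                 hemisphere = hemisphere, structure = structure_lbl,
                 conformation_type = as.integer(conformation_type),
                 volume = volume),
            class = "subject_mask")
}

check_binary <- function(data, tol = 1e-6) {
  bad <- abs(data) > tol & abs(data - 1) > tol
  if (any(bad)) {
    rng <- range(data[bad])
    stop(sprintf("non-binary mask: values outside {0,1} in range [%g, %g]",
                 rng[1], rng[2]))
  }
  invisible(TRUE)
}

#' Read a binary mask from NIfTI
#'
#' Values must be 0/1 after a rounding tolerance of 1e-6. Metadata
#' (subject, hemisphere, structure) is parsed from the filename convention
#' `<subject>_<hemisphere>_<structure>.nii[.gz]` unless given explicitly.
#'
#' @param path NIfTI file path.
#' @param subject_id,hemisphere,structure Optional metadata overrides.
#' @param conformation_type Optional type (1/2), e.g. joined from a cohort
#'   table sidecar.
#' @return A `subject_mask`.
#' @export
read_mask <- function(path, subject_id = NULL, hemisphere = NULL,
                      structure = NULL, conformation_type = NA_integer_) {
  vol <- read_volume(path)
  check_binary(vol$data)
  vol$data <- round(vol$data)
  if (!any(vol$data != 0)) stop("empty mask: no nonzero voxel")
  if (is.null(subject_id) || is.null(hemisphere) || is.null(structure)) {
    base <- sub("\\.nii(\\.gz)?$", "", basename(path))
    parts <- strsplit(base, "_", fixed = TRUE)[[1]]
    if (length(parts) < 3L)
      stop("cannot parse metadata from filename '", basename(path),
           "'; expected <subject>_<hemisphere>_<structure>.nii[.gz]")
    if (is.null(subject_id)) subject_id <- paste(parts[seq_len(length(parts) - 2L)], collapse = "_")
    if (is.null(hemisphere)) hemisphere <- parts[length(parts) - 1L]
    if (is.null(structure)) structure <- parts[length(parts)]
  }
  subject_mask(subject_id, hemisphere, structure, vol, conformation_type)
}

#' Write a subject mask to NIfTI using the filename convention
#'
#' @param mask A `subject_mask`.
#' @param dir Output directory.
#' @return The file path written, invisibly.
#' @export
write_mask <- function(mask, dir) {
  path <- file.path(dir, sprintf("%s_%s_%s.nii.gz", mask$subject_id,
                                 mask$hemisphere, mask$structure))
  write_volume(mask$volume, path)
  invisible(path)
}

#' Validate and read a cohort metadata table (TSV)
#'
#' Expected columns: subject_id, age, sex (F/M), hemisphere (L/R),
#' hemisphere_volume (mm^3), hemisphere_surface (mm^2),
#' conformation_type (1/2). One row per subject x hemisphere.
#'
#' @param path TSV path.
#' @param age_range Permitted age range in years.
#' @return A data.frame.
#' @export
read_cohort_table <- function(path, age_range = c(7, 17)) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_cohort_table(tab, age_range)
}

validate_cohort_table <- function(tab, age_range = c(7, 17)) {
  need <- c("subject_id", "age", "sex", "hemisphere", "hemisphere_volume",
            "hemisphere_surface", "conformation_type")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("cohort table missing columns: ", paste(missing_cols, collapse = ", "))
  if (!all(tab$sex %in% c("F", "M"))) stop("sex must be F or M")
  if (!all(tab$hemisphere %in% c("L", "R"))) stop("hemisphere must be L or R")
  if (anyDuplicated(tab[c("subject_id", "hemisphere")]))
    stop("cohort table must have one row per subject x hemisphere")
  if (any(tab$age < age_range[1] | tab$age > age_range[2]))
    stop(sprintf("ages outside configured range [%g, %g]",
                 age_range[1], age_range[2]))
  tab
}

#' Write a cohort table to TSV
#' @param tab Cohort data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sulcal morphometry table (TSV)
#'
#' Columns: subject_id, hemisphere, sulcus (RS/CSproper/CSpost), max_depth,
#' mean_depth, length (all mm, strictly positive, mean_depth <= max_depth),
#' conformation_type.
#'
#' @param path TSV path.
#' @return A data.frame.
#' @export
read_morphometry_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_morphometry_table(tab)
}

validate_morphometry_table <- function(tab) {
  need <- c("subject_id", "hemisphere", "sulcus", "max_depth", "mean_depth",
            "length", "conformation_type")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("morphometry table missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (!all(tab$sulcus %in% SULCI)) stop("unknown sulcus label")
  if (any(tab$max_depth <= 0 | tab$mean_depth <= 0 | tab$length <= 0))
    stop("morphometry measurements must be strictly positive")
  if (any(tab$mean_depth > tab$max_depth))
    stop("mean_depth must not exceed max_depth")
  tab
}

#' @rdname read_morphometry_table
#' @param tab Morphometry data.frame.
#' @export
write_morphometry_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) && max(abs(a$affine - b$affine)) < tol
}
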