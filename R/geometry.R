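# Geometric summaries of blobs and masks: per-axis extrema ("bounding box"),
# centers of mass, and total-least-squares (orthogonal distance) line fits.

coords_of <- function(x) {
  if (inherits(x, "blob")) return(blob_world_coords(x))
  if (inherits(x, "subject_mask")) x <- x$volume
  if (inherits(x, "probability_map")) x <- x$volume
  if (inherits(x, "labeled_volume")) return(nonzero_world_coords(x))
  if (is.matrix(x) && ncol(x) == 3L) return(x)
  stop("cannot extract coordinates from object of class ",
       paste(class(x), collapse = "/"))
}

#' Bounding box of a blob or mask
#'
#' Per-axis minimum and maximum world coordinates (mm) of occupied voxel
#' centers. On the mediolateral (x), rostrocaudal (y) and dorsoventral (z)
#' axes these are the structure's extrema.
#'
#' @param x A `blob`, `subject_mask`, `labeled_volume`, or n x 3 coordinate
#'   matrix.
#' @return A list with `min` and `max`, each a named (x, y, z) triple in mm.
#' @export
bounding_box <- function(x) {
  xyz <- coords_of(x)
  if (nrow(xyz) == 0L) stop("empty blob: no voxels")
  structure(list(min = stats::setNames(apply(xyz, 2, min), c("x", "y", "z")),
                 max = stats::setNames(apply(xyz, 2, max), c("x", "y", "z"))),
            class = "bounding_box")
}

#' @export
print.bounding_box <- function(x, ...) {
  cat("<bounding_box> (mm)\n")
  print(rbind(min = x$min, max = x$max))
  invisible(x)
}

#' Center of mass of a blob or mask
#'
#' Unweighted mean of member-voxel world coordinates: binary occupancy
#' weighting. A blob is a voxel set, not a weighted cloud, so occurrence
#' values do not weight the mean; set `weighted = TRUE` to weight by voxel
#' values of a `labeled_volume` instead.
#'
#' @param x A `blob`, `subject_mask`, `labeled_volume`, or n x 3 coordinate
#'   matrix.
#' @param weighted If `TRUE` and `x` carries voxel values, weight by them.
#' @return Named (x, y, z) world-mm triple.
#' @export
center_of_mass <- function(x, weighted = FALSE) {
  if (weighted) {
    if (inherits(x, "probability_map")) x <- x$volume
    if (!inherits(x, "labeled_volume"))
      stop("'weighted = TRUE' needs a labeled_volume")
    idx <- which(x$data != 0, arr.ind = TRUE)
    if (nrow(idx) == 0L) stop("empty volume")
    w <- x$data[idx]
    xyz <- voxel_to_world(x, idx - 1L)
    return(stats::setNames(colSums(xyz * w) / sum(w), c("x", "y", "z")))
  }
  xyz <- coords_of(x)
  if (nrow(xyz) == 0L) stop("empty blob: no voxels")
  stats::setNames(colMeans(xyz), c("x", "y", "z"))
}

#' Fit a 3D line by orthogonal distance regression (SVD)
#'
#' Fits the parametric line P = p0 + t * d to a cloud of 3D points, where
#' p0 is the coordinate mean, d the dominant right singular vector of the
#' centered point matrix (the direction minimizing total squared orthogonal
#' distance), and t the per-point projection. The sign of d is
#' canonicalized so the component of largest absolute value is positive
#' (ties broken in x, y, z order), making the fit a deterministic function
#' of the point set.
#'
#' @param points n x 3 matrix of world-mm coordinates, n >= 2, not all
#'   identical.
#' @return An object of class `line_fit` with `p0`, `d` (unit), `t_values`
#'   (zero-mean), `rss` (sum of squared orthogonal distances, mm^2) and
#'   `degenerate_direction` (`TRUE` when the two leading singular values
#'   tie, leaving the direction ill-determined).
#' @export
fit_odr_line <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("'points' must be an n x 3 matrix")
  if (nrow(points) < 2L) stop("need at least 2 points")
  p0 <- colMeans(points)
  centered <- sweep(points, 2, p0)
  if (max(abs(centered)) < 1e-12) stop("degenerate cloud: all points identical")
  sv <- svd(centered)
  d <- sv$v[, 1]
  d <- canonicalize_direction(d)
  tv <- drop(centered %*% d)
  rss <- sum(centered^2) - sum(tv^2)
  tie <- length(sv$d) >= 2 && sv$d[1] > 0 &&
    (sv$d[1] - sv$d[2]) / sv$d[1] < 1e-9
  if (tie)
    warning("leading singular values tie: line direction is ill-determined")
  structure(list(p0 = stats::setNames(p0, c("x", "y", "z")),
                 d = stats::setNames(d, c("x", "y", "z")),
                 t_values = tv, rss = max(rss, 0),
                 degenerate_direction = tie),
            class = "line_fit")
}

canonicalize_direction <- function(d) {
  d <- d / sqrt(sum(d^2))
  lead <- which.max(abs(d))   # which.max takes the first on ties: x, y, z order
  if (d[lead] < 0) d <- -d
  d
}

#' @export
print.line_fit <- function(x, ...) {
  cat(sprintf("<line_fit> p0 = (%.2f, %.2f, %.2f) mm, d = (%.3f, %.3f, %.3f), rss = %.3f mm^2\n",
              x$p0[1], x$p0[2], x$p0[3], x$d[1], x$d[2], x$d[3], x$rss))
  invisible(x)
}

#' Blob summary: bounding box, centroid, voxel count
#'
#' @param blob A `blob`.
#' @return A list suitable for JSON serialization.
#' @export
blob_summary <- function(blob) {
  bb <- bounding_box(blob)
  list(n_voxels = nrow(blob$voxel_indices),
       threshold = blob$threshold,
       bounding_box = list(min = as.list(bb$min), max = as.list(bb$max)),
       centroid = as.list(center_of_mass(blob)))
}
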