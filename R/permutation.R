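# Resampling inference between conformation types: permutation tests on
# group-blob bounding-box extrema and on centroids, and paired comparison
# of fitted line directions.

with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  expr
}

#' Construct a permutation test result
#'
#' The decision rule is two-sided by default: the observed group difference
#' is significant when it falls outside the central 95% interval of the
#' permutation null (2.5th-97.5th centiles, linear-interpolation
#' quantiles). A one-sided rule (significant when above the 95th centile)
#' is available via `alternative = "greater"`.
#'
#' @param statistic_name Label, e.g. `"x_max_diff"`.
#' @param observed Observed group difference (mm).
#' @param null_values Permutation null draws (length `n_perm`).
#' @param seed Seed used to build the null.
#' @param group_sizes Integer pair (n1, n2).
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @param conf_level Central interval mass (default 0.95).
#' @return An object of class `permutation_result` with the observed value,
#'   the null draws, the interval bounds and a significance flag.
#' @export
permutation_result <- function(statistic_name, observed, null_values,
                               seed = NA_integer_, group_sizes = c(NA, NA),
                               alternative = c("two.sided", "greater"),
                               conf_level = 0.95) {
  alternative <- match.arg(alternative)
  interval <- if (alternative == "two.sided") {
    unname(stats::quantile(null_values,
                           c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
                           type = 7))
  } else {
    c(-Inf, unname(stats::quantile(null_values, conf_level, type = 7)))
  }
  structure(list(statistic_name = statistic_name, observed = observed,
                 null_values = null_values, interval = interval,
                 significant = decide_significance(observed, interval),
                 n_perm = length(null_values), seed = seed,
                 group_sizes = group_sizes, alternative = alternative),
            class = "permutation_result")
}

#' Interval decision rule for permutation tests
#'
#' @param observed Observed statistic.
#' @param interval Length-2 numeric (lower, upper) null interval.
#' @return `TRUE` iff `observed` lies strictly outside the interval.
#' @export
decide_significance <- function(observed, interval) {
  observed < interval[1] || observed > interval[2]
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> %s: observed %.3g mm, null 95%% interval [%.3g, %.3g] (n_perm %d)%s\n",
              x$statistic_name, x$observed, x$interval[1], x$interval[2],
              x$n_perm, if (x$significant) " *" else ""))
  invisible(x)
}

#' Group-level blob: merge one group's masks and threshold
#'
#' Composition of [build_probability_map()] and [threshold_map()]
#' restricted to one group's masks.
#'
#' @param masks List of `subject_mask`/`labeled_volume` on one grid.
#' @param fraction Occurrence threshold in (0, 1].
#' @param smoothing_fwhm Per-subject Gaussian FWHM, mm.
#' @return A `blob`.
#' @export
group_blob <- function(masks, fraction, smoothing_fwhm = 0) {
  threshold_map(build_probability_map(masks, smoothing_fwhm), fraction)
}

conformation_labels <- function(masks) {
  labs <- vapply(masks, function(m) m$conformation_type, integer(1))
  if (anyNA(labs))
    stop("masks carry no conformation_type; supply 'labels' explicitly")
  labs
}

# stack (optionally smoothed) volumes over their joint nonzero support:
# returns V (n_support x n_masks), support world coords, grid reference
stack_support <- function(masks, smoothing_fwhm) {
  vols <- lapply(masks, function(m) {
    v <- if (inherits(m, "subject_mask")) m$volume else m
    if (smoothing_fwhm > 0) v <- smooth_volume(v, smoothing_fwhm)
    v
  })
  ref <- vols[[1]]
  bad <- which(!vapply(vols, same_grid, logical(1), b = ref))
  if (length(bad))
    stop("masks on mismatched grids at positions: ",
         paste(bad, collapse = ", "))
  any_nz <- Reduce(`+`, lapply(vols, function(v) as.numeric(v$data != 0)))
  support <- which(any_nz > 0)
  V <- vapply(vols, function(v) v$data[support], numeric(length(support)))
  idx <- arrayInd(support, dim(ref$data)) - 1L
  coords <- voxel_to_world(ref, idx)
  list(V = V, coords = coords, ref = ref)
}

# 6 bounding-box extrema (x/y/z min and max) of the voxels of `sel`
support_extrema <- function(coords, sel) {
  if (!any(sel)) return(NULL)
  xyz <- coords[sel, , drop = FALSE]
  c(x_min = min(xyz[, 1]), y_min = min(xyz[, 2]), z_min = min(xyz[, 3]),
    x_max = max(xyz[, 1]), y_max = max(xyz[, 2]), z_max = max(xyz[, 3]))
}

#' Permutation test on group-blob bounding-box extrema
#'
#' For each of the 12 extremum statistics (minimum and maximum along the
#' mediolateral x, rostrocaudal y and dorsoventral z axes), the observed
#' statistic is the group-1 blob extremum minus the group-2 blob extremum
#' (mm, signed). The null is built from `n_perm` random relabelings
#' preserving the group sizes, recomputing both group blobs and their
#' extrema each time. Per-subject smoothed volumes are cached across
#' permutations (mathematically identical to re-smoothing). A permutation
#' yielding an empty blob is redrawn (bounded retries, reported via
#' `message`).
#'
#' @param masks List of `subject_mask` on one grid (one structure).
#' @param fraction Occurrence threshold defining the blobs.
#' @param smoothing_fwhm Per-subject Gaussian FWHM, mm.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed; results are fully deterministic given it.
#' @param labels Optional group labels (defaults to the masks'
#'   `conformation_type`); group 1 is the lower label value.
#' @param alternative Decision rule, see [permutation_result()].
#' @return Named list of 12 `permutation_result` objects
#'   (`x_min_diff`, ..., `z_max_diff`).
#' @export
extrema_permutation_test <- function(masks, fraction, smoothing_fwhm = 0,
                                     n_perm = 1000, seed = 1L,
                                     labels = NULL,
                                     alternative = "two.sided") {
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (is.null(labels)) labels <- conformation_labels(masks)
  stopifnot(length(labels) == length(masks))
  if (all(vapply(masks, inherits, logical(1), what = "subject_mask"))) {
    # canonical subject order, so results do not depend on input order
    ord <- order(vapply(masks, `[[`, character(1), "subject_id"),
                 vapply(masks, `[[`, character(1), "hemisphere"))
    masks <- masks[ord]
    labels <- labels[ord]
  }
  lev <- sort(unique(labels))
  if (length(lev) != 2L) stop("need exactly two group labels")
  g1 <- labels == lev[1]
  n1 <- sum(g1); n2 <- sum(!g1); n <- length(masks)
  if (n1 == 0L || n2 == 0L) stop("both groups must be nonempty")

  st <- stack_support(masks, smoothing_fwhm)
  V <- st$V; coords <- st$coords
  total <- rowSums(V)
  # a voxel whose values sum below fraction * min(n1, n2) cannot reach the
  # threshold in any subgroup of either size: drop it (exact pruning)
  keep <- total >= fraction * min(n1, n2) - 1e-12
  V <- V[keep, , drop = FALSE]
  coords <- coords[keep, , drop = FALSE]
  total <- total[keep]
  ext_of <- function(mean_vec) support_extrema(coords, mean_vec >= fraction)

  obs1 <- ext_of(rowSums(V[, g1, drop = FALSE]) / n1)
  obs2 <- ext_of(rowSums(V[, !g1, drop = FALSE]) / n2)
  if (is.null(obs1) || is.null(obs2))
    stop(sprintf("observed group blob empty at threshold %g", fraction))
  observed <- obs1 - obs2

  null_mat <- with_seed(seed, {
    out <- matrix(NA_real_, n_perm, 6)
    chunk <- 250L
    p <- 0L
    n_redraw <- 0L
    while (p < n_perm) {
      m <- min(chunk, n_perm - p)
      A <- matrix(0, n, m)
      for (j in seq_len(m)) A[sample(n, n1), j] <- 1
      S1 <- V %*% A
      G1 <- S1 / n1
      G2 <- (total - S1) / n2
      for (j in seq_len(m)) {
        e1 <- ext_of(G1[, j]); e2 <- ext_of(G2[, j])
        retries <- 0L
        while ((is.null(e1) || is.null(e2)) && retries < 100L) {
          n_redraw <- n_redraw + 1L
          retries <- retries + 1L
          a <- rep(0, n); a[sample(n, n1)] <- 1
          s1 <- drop(V %*% a)
          e1 <- ext_of(s1 / n1); e2 <- ext_of((total - s1) / n2)
        }
        if (is.null(e1) || is.null(e2))
          stop("permuted group blobs empty after 100 redraws")
        out[p + j, ] <- e1 - e2
      }
      p <- p + m
    }
    if (n_redraw > 0L)
      message(sprintf("extrema_permutation_test: redrew %d permutations with empty blobs", n_redraw))
    out
  })

  nms <- names(observed)
  res <- lapply(seq_along(nms), function(k)
    permutation_result(paste0(nms[k], "_diff"), observed[[k]],
                       null_mat[, k], seed = seed,
                       group_sizes = c(n1, n2), alternative = alternative))
  names(res) <- paste0(nms, "_diff")
  res
}

#' Permutation test on group centroid coordinates
#'
#' Tests the difference of group means of per-subject centroid coordinates
#' on one axis between two groups, with a relabeling null and the same
#' interval decision rule as the extrema test.
#'
#' @param centroids n x 3 matrix (or data.frame with columns x, y, z) of
#'   per-subject centroid world coordinates (mm).
#' @param labels Group labels (two levels); group 1 is the lower level.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param alternative Decision rule, see [permutation_result()].
#' @return A `permutation_result`.
#' @export
centroid_permutation_test <- function(centroids, labels,
                                      axis = c("x", "y", "z"),
                                      n_perm = 1000, seed = 1L,
                                      alternative = "two.sided") {
  axis <- match.arg(axis)
  if (is.data.frame(centroids)) centroids <- as.matrix(centroids[c("x", "y", "z")])
  colnames(centroids) <- c("x", "y", "z")
  v <- centroids[, axis]
  stopifnot(length(labels) == length(v))
  lev <- sort(unique(labels))
  if (length(lev) != 2L) stop("need exactly two group labels")
  g1 <- labels == lev[1]
  n1 <- sum(g1); n2 <- sum(!g1); n <- length(v)
  if (n1 == 0L || n2 == 0L) stop("both groups must be nonempty")
  observed <- mean(v[g1]) - mean(v[!g1])
  nulls <- with_seed(seed, {
    vapply(seq_len(n_perm), function(j) {
      idx <- sample(n, n1)
      mean(v[idx]) - mean(v[-idx])
    }, numeric(1))
  })
  permutation_result(paste0(axis, "_centroid_diff"), observed, nulls,
                     seed = seed, group_sizes = c(n1, n2),
                     alternative = alternative)
}

#' Paired comparison of two fitted line directions
#'
#' Pairs the three direction-vector components of two sign-canonicalized
#' line fits and applies a paired t-test (n = 3, df = 2). With only three
#' paired components this test has very low power and is insensitive to
#' symmetric component swaps; it is provided as the complementary
#' direction-variability analysis, not as a powerful detector.
#'
#' @param fit1,fit2 `line_fit` objects (unit, canonicalized directions).
#' @return A list with `method`, `statistic` (t), `df`, `p_value` and the
#'   component-wise `differences`.
#' @export
compare_directions <- function(fit1, fit2) {
  for (f in list(fit1, fit2)) {
    if (!inherits(f, "line_fit")) stop("inputs must be line_fit objects")
    if (abs(sqrt(sum(f$d^2)) - 1) > 1e-9) stop("non-unit direction vector")
  }
  diffs <- unname(fit1$d - fit2$d)
  m <- mean(diffs); s <- stats::sd(diffs)
  if (s == 0) {
    tstat <- if (m == 0) 0 else sign(m) * Inf
  } else {
    tstat <- m / (s / sqrt(3))
  }
  p <- if (is.infinite(tstat)) 0 else 2 * stats::pt(-abs(tstat), df = 2)
  list(method = "paired t-test on direction components",
       statistic = tstat, df = 2, p_value = p, differences = diffs)
}

#' Per-subject centroid table for a set of masks
#'
#' @param masks List of `subject_mask`.
#' @return data.frame with subject_id, hemisphere, structure,
#'   conformation_type and centroid x, y, z (mm).
#' @export
mask_centroids <- function(masks) {
  rows <- lapply(masks, function(m) {
    cm <- center_of_mass(m)
    data.frame(subject_id = m$subject_id, hemisphere = m$hemisphere,
               structure = m$structure,
               conformation_type = m$conformation_type,
               x = cm[["x"]], y = cm[["y"]], z = cm[["z"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
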