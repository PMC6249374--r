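# Synthetic cohort generation: tubular sulcal imprints rasterized onto a
# shared 1 mm grid, with the two rhinal/collateral conformation types
# (Type 1 = connected, Type 2 = separated), inter-subject jitter, optional
# systematic between-type shifts, and surrogate metadata/morphometry.

#' Create an empty grid volume
#'
#' @param shape Integer triple of voxel counts.
#' @param origin World-mm coordinate of voxel (0,0,0)'s center.
#' @param spacing Voxel size in mm (isotropic scalar or triple).
#' @return A `labeled_volume` of zeros.
#' @export
make_grid <- function(shape = c(80, 96, 72), origin = c(-40, -86, -50),
                      spacing = 1) {
  spacing <- rep(spacing, length.out = 3)
  aff <- diag(c(spacing, 1))
  aff[1:3, 4] <- origin
  labeled_volume(array(0, shape), aff)
}

#' Sulcus template: a tube around a 3D control polyline
#'
#' @param control_points n x 3 matrix (n >= 3) of world-mm points defining
#'   the curve.
#' @param tube_radius Tube radius, mm (> 0).
#' @param structure Structure label.
#' @param hemisphere `"L"` or `"R"`.
#' @return An object of class `sulcus_template`.
#' @export
sulcus_template <- function(control_points, tube_radius, structure,
                            hemisphere) {
  control_points <- as.matrix(control_points)
  if (nrow(control_points) < 3L) stop("need >= 3 control points")
  if (ncol(control_points) != 3L) stop("control points must be n x 3")
  if (tube_radius <= 0) stop("tube_radius must be > 0")
  structure(list(control_points = control_points, tube_radius = tube_radius,
                 structure = structure, hemisphere = hemisphere),
            class = "sulcus_template")
}

# densify a control polyline to steps of at most `step` mm
sample_polyline <- function(pts, step = 0.25) {
  out <- list(pts[1, , drop = FALSE])
  for (i in seq_len(nrow(pts) - 1L)) {
    a <- pts[i, ]; b <- pts[i + 1L, ]
    len <- sqrt(sum((b - a)^2))
    nseg <- max(1L, ceiling(len / step))
    tt <- seq_len(nseg) / nseg
    out[[i + 1L]] <- cbind(a[1] + tt * (b[1] - a[1]),
                           a[2] + tt * (b[2] - a[2]),
                           a[3] + tt * (b[3] - a[3]))
  }
  do.call(rbind, out)
}

#' Rasterize a tubular template onto a grid
#'
#' The voxel set is every voxel whose world center lies within
#' `tube_radius` of the template curve, with the curve distance evaluated
#' on a dense polyline sampling (step <= 0.25 mm). Each sampled curve
#' point's nearest voxel is always included, so even a sub-voxel radius
#' yields a connected rod.
#'
#' @param template A `sulcus_template`.
#' @param grid A `labeled_volume` defining shape and affine (values unused).
#' @return A binary `labeled_volume` on `grid`'s geometry.
#' @export
rasterize_tube <- function(template, grid) {
  samples <- sample_polyline(template$control_points)
  r <- template$tube_radius
  dims <- dim(grid$data)
  lo_idx <- floor(world_to_voxel(grid, apply(samples, 2, min) - r))
  hi_idx <- ceiling(world_to_voxel(grid, apply(samples, 2, max) + r))
  if (any(hi_idx < 0) || any(lo_idx > dims - 1L))
    stop("curve lies outside the grid")
  if (any(lo_idx < 0) || any(hi_idx > dims - 1L))
    stop("curve (dilated by tube_radius) leaves the grid")
  rng <- lapply(1:3, function(k) lo_idx[k]:hi_idx[k])
  cand <- as.matrix(expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]]))
  centers <- voxel_to_world(grid, cand)
  d2min <- min_sqdist_to_points(centers, samples)
  keep <- cand[d2min <= r^2 + 1e-12, , drop = FALSE]
  nearest <- round(world_to_voxel(grid, samples))   # nearest-voxel guarantee
  keep <- unique(rbind(keep, nearest))
  arr <- array(0, dims)
  arr[keep + 1L] <- 1
  labeled_volume(arr, grid$affine)
}

# ellipsoid blob for compact cortical / hippocampal structures
rasterize_ellipsoid <- function(center, radii, grid) {
  dims <- dim(grid$data)
  lo_idx <- pmax(0, floor(world_to_voxel(grid, center - radii)))
  hi_idx <- pmin(dims - 1L, ceiling(world_to_voxel(grid, center + radii)))
  if (any(hi_idx < lo_idx)) stop("ellipsoid lies outside the grid")
  rng <- lapply(1:3, function(k) lo_idx[k]:hi_idx[k])
  cand <- as.matrix(expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]]))
  centers <- voxel_to_world(grid, cand)
  u <- sweep(sweep(centers, 2, center), 2, radii, "/")
  keep <- cand[rowSums(u^2) <= 1, , drop = FALSE]
  arr <- array(0, dims)
  arr[keep + 1L] <- 1
  labeled_volume(arr, grid$affine)
}

# 26-connected components of a binary volume's voxel set
component_count <- function(volume) {
  idx <- which(volume$data != 0, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0L) return(0L)
  dims <- dim(volume$data)
  key <- function(m) m[, 1] + dims[1] * (m[, 2] + dims[2] * m[, 3])
  keys <- key(idx)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
               (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), ,
               drop = FALSE]   # positive half of the 26-neighbourhood
  edges <- list()
  for (o in seq_len(nrow(offs))) {
    sh <- sweep(idx, 2, -offs[o, ])
    inb <- sh[, 1] >= 1 & sh[, 1] <= dims[1] &
           sh[, 2] >= 1 & sh[, 2] <= dims[2] &
           sh[, 3] >= 1 & sh[, 3] <= dims[3]
    m <- match(key(sh[inb, , drop = FALSE]), keys)
    hit <- which(!is.na(m))
    if (length(hit))
      edges[[length(edges) + 1L]] <- cbind(which(inb)[hit], m[hit])
  }
  if (!length(edges)) return(n)
  g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::components(g)$no
}

#' Count 26-connected components of a binary mask
#' @param x A `subject_mask` or binary `labeled_volume`.
#' @return Integer component count.
#' @export
count_components <- function(x) {
  if (inherits(x, "subject_mask")) x <- x$volume
  component_count(x)
}

#' Classify the rhinal/collateral conformation of one hemisphere
#'
#' Returns Type 1 when the union of the rhinal sulcus and collateral
#' sulcus proper voxel sets forms a single 26-connected component
#' (connected conformation), else Type 2 (separated).
#'
#' @param rs,cs_proper `subject_mask` objects on the same grid.
#' @return 1L or 2L.
#' @export
classify_conformation <- function(rs, cs_proper) {
  va <- if (inherits(rs, "subject_mask")) rs$volume else rs
  vb <- if (inherits(cs_proper, "subject_mask")) cs_proper$volume else cs_proper
  if (!same_grid(va, vb)) stop("masks are on mismatched grids")
  uni <- labeled_volume(pmin(va$data + vb$data, 1), va$affine)
  if (component_count(uni) == 1L) 1L else 2L
}

# min squared distance from each row of `a` to the point set `b` (both
# n x 3), via the ||a||^2 + ||b||^2 - 2 a.b expansion (BLAS crossproduct)
min_sqdist_to_points <- function(a, b) {
  d2 <- -2 * a %*% t(b)
  d2 <- sweep(d2, 2, rowSums(b^2), "+") + rowSums(a^2)
  pmax(d2[cbind(seq_len(nrow(a)), max.col(-d2, ties.method = "first"))], 0)
}

# minimum distance between the voxel-center sets of two binary volumes
min_voxel_distance <- function(va, vb) {
  a <- nonzero_world_coords(va); b <- nonzero_world_coords(vb)
  if (nrow(a) == 0L || nrow(b) == 0L) return(Inf)
  sqrt(min(min_sqdist_to_points(a, b)))
}

# Base right-hemisphere sulcal control points (world mm). The rhinal sulcus
# runs rostral-medial; the collateral sulcus proper caudal-lateral; the
# collateral sulcus post caudal to the transition plane. Left hemisphere
# mirrors x. The rostral end of CS proper sits ~10 mm from the caudal end
# of RS, so the separated (Type 2) conformation holds under moderate jitter
# and Type 1 is realized by bridging the two endpoints.
base_control_points <- function(structure) {
  switch(structure,
    RS = rbind(c(20, -2, -24), c(21, -10, -27), c(22, -18, -30),
               c(23, -26, -32)),
    CSproper = rbind(c(26, -17, -28), c(27, -30, -32), c(28, -40, -34),
                     c(28, -48, -35)),
    CSpost = rbind(c(27, -54, -31), c(27, -60, -26), c(26, -66, -21),
                   c(25, -70, -18)),
    stop("no tubular template for structure ", structure))
}

base_ellipsoid <- function(structure) {
  switch(structure,
    ERC = list(center = c(17, -10, -28), radii = c(4, 8, 5)),
    HH  = list(center = c(24, -12, -16), radii = c(6, 7, 6)),
    HB  = list(center = c(28, -28, -12), radii = c(5, 8, 5)),
    stop("no ellipsoid template for structure ", structure))
}

mirror_x <- function(pts) {
  if (is.matrix(pts)) cbind(-pts[, 1], pts[, 2:3]) else c(-pts[1], pts[2:3])
}

#' Synthetic cohort configuration
#'
#' Defaults define the reference simulation conditions: 38 subjects aged
#' 7-17 with balanced sexes, both hemispheres, Type-1 probability 0.38 with
#' inter-hemispheric concordance 0.71, 1.5 mm positional jitter, and
#' depth surrogates whose per-type distributions mirror the reported
#' morphometry (deeper right rhinal sulcus in the connected type).
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param p_type1 Probability a hemisphere is Type 1 (connected).
#' @param balanced_types If `TRUE`, assign exactly `round(n * p_type1)`
#'   Type-1 hemispheres per hemisphere label instead of sampling.
#' @param concordance Probability the second hemisphere copies the
#'   subject's first-hemisphere type (drives the inter-hemispheric phi).
#' @param jitter_sd SD (mm per axis) of the rigid per-structure translation
#'   applied per subject.
#' @param cp_noise_sd SD (mm) of additional per-control-point noise.
#' @param type_shift mm triple added to Type-2 hemispheres' sulcal
#'   templates (systematic between-type location offset; default zero).
#' @param type_affects_geometry If `FALSE`, all hemispheres are built from
#'   the separated template regardless of their assigned type, making the
#'   conformation type a pure label on exchangeable geometry (apart from
#'   any `type_shift`). Used for null-calibration and power simulations.
#' @param connection_gap Minimum voxel-center distance (mm) required
#'   between RS and CS proper in Type-2 hemispheres.
#' @param bridge_radius Radius (mm) of the Type-1 connecting segment.
#' @param tube_radius Sulcal tube radius, mm.
#' @param depth_params Per-sulcus, per-type normal parameters for the
#'   morphometry surrogates (see defaults for the structure).
#' @param age_range Ages are drawn uniformly on this range (years).
#' @param hemispheres Hemispheres to generate (`c("L","R")` or one).
#' @param structures Structures to generate; tubular sulci plus optionally
#'   compact blobs (`ERC`, `HH`, `HB`).
#' @param grid_shape,grid_origin Grid geometry (1 mm isotropic).
#' @param edge_margin_mm Required distance from any mask voxel to the grid
#'   edge (re-jitter when violated; keeps later smoothing mass-conserving).
#' @param max_retries Retry bound for jitter rejection.
#' @param seed Integer seed; the generator is deterministic given it.
#' @return A validated config list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 38,
                          p_type1 = 0.38,
                          balanced_types = FALSE,
                          concordance = 0.71,
                          jitter_sd = 1.5,
                          cp_noise_sd = 0.3,
                          type_shift = c(0, 0, 0),
                          type_affects_geometry = TRUE,
                          connection_gap = 3,
                          bridge_radius = 1.5,
                          tube_radius = 2,
                          depth_params = default_depth_params(),
                          age_range = c(7, 17),
                          hemispheres = c("L", "R"),
                          structures = c("RS", "CSproper", "CSpost"),
                          grid_shape = c(80, 96, 72),
                          grid_origin = c(-40, -86, -50),
                          edge_margin_mm = 7,
                          max_retries = 25L,
                          seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects), p_type1 = p_type1,
              balanced_types = isTRUE(balanced_types),
              concordance = concordance, jitter_sd = jitter_sd,
              cp_noise_sd = cp_noise_sd, type_shift = type_shift,
              type_affects_geometry = isTRUE(type_affects_geometry),
              connection_gap = connection_gap,
              bridge_radius = bridge_radius, tube_radius = tube_radius,
              depth_params = depth_params, age_range = age_range,
              hemispheres = match.arg(hemispheres, c("L", "R"),
                                      several.ok = TRUE),
              structures = structures, grid_shape = grid_shape,
              grid_origin = grid_origin, edge_margin_mm = edge_margin_mm,
              max_retries = as.integer(max_retries),
              seed = as.integer(seed))
  if (cfg$n_subjects < 2L) stop("n_subjects must be >= 2")
  if (cfg$jitter_sd < 0) stop("jitter_sd must be >= 0")
  if (cfg$connection_gap <= 0) stop("connection_gap must be > 0")
  if (cfg$p_type1 < 0 || cfg$p_type1 > 1) stop("p_type1 must be in [0,1]")
  if (length(cfg$type_shift) != 3L) stop("type_shift must be a mm triple")
  class(cfg) <- "cohort_config"
  cfg
}

#' Default per-type morphometry surrogate parameters
#'
#' Normal (mean, sd) in mm for maximum depth and mean depth per sulcus and
#' conformation type (connected sulci slightly deeper), plus a per-sulcus
#' length distribution shared by both types.
#' @return Nested list keyed by sulcus.
#' @export
default_depth_params <- function() {
  list(
    RS = list(max = list("1" = c(16.2, 2.4), "2" = c(13.6, 2.5)),
              mean = list("1" = c(10.4, 1.2), "2" = c(8.1, 1.3)),
              length = c(35, 4)),
    CSproper = list(max = list("1" = c(16.9, 1.9), "2" = c(16.4, 2.2)),
                    mean = list("1" = c(12.4, 2.2), "2" = c(11.0, 2.2)),
                    length = c(45, 5)),
    CSpost = list(max = list("1" = c(16.4, 1.6), "2" = c(16.4, 1.8)),
                  mean = list("1" = c(11.2, 1.4), "2" = c(10.7, 1.1)),
                  length = c(40, 5)))
}

# rigid per-structure translation + per-control-point noise
jitter_points <- function(pts, jitter_sd, cp_noise_sd) {
  shift <- stats::rnorm(3, 0, jitter_sd)
  pts <- sweep(pts, 2, -shift)
  if (cp_noise_sd > 0)
    pts <- pts + matrix(stats::rnorm(length(pts), 0, cp_noise_sd),
                        nrow(pts), 3)
  pts
}

within_margin <- function(volume, margin_mm) {
  xyz <- nonzero_world_coords(volume)
  bb_lo <- voxel_to_world(volume, c(0, 0, 0))
  bb_hi <- voxel_to_world(volume, dim(volume$data) - 1L)
  all(apply(xyz, 2, min) >= bb_lo + margin_mm) &&
    all(apply(xyz, 2, max) <= bb_hi - margin_mm)
}

# NULL when the error is a retryable jitter/grid constraint, else rethrow
raster_or_null <- function(expr) {
  tryCatch(expr, error = function(e) {
    if (grepl("leaves the grid|outside the grid", conditionMessage(e)))
      NULL
    else stop(e)
  })
}

# generate the sulcal masks of one hemisphere of one subject; returns NULL
# when a jitter draw violates the grid-margin or separation constraints
generate_hemisphere_masks <- function(cfg, grid, hemisphere, type) {
  sulci <- intersect(cfg$structures, SULCI)
  pts <- lapply(sulci, base_control_points)
  names(pts) <- sulci
  if (hemisphere == "L") pts <- lapply(pts, mirror_x)
  if (type == 2L)
    pts <- lapply(pts, function(p) sweep(p, 2, -cfg$type_shift))
  pts <- lapply(pts, jitter_points, jitter_sd = cfg$jitter_sd,
                cp_noise_sd = cfg$cp_noise_sd)
  # with type_affects_geometry = FALSE the conformation type is a pure
  # label on exchangeable geometry (all hemispheres separated): the
  # configuration for null-calibration and pure-shift simulations
  geom_type <- if (cfg$type_affects_geometry) type else 2L
  vols <- raster_or_null({
    if (geom_type == 1L && all(c("RS", "CSproper") %in% sulci)) {
      # connected conformation: the rhinal sulcus extends caudally to meet
      # the rostral end of the collateral sulcus proper
      bridge <- rbind(pts$RS[nrow(pts$RS), ],
                      (pts$RS[nrow(pts$RS), ] + pts$CSproper[1, ]) / 2,
                      pts$CSproper[1, ])
      vols <- list()
      for (s in sulci) {
        vols[[s]] <- rasterize_tube(
          sulcus_template(pts[[s]], cfg$tube_radius, s, hemisphere), grid)
      }
      bridge_vol <- rasterize_tube(
        sulcus_template(bridge, cfg$bridge_radius, "RS", hemisphere), grid)
      vols$RS <- labeled_volume(pmin(vols$RS$data + bridge_vol$data, 1),
                                grid$affine)
    } else {
      vols <- lapply(sulci, function(s)
        rasterize_tube(sulcus_template(pts[[s]], cfg$tube_radius, s,
                                       hemisphere), grid))
      names(vols) <- sulci
    }
    blobs <- intersect(cfg$structures, setdiff(STRUCTURES, SULCI))
    for (s in blobs) {
      e <- base_ellipsoid(s)
      ctr <- if (hemisphere == "L") mirror_x(e$center) else e$center
      ctr <- ctr + stats::rnorm(3, 0, cfg$jitter_sd)
      vols[[s]] <- rasterize_ellipsoid(ctr, e$radii, grid)
    }
    vols
  })
  if (is.null(vols)) return(NULL)
  for (v in vols) if (!within_margin(v, cfg$edge_margin_mm)) return(NULL)
  if (geom_type == 2L && all(c("RS", "CSproper") %in% sulci) &&
      min_voxel_distance(vols$RS, vols$CSproper) < cfg$connection_gap)
    return(NULL)
  vols
}

draw_types <- function(cfg) {
  n <- cfg$n_subjects
  hemis <- cfg$hemispheres
  types <- matrix(NA_integer_, n, length(hemis),
                  dimnames = list(NULL, hemis))
  if (cfg$balanced_types) {
    n1 <- round(n * cfg$p_type1)
    for (h in seq_along(hemis))
      types[, h] <- sample(rep(c(1L, 2L), c(n1, n - n1)))
    return(types)
  }
  base <- ifelse(stats::runif(n) < cfg$p_type1, 1L, 2L)
  types[, 1] <- base
  if (length(hemis) == 2L) {
    copy <- stats::runif(n) < cfg$concordance
    redraw <- ifelse(stats::runif(n) < cfg$p_type1, 1L, 2L)
    types[, 2] <- ifelse(copy, base, redraw)
  }
  types
}

truncnorm_pos <- function(n, mean, sd, lower = 0.1) {
  pmax(stats::rnorm(n, mean, sd), lower)
}

#' Generate a synthetic cohort of masks, metadata and morphometry
#'
#' Deterministic given `config$seed`. Every subject x hemisphere gets one
#' binary mask per configured structure on the shared grid; Type-1
#' hemispheres have a 26-connected RS-union-CSproper voxel set, Type-2
#' hemispheres keep the two sulci at least `connection_gap` mm apart.
#' Ages are uniform on `age_range`, sexes balanced, and the morphometry
#' surrogates follow the configured per-type depth distributions.
#'
#' @param config A `cohort_config`.
#' @return A list with `masks` (list of `subject_mask`), `cohort`
#'   (data.frame), `morphometry` (data.frame), and `grid`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(config$seed)

  grid <- make_grid(config$grid_shape, config$grid_origin)
  n <- config$n_subjects
  ids <- sprintf("S%03d", seq_len(n))
  types <- draw_types(config)
  ages <- round(stats::runif(n, config$age_range[1], config$age_range[2]), 1)
  sexes <- sample(rep(c("F", "M"), length.out = n))

  masks <- list()
  cohort <- list()
  morpho <- list()
  for (i in seq_len(n)) {
    for (h in config$hemispheres) {
      type <- types[i, h]
      vols <- NULL
      for (try in seq_len(config$max_retries)) {
        vols <- generate_hemisphere_masks(config, grid, h, type)
        if (!is.null(vols)) break
      }
      if (is.null(vols))
        stop(sprintf("subject %s hemisphere %s: jitter constraints not met after %d retries",
                     ids[i], h, config$max_retries))
      for (s in names(vols)) {
        masks[[length(masks) + 1L]] <-
          subject_mask(ids[i], h, s, vols[[s]],
                       if (s %in% SULCI) type else NA_integer_)
      }
      cohort[[length(cohort) + 1L]] <- data.frame(
        subject_id = ids[i], age = ages[i], sex = sexes[i], hemisphere = h,
        hemisphere_volume = round(stats::rnorm(1, 5.5e5, 4.5e4)),
        hemisphere_surface = round(stats::rnorm(1, 9.0e4, 8.0e3)),
        conformation_type = type, stringsAsFactors = FALSE)
      for (s in intersect(names(vols), SULCI)) {
        dp <- config$depth_params[[s]]
        tkey <- as.character(type)
        maxd <- truncnorm_pos(1, dp$max[[tkey]][1], dp$max[[tkey]][2])
        meand <- min(truncnorm_pos(1, dp$mean[[tkey]][1], dp$mean[[tkey]][2]),
                     0.95 * maxd)
        morpho[[length(morpho) + 1L]] <- data.frame(
          subject_id = ids[i], hemisphere = h, sulcus = s,
          max_depth = round(maxd, 2), mean_depth = round(meand, 2),
          length = round(truncnorm_pos(1, dp$length[1], dp$length[2]), 2),
          conformation_type = type, stringsAsFactors = FALSE)
      }
    }
  }
  list(masks = masks,
       cohort = do.call(rbind, cohort),
       morphometry = do.call(rbind, morpho),
       grid = grid)
}

#' Select masks of one structure (and optionally hemisphere) from a cohort
#' @param masks List of `subject_mask`.
#' @param structure Structure label.
#' @param hemisphere Optional hemisphere filter.
#' @return Filtered list of `subject_mask`.
#' @export
select_masks <- function(masks, structure, hemisphere = NULL) {
  keep <- vapply(masks, function(m) {
    m$structure == structure &&
      (is.null(hemisphere) || m$hemisphere == hemisphere)
  }, logical(1))
  masks[keep]
}
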