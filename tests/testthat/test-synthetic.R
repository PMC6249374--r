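test_that("rasterize_tube matches a brute-force distance scan", {
  set.seed(21)
  grid <- make_grid(c(26, 26, 26), c(-13, -13, -13))
  for (i in 1:6) {
    p0 <- runif(3, -1, 1)
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    cps <- rbind(p0, p0 + 5 * dir + rnorm(3, sd = 0.5), p0 + 10 * dir)
    r <- runif(1, 0.8, 2)
    tpl <- sulcus_template(cps, r, "RS", "R")
    vol <- rasterize_tube(tpl, grid)

    # oracle: exhaustive distance evaluation of every grid voxel against a
    # very fine polyline sampling
    fine <- mtlatlas:::sample_polyline(cps, step = 0.02)
    all_idx <- as.matrix(expand.grid(0:25, 0:25, 0:25))
    centers <- voxel_to_world(grid, all_idx)
    d2 <- mtlatlas:::min_sqdist_to_points(centers, fine)
    inside <- d2 <= r^2
    got <- vol$data[all_idx + 1L] != 0
    # sampling at 0.25 mm bounds the curve-distance error by 0.125 mm;
    # ignore voxels within that band of the boundary
    boundary <- abs(sqrt(d2) - r) < 0.13
    expect_identical(got[!boundary], inside[!boundary])
  }
})

test_that("a 10 mm straight rod of radius 1 mm has the brute-force voxel count", {
  grid <- make_grid(c(16, 16, 16), c(-3, -6, -6))
  cps <- rbind(c(0, 0, 0), c(5, 0, 0), c(10, 0, 0))
  vol <- rasterize_tube(sulcus_template(cps, 1, "RS", "R"), grid)
  all_idx <- as.matrix(expand.grid(0:15, 0:15, 0:15))
  centers <- voxel_to_world(grid, all_idx)
  seg <- cbind(seq(0, 10, by = 0.01), 0, 0)
  d2 <- mtlatlas:::min_sqdist_to_points(centers, seg)
  expect_equal(sum(vol$data), sum(d2 <= 1 + 1e-12))
  expect_equal(count_components(vol), 1L)
})

test_that("sub-voxel radius still rasterizes a connected rod", {
  grid <- make_grid(c(16, 16, 16), c(0, 0, 0))
  cps <- rbind(c(3, 3, 3), c(7, 6, 5), c(11, 9, 8))
  vol <- rasterize_tube(sulcus_template(cps, 0.2, "RS", "R"), grid)
  expect_gte(sum(vol$data), 1)
  expect_equal(count_components(vol), 1L)
})

test_that("disjoint templates rasterize to disjoint voxel sets", {
  grid <- make_grid(c(24, 24, 24), c(0, 0, 0))
  a <- rasterize_tube(sulcus_template(rbind(c(4, 4, 4), c(8, 4, 4), c(12, 4, 4)),
                                      1, "RS", "R"), grid)
  b <- rasterize_tube(sulcus_template(rbind(c(4, 10, 4), c(8, 10, 4), c(12, 10, 4)),
                                      1, "CSproper", "R"), grid)
  expect_equal(sum(a$data * b$data), 0)
})

test_that("generation is deterministic given the seed", {
  cfg <- sim_rs_config(seed = 5, n_subjects = 4)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$morphometry, b$morphometry)
  expect_identical(lapply(a$masks, function(m) m$volume$data),
                   lapply(b$masks, function(m) m$volume$data))
})

test_that("conformation classification matches construction for both pure types", {
  cfg1 <- cohort_config(n_subjects = 3, p_type1 = 1, seed = 7,
                        hemispheres = "R")
  sim1 <- generate_cohort(cfg1)
  for (id in unique(sim1$cohort$subject_id)) {
    rs <- select_masks(sim1$masks, "RS", "R")
    rs <- rs[[which(vapply(rs, `[[`, character(1), "subject_id") == id)]]
    cs <- select_masks(sim1$masks, "CSproper", "R")
    cs <- cs[[which(vapply(cs, `[[`, character(1), "subject_id") == id)]]
    uni <- labeled_volume(pmin(rs$volume$data + cs$volume$data, 1),
                          rs$volume$affine)
    expect_equal(count_components(uni), 1L)
    expect_equal(classify_conformation(rs, cs), 1L)
  }

  cfg2 <- cohort_config(n_subjects = 3, p_type1 = 0, seed = 8,
                        hemispheres = "R")
  sim2 <- generate_cohort(cfg2)
  for (id in unique(sim2$cohort$subject_id)) {
    rs <- select_masks(sim2$masks, "RS", "R")
    rs <- rs[[which(vapply(rs, `[[`, character(1), "subject_id") == id)]]
    cs <- select_masks(sim2$masks, "CSproper", "R")
    cs <- cs[[which(vapply(cs, `[[`, character(1), "subject_id") == id)]]
    expect_gte(mtlatlas:::min_voxel_distance(rs$volume, cs$volume),
               cfg2$connection_gap)
    expect_equal(classify_conformation(rs, cs), 2L)
  }
})

test_that("classifier recovers the generator's type on a mixed cohort", {
  cfg <- cohort_config(n_subjects = 5, p_type1 = 0.5, seed = 9)
  sim <- generate_cohort(cfg)
  for (h in c("L", "R")) {
    rs_all <- select_masks(sim$masks, "RS", h)
    cs_all <- select_masks(sim$masks, "CSproper", h)
    for (k in seq_along(rs_all)) {
      expect_equal(classify_conformation(rs_all[[k]], cs_all[[k]]),
                   rs_all[[k]]$conformation_type)
    }
  }
})

test_that("touching and separated voxel pairs classify as types 1 and 2", {
  a <- mask_from_voxels(c(3, 3, 3), structure = "RS")
  b <- mask_from_voxels(c(4, 3, 3), structure = "CSproper")
  expect_equal(classify_conformation(a, b), 1L)
  b2 <- mask_from_voxels(c(7, 3, 3), structure = "CSproper")
  expect_equal(classify_conformation(a, b2), 2L)
  off <- mask_from_voxels(c(4, 3, 3), shape = c(11, 10, 10),
                          structure = "CSproper")
  expect_error(classify_conformation(a, off), "mismatched grids")
})

test_that("a systematic type shift moves mean centroids by the shift", {
  base <- sim_rs_config(seed = 31, n_subjects = 10, jitter_sd = 0,
                        cp_noise_sd = 0, type_shift = c(0, 6, 0),
                        type_affects_geometry = FALSE)
  sim <- generate_cohort(base)
  cent <- mask_centroids(sim$masks)
  d <- colMeans(cent[cent$conformation_type == 2L, c("x", "y", "z")]) -
       colMeans(cent[cent$conformation_type == 1L, c("x", "y", "z")])
  # shift commutes with rasterization up to < 0.5 voxel discretization
  expect_lt(abs(d[["y"]] - 6), 0.5)
  expect_lt(abs(d[["x"]]), 0.5)
  expect_lt(abs(d[["z"]]), 0.5)
})

test_that("without a type shift, group centroid means agree within 3 SE", {
  cfg <- sim_rs_config(seed = 33, n_subjects = 200, type_shift = c(0, 0, 0),
                       type_affects_geometry = FALSE)
  sim <- generate_cohort(cfg)
  cent <- mask_centroids(sim$masks)
  for (ax in c("x", "y", "z")) {
    v1 <- cent[[ax]][cent$conformation_type == 1L]
    v2 <- cent[[ax]][cent$conformation_type == 2L]
    se <- sqrt(stats::var(v1) / length(v1) + stats::var(v2) / length(v2))
    expect_lt(abs(mean(v1) - mean(v2)), 3 * se)
  }
})

test_that("cohort metadata follows the configured distributions", {
  cfg <- cohort_config(n_subjects = 20, seed = 13, hemispheres = "R",
                       structures = "RS")
  sim <- generate_cohort(cfg)
  expect_equal(nrow(sim$cohort), 20)
  expect_true(all(sim$cohort$age >= 7 & sim$cohort$age <= 17))
  expect_equal(sum(sim$cohort$sex == "F"), 10)
  expect_true(all(sim$morphometry$mean_depth <= sim$morphometry$max_depth))
  expect_true(all(sim$morphometry$max_depth > 0))
})
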