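# a 41-value null whose type-7 2.5th/97.5th centiles are exactly -2 and 3
null_with_interval <- function(lower = -2, upper = 3) {
  c(lower - 0.5, lower, seq(lower + 0.1, upper - 0.1, length.out = 37),
    upper, upper + 0.5)
}

test_that("the interval decision rule flags only values outside the null band", {
  nv <- null_with_interval(-2, 3)
  expect_equal(unname(stats::quantile(nv, c(0.025, 0.975))), c(-2, 3))

  res <- permutation_result("x_max_diff", observed = -5, null_values = nv)
  expect_equal(res$interval, c(-2, 3))
  expect_true(res$significant)

  expect_false(permutation_result("s", 0, nv)$significant)
  expect_false(permutation_result("s", -2, nv)$significant)  # boundary: inside
  expect_false(permutation_result("s", 3, nv)$significant)
  expect_true(permutation_result("s", 3.5, nv)$significant)

  expect_true(decide_significance(-5, c(-2, 3)))
  expect_false(decide_significance(2.9, c(-2, 3)))

  one_sided <- permutation_result("s", 4, nv, alternative = "greater")
  expect_true(one_sided$significant)
  expect_false(permutation_result("s", -5, nv,
                                  alternative = "greater")$significant)
})

test_that("group_blob reduces to the masks for degenerate groups", {
  m <- mask_from_voxels(rbind(c(2, 2, 2), c(3, 2, 2)))
  b <- group_blob(list(m), fraction = 0.05)
  expect_identical(blob_to_volume(b)$data != 0, m$volume$data != 0)

  m2 <- mask_from_voxels(c(7, 7, 7), subject_id = "S002")
  b2 <- group_blob(list(m, m2), fraction = 0.05)
  expect_equal(nrow(b2$voxel_indices), 3)   # union: each voxel at 0.5 >= 0.05

  b3 <- group_blob(rep(list(m), 4), fraction = 0.6)
  expect_identical(blob_to_volume(b3)$data != 0, m$volume$data != 0)
})

test_that("identical group multisets give zero observed differences", {
  set.seed(63)
  masks <- lapply(1:6, function(i)
    mask_from_voxels(arrayInd(sample(1000, 20), c(10, 10, 10)) - 1L,
                     subject_id = sprintf("S%03d", i)))
  both <- c(masks, masks)
  labels <- rep(c(1, 2), each = 6)
  res <- extrema_permutation_test(both, fraction = 0.1, n_perm = 100,
                                  seed = 3, labels = labels)
  expect_length(res, 6)
  for (r in res) {
    expect_equal(r$observed, 0)
    expect_false(r$significant)
    expect_equal(r$group_sizes, c(6, 6))
    expect_equal(r$n_perm, 100)
  }
})

test_that("results are deterministic and invariant to mask input order", {
  cfg <- sim_rs_config(seed = 65, n_subjects = 12,
                       type_affects_geometry = FALSE)
  sim <- generate_cohort(cfg)
  labs <- sim$cohort$conformation_type
  run <- function(masks, labels)
    extrema_permutation_test(masks, fraction = 0.05, smoothing_fwhm = 3,
                             n_perm = 100, seed = 17, labels = labels)
  r1 <- run(sim$masks, labs)
  r2 <- run(sim$masks, labs)
  expect_identical(lapply(r1, `[[`, "null_values"),
                   lapply(r2, `[[`, "null_values"))

  perm <- sample(length(sim$masks))
  r3 <- run(sim$masks[perm], labs[perm])
  expect_equal(vapply(r1, `[[`, numeric(1), "observed"),
               vapply(r3, `[[`, numeric(1), "observed"))
  expect_identical(lapply(r1, `[[`, "null_values"),
                   lapply(r3, `[[`, "null_values"))
})

test_that("centroid tests detect a dominant deterministic shift", {
  set.seed(67)
  a <- matrix(rnorm(30, sd = 0.01), 10)
  b <- a; b[, 2] <- b[, 2] + 10
  centroids <- rbind(a, b)
  labels <- rep(c(1, 2), each = 10)
  res <- centroid_permutation_test(centroids, labels, axis = "y",
                                   n_perm = 200, seed = 5)
  expect_equal(res$observed, -10, tolerance = 0.01)
  expect_true(res$significant)

  same <- centroid_permutation_test(rbind(a, a), labels, axis = "y",
                                    n_perm = 200, seed = 5)
  expect_equal(same$observed, 0, tolerance = 1e-12)
  expect_false(same$significant)

  x_axis <- centroid_permutation_test(centroids, labels, axis = "x",
                                      n_perm = 200, seed = 5)
  expect_false(x_axis$significant)
})

test_that("direction comparison reduces to the closed-form paired t on 3 values", {
  mk_fit <- function(d) {
    d <- d / sqrt(sum(d^2))
    structure(list(p0 = c(0, 0, 0), d = stats::setNames(d, c("x", "y", "z")),
                   t_values = numeric(0), rss = 0,
                   degenerate_direction = FALSE), class = "line_fit")
  }
  ident <- compare_directions(mk_fit(c(1, 0, 0)), mk_fit(c(1, 0, 0)))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)

  # symmetric swap: differences (1, -1, 0) have mean 0 -> t = 0, p = 1
  swap <- compare_directions(mk_fit(c(1, 0, 0)), mk_fit(c(0, 1, 0)))
  expect_equal(swap$differences, c(1, -1, 0))
  expect_equal(swap$statistic, 0)
  expect_equal(swap$p_value, 1)

  gen <- compare_directions(mk_fit(c(1, 0, 0)), mk_fit(c(0.8, 0.6, 0)))
  diffs <- c(1, 0, 0) - c(0.8, 0.6, 0)
  t_oracle <- mean(diffs) / (stats::sd(diffs) / sqrt(3))
  expect_equal(gen$statistic, t_oracle, tolerance = 1e-12)
  expect_equal(gen$p_value, 2 * stats::pt(-abs(t_oracle), 2),
               tolerance = 1e-12)
  expect_equal(gen$df, 2)

  bad <- mk_fit(c(1, 0, 0)); bad$d <- bad$d * 2
  expect_error(compare_directions(bad, mk_fit(c(1, 0, 0))), "non-unit")
})
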