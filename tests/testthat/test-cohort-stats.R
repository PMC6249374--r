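test_that("type-proportion summaries reproduce the printed cohort percentages", {
  cohort <- data.frame(conformation_type = rep(c(1L, 2L), c(29, 47)))
  s <- summarize_types(cohort)
  expect_equal(s$n_hemispheres, 76)
  expect_equal(s$n_type1, 29)
  expect_equal(s$n_type2, 47)
  expect_equal(s$pct_type1, 38.15)
  expect_equal(s$pct_type2, 61.85)
  expect_equal(s$prop_type1, 29 / 76)

  none <- summarize_types(data.frame(conformation_type = rep(2L, 10)))
  expect_equal(none$pct_type1, 0)
  expect_equal(none$pct_type2, 100)

  expect_error(summarize_types(data.frame(conformation_type = c(1L, 3L))),
               "unknown conformation types")
})

test_that("one-sample proportion z matches the closed form", {
  null_eq <- proportion_test(30, 100, 0.3)
  expect_equal(null_eq$statistic, 0)
  expect_equal(null_eq$p_value, 1)

  zt <- proportion_test(29, 76, 0.28)
  p1 <- 29 / 76
  z_oracle <- (p1 - 0.28) / sqrt(p1 * (1 - p1) / 76)
  expect_equal(zt$statistic, z_oracle, tolerance = 1e-12)
  expect_equal(zt$statistic, 1.8229, tolerance = 1e-4)
  expect_equal(zt$p_value, 2 * stats::pnorm(-abs(z_oracle)), tolerance = 1e-12)
  expect_equal(zt$p_value, 0.0683, tolerance = 1e-3)

  znull <- proportion_test(29, 76, 0.28, variance = "null")
  expect_equal(znull$statistic,
               (p1 - 0.28) / sqrt(0.28 * 0.72 / 76), tolerance = 1e-12)
  expect_error(proportion_test(0, 10, 0.5), "variance")
  expect_silent(proportion_test(0, 10, 0.5, variance = "null"))
})

test_that("two-sample proportion z uses the pooled variance and is antisymmetric", {
  zt <- proportion_test(29, 76, c(18, 50))
  pp <- (29 + 18) / (76 + 50)
  z_oracle <- (29 / 76 - 18 / 50) / sqrt(pp * (1 - pp) * (1 / 76 + 1 / 50))
  expect_equal(zt$statistic, z_oracle, tolerance = 1e-12)
  expect_equal(zt$statistic, 0.2450, tolerance = 1e-3)

  swapped <- proportion_test(18, 50, c(29, 76))
  expect_equal(swapped$statistic, -zt$statistic, tolerance = 1e-12)
  expect_equal(swapped$p_value, zt$p_value, tolerance = 1e-12)
})

test_that("group t-tests match the pooled closed form and flag by BH", {
  tab <- data.frame(conformation_type = rep(c(1L, 2L), each = 3),
                    v = c(1, 2, 3, 4, 5, 6))
  res <- group_ttests(tab, columns = "v")
  sp2 <- (2 * stats::var(c(1, 2, 3)) + 2 * stats::var(c(4, 5, 6))) / 4
  t_oracle <- (2 - 5) / sqrt(sp2 * (2 / 3))
  expect_equal(res$statistic, t_oracle, tolerance = 1e-12)
  expect_equal(res$statistic, -3.6742, tolerance = 1e-4)
  expect_equal(res$p_value, 2 * stats::pt(-abs(t_oracle), 4), tolerance = 1e-12)
  expect_equal(res$p_value, 0.0213, tolerance = 1e-3)
  expect_equal(res$df, 4)

  same <- data.frame(conformation_type = rep(c(1L, 2L), each = 3),
                     v = rep(c(9, 10, 11), 2))
  r0 <- group_ttests(same, columns = "v")
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  flat <- data.frame(conformation_type = rep(c(1L, 2L), each = 3),
                     v = rep(5, 6))
  expect_error(group_ttests(flat, columns = "v"), "zero within-group variance")
})

test_that("BH adjustment matches the brute-force step-up rule", {
  bh_oracle <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    pmin(adj, 1)[order(o)]
  }
  tab <- data.frame(g = rep(c(1, 2), each = 4),
                    a = c(1, 2, 3, 4, 10, 11, 12, 13),
                    b = c(1, 2, 3, 4, 1.1, 2.2, 3.1, 4.4),
                    c = c(5, 6, 7, 8, 5.1, 6.1, 7.3, 8.2),
                    d = c(1, 3, 5, 7, 20, 25, 30, 35))
  res <- group_ttests(tab, group_col = "g", columns = c("a", "b", "c", "d"))
  expect_equal(res$p_adjusted, bh_oracle(res$p_value), tolerance = 1e-12)
  expect_true(all(res$p_adjusted >= res$p_value - 1e-15))
  expect_true(all(res$p_adjusted <= 1))

  set.seed(71)
  for (i in 1:100) {
    p <- runif(sample(2:12, 1))
    expect_equal(stats::p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }

  # the family {0.01, 0.02, 0.03, 0.04} is fully rejected at alpha 0.05
  adj <- stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH")
  expect_true(all(adj <= 0.05))
})

test_that("interhemispheric phi equals the closed-form 2x2 coefficient", {
  mk_cohort <- function(l_types, r_types) {
    n <- length(l_types)
    data.frame(subject_id = rep(sprintf("S%03d", 1:n), 2),
               hemisphere = rep(c("L", "R"), each = n),
               conformation_type = c(l_types, r_types))
  }
  perfect <- mk_cohort(c(1, 1, 2, 2, 1), c(1, 1, 2, 2, 1))
  expect_equal(interhemispheric_type_correlation(perfect)$statistic, 1)

  # 2x2 table a=10 (both Type 1), b=2, c=3, d=15
  l <- rep(c(1, 1, 2, 2), c(10, 2, 3, 15))
  r <- rep(c(1, 2, 1, 2), c(10, 2, 3, 15))
  res <- interhemispheric_type_correlation(mk_cohort(l, r))
  phi_oracle <- (10 * 15 - 2 * 3) /
    sqrt((10 + 2) * (3 + 15) * (10 + 3) * (2 + 15))
  expect_equal(res$statistic, phi_oracle, tolerance = 1e-12)
  expect_equal(res$statistic, 0.6591, tolerance = 1e-4)

  missing_r <- mk_cohort(c(1, 2), c(1, 2))[-4, ]
  expect_error(interhemispheric_type_correlation(missing_r),
               "both hemispheres")
})

test_that("phi is near zero when hemisphere types are independent", {
  set.seed(73)
  n <- 400
  cohort <- data.frame(subject_id = rep(sprintf("S%03d", 1:n), 2),
                       hemisphere = rep(c("L", "R"), each = n),
                       conformation_type = sample(c(1L, 2L), 2 * n,
                                                  replace = TRUE))
  res <- interhemispheric_type_correlation(cohort)
  expect_lt(abs(res$statistic), 3 / sqrt(n))
})
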