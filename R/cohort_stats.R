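# Cohort-level classical statistics: conformation-type proportions and
# z-tests, covariate/morphometry group comparisons with FDR control, and
# the inter-hemispheric type concordance (phi coefficient).

#' Summarize conformation-type proportions over hemispheres
#'
#' Counts Type-1 and Type-2 hemispheres and reports percentages. Display
#' percentages follow the reporting convention of truncating the Type-1
#' percentage to two decimals and giving Type 2 as its complement to 100
#' (which reproduces printed pairs like 38.15 / 61.85 for 29 and 47 of 76);
#' full-precision fractions are kept alongside.
#'
#' @param cohort Cohort data.frame with a `conformation_type` column
#'   (values 1/2 only).
#' @return A list of class `type_proportion_summary`: `n_hemispheres`,
#'   `n_type1`, `n_type2`, `pct_type1`, `pct_type2` (display, 2 dp) and
#'   `prop_type1`, `prop_type2` (full precision).
#' @export
summarize_types <- function(cohort) {
  ty <- cohort$conformation_type
  if (is.null(ty)) stop("cohort table lacks a conformation_type column")
  if (!all(ty %in% c(1L, 2L)))
    stop("unknown conformation types present (must be 1 or 2)")
  n <- length(ty); n1 <- sum(ty == 1L); n2 <- n - n1
  pct1 <- trunc(1e4 * n1 / n + 1e-9) / 100
  structure(list(n_hemispheres = n, n_type1 = n1, n_type2 = n2,
                 pct_type1 = pct1, pct_type2 = 100 - pct1,
                 prop_type1 = n1 / n, prop_type2 = n2 / n),
            class = "type_proportion_summary")
}

#' @export
print.type_proportion_summary <- function(x, ...) {
  cat(sprintf("Of %d hemispheres, %d Type 1 (%.2f%%) and %d Type 2 (%.2f%%)\n",
              x$n_hemispheres, x$n_type1, x$pct_type1, x$n_type2,
              x$pct_type2))
  invisible(x)
}

stat_result <- function(method, statistic, p_value, comparison = NA_character_,
                        p_adjusted = NA_real_, ...) {
  structure(list(method = method, statistic = statistic, p_value = p_value,
                 p_adjusted = p_adjusted, comparison = comparison, ...),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<%s>%s statistic %.4f, p = %.4g%s\n", x$method,
              if (is.na(x$comparison)) "" else paste0(" [", x$comparison, "]"),
              x$statistic, x$p_value,
              if (is.na(x$p_adjusted)) "" else
                sprintf(" (adjusted %.4g)", x$p_adjusted)))
  invisible(x)
}

#' Proportion z-test (one- or two-sample)
#'
#' One-sample: tests a count/nobs proportion against a fixed reference
#' proportion with a z statistic and two-sided normal p-value. The default
#' standard error uses the sample proportion (`variance = "sample"`); a
#' null-variance score-test variant is available. Two-sample (reference
#' given as `c(count2, nobs2)`): pooled-proportion variance.
#'
#' @param count Successes in the first sample.
#' @param nobs Size of the first sample.
#' @param reference Either a single proportion in [0,1], or an integer pair
#'   `c(count2, nobs2)` for the two-sample test.
#' @param variance For the one-sample test: `"sample"` (default) or
#'   `"null"`.
#' @return A `stat_result` with the z statistic and two-sided p-value.
#' @export
proportion_test <- function(count, nobs, reference,
                            variance = c("sample", "null")) {
  variance <- match.arg(variance)
  if (count < 0 || count > nobs || nobs <= 0)
    stop("need 0 <= count <= nobs, nobs > 0")
  p1 <- count / nobs
  if (length(reference) == 1L) {
    p0 <- reference
    if (p0 < 0 || p0 > 1) stop("reference proportion must be in [0,1]")
    se <- if (variance == "sample") {
      if (p1 %in% c(0, 1))
        stop("sample proportion is 0 or 1: the sample-variance z is undefined; use variance = \"null\"")
      sqrt(p1 * (1 - p1) / nobs)
    } else {
      sqrt(p0 * (1 - p0) / nobs)
    }
    z <- (p1 - p0) / se
    stat_result("one-proportion z-test", z, 2 * stats::pnorm(-abs(z)),
                comparison = sprintf("%d/%d vs %.4g", count, nobs, p0))
  } else if (length(reference) == 2L) {
    c2 <- reference[1]; n2 <- reference[2]
    if (c2 < 0 || c2 > n2 || n2 <= 0) stop("invalid second sample")
    p2 <- c2 / n2
    pp <- (count + c2) / (nobs + n2)
    if (pp %in% c(0, 1)) stop("degenerate pooled proportion")
    z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / nobs + 1 / n2))
    stat_result("two-proportion z-test (pooled)", z,
                2 * stats::pnorm(-abs(z)),
                comparison = sprintf("%d/%d vs %d/%d", count, nobs, c2, n2))
  } else stop("'reference' must be a proportion or c(count2, nobs2)")
}

#' Two-group t-tests over numeric columns with FDR control
#'
#' Runs a two-sided independent two-sample Student t-test (pooled
#' variance) per numeric column against the two-level group label, then
#' adjusts the p-value family with Benjamini-Hochberg and flags rejections
#' at `fdr_alpha`. The correction family is all columns tested in the call.
#'
#' @param table data.frame containing `group_col` and numeric columns.
#' @param group_col Name of the two-level grouping column.
#' @param columns Columns to test (default: all numeric columns except the
#'   group column).
#' @param fdr_alpha FDR level for the rejection flags.
#' @param na_on_degenerate If `TRUE`, a column with zero within-group
#'   variance in both groups (or fewer than 2 observations per group)
#'   yields NA statistics instead of an error; NA p-values are excluded
#'   from the BH family.
#' @return data.frame with one row per column: t statistic, df, p, BH
#'   adjusted p, rejection flag, group means.
#' @export
group_ttests <- function(table, group_col = "conformation_type",
                         columns = NULL, fdr_alpha = 0.05,
                         na_on_degenerate = FALSE) {
  g <- table[[group_col]]
  lev <- sort(unique(g))
  if (length(lev) != 2L) stop("grouping column must have exactly two levels")
  if (is.null(columns)) {
    columns <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                       group_col)
  }
  rows <- lapply(columns, function(cl) {
    x <- table[[cl]][g == lev[1]]
    y <- table[[cl]][g == lev[2]]
    degenerate <- length(x) < 2L || length(y) < 2L ||
      (stats::var(x) == 0 && stats::var(y) == 0)
    if (degenerate) {
      if (!na_on_degenerate) {
        if (length(x) < 2L || length(y) < 2L)
          stop("need >= 2 observations per group for column ", cl)
        stop("zero within-group variance in both groups for column ", cl)
      }
      return(data.frame(column = cl, statistic = NA_real_, df = NA_real_,
                        p_value = NA_real_, mean_group1 = mean(x),
                        mean_group2 = mean(y), stringsAsFactors = FALSE))
    }
    tt <- stats::t.test(x, y, var.equal = TRUE)
    data.frame(column = cl, statistic = unname(tt$statistic),
               df = unname(tt$parameter), p_value = tt$p.value,
               mean_group1 = mean(x), mean_group2 = mean(y),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out$rejected <- !is.na(out$p_adjusted) & out$p_adjusted <= fdr_alpha
  out
}

#' Inter-hemispheric conformation-type concordance (phi coefficient)
#'
#' Pearson correlation of the 0/1-coded conformation type across each
#' subject's left/right hemisphere pair; identical to the closed-form 2x2
#' phi coefficient.
#'
#' @param cohort Cohort data.frame with one row per subject x hemisphere
#'   and both hemispheres present for every subject.
#' @return A `stat_result` with the phi coefficient as the statistic and
#'   the 2x2 table attached.
#' @export
interhemispheric_type_correlation <- function(cohort) {
  wide <- merge(cohort[cohort$hemisphere == "L", c("subject_id", "conformation_type")],
                cohort[cohort$hemisphere == "R", c("subject_id", "conformation_type")],
                by = "subject_id", suffixes = c("_L", "_R"))
  n_sub <- length(unique(cohort$subject_id))
  if (nrow(wide) != n_sub)
    stop("every subject must have both hemispheres")
  l <- as.numeric(wide$conformation_type_L == 1L)
  r <- as.numeric(wide$conformation_type_R == 1L)
  if (stats::var(l) == 0 || stats::var(r) == 0)
    stop("a hemisphere has only one type: phi is undefined")
  phi <- stats::cor(l, r)
  tab <- table(factor(l, c(1, 0)), factor(r, c(1, 0)))
  stat_result("interhemispheric phi coefficient", phi,
              p_value = NA_real_, comparison = "L vs R type",
              table = tab, n_subjects = nrow(wide))
}
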