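# End-to-end experiment: simulate a cohort, build per-structure occurrence
# maps and blobs, run the conformation-type permutation tests and line-fit
# comparisons, compute cohort statistics, and write a JSON report plus a
# reproducibility manifest.

#' Adult-literature reference proportions of the connected conformation
#'
#' Published Type-1 (connected rhinal/collateral) percentages and sample
#' sizes from adult studies, used as fixed references for one-proportion
#' z-tests (anonymized labels A-E; the last is a formalin-fixed
#' hemisphere series).
#' @return data.frame with columns study, pct_type1, n_subjects.
#' @export
adult_reference_proportions <- function() {
  data.frame(
    study = c("adult_study_A", "adult_study_B", "adult_study_C",
              "adult_study_D", "adult_study_E"),
    pct_type1 = c(28, 36, 45, 36.25, 50),
    n_subjects = c(25, 50, 51, 40, 30),
    stringsAsFactors = FALSE)
}

#' Default experiment configuration
#'
#' Nested list accepted by [run_experiment()]: `cohort` holds
#' [cohort_config()] arguments, `analysis` the map/permutation parameters
#' (thresholds 5% and 25%, 3 mm smoothing for sulci, 1000 permutations),
#' and `seed` the top-level seed from which per-stage seeds are derived
#' (simulate: seed; extrema tests: seed + 1000 + test index; centroid
#' tests: seed + 2000 + test index).
#'
#' @param seed Top-level integer seed.
#' @return Config list.
#' @export
default_experiment_config <- function(seed = 1L) {
  list(seed = as.integer(seed),
       cohort = list(n_subjects = 38),
       analysis = list(fractions = c(0.05, 0.25), smoothing_fwhm = 3,
                       n_perm = 1000, fdr_alpha = 0.05))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load an experiment configuration from YAML (merged over defaults)
#' @param path YAML file path.
#' @return Config list.
#' @export
read_experiment_config <- function(path) {
  merge_config(default_experiment_config(), yaml::read_yaml(path))
}

vlog <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

#' Run the full synthetic-cohort experiment
#'
#' Stages: simulate the cohort; build per-structure, per-hemisphere
#' occurrence maps (sulci smoothed, compact structures not) and 5%/25%
#' blobs with bounding-box/centroid summaries; run the extrema permutation
#' tests between conformation types at both thresholds; run per-axis
#' centroid permutation tests and the orthogonal-regression direction
#' comparison; compute cohort statistics (type proportions, z-tests
#' against adult references, age/sex/brain-size and morphometry t-tests
#' with FDR, inter-hemispheric phi). Writes `report.json`, `cohort.tsv`,
#' `morphometry.tsv` and `manifest.json` under `out_dir`.
#'
#' @param config Config list (see [default_experiment_config()]) or a YAML
#'   path.
#' @param out_dir Output directory (created if needed).
#' @param write_masks Also write every subject mask as NIfTI.
#' @param verbose Log stage progress via `message()`.
#' @return The report, invisibly, with the manifest attached as
#'   `$manifest`.
#' @export
run_experiment <- function(config = default_experiment_config(),
                           out_dir = tempfile("mtlatlas_run_"),
                           write_masks = FALSE, verbose = FALSE) {
  if (is.character(config)) config <- read_experiment_config(config)
  config <- merge_config(default_experiment_config(), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  an <- config$analysis

  vlog(verbose, "stage simulate: n = %s, seed = %d",
       config$cohort$n_subjects, seed)
  ccfg <- do.call(cohort_config, c(config$cohort, list(seed = seed)))
  sim <- generate_cohort(ccfg)
  write_cohort_table(sim$cohort, file.path(out_dir, "cohort.tsv"))
  write_morphometry_table(sim$morphometry,
                          file.path(out_dir, "morphometry.tsv"))
  if (write_masks) {
    mask_dir <- file.path(out_dir, "masks")
    dir.create(mask_dir, showWarnings = FALSE)
    for (m in sim$masks) write_mask(m, mask_dir)
  }

  sulci <- intersect(ccfg$structures, SULCI)
  hemis <- ccfg$hemispheres
  fwhm_for <- function(s) if (s %in% SULCI) an$smoothing_fwhm else 0

  vlog(verbose, "stage maps: structures %s", paste(ccfg$structures, collapse = ","))
  maps <- list()
  for (s in ccfg$structures) for (h in hemis) {
    mk <- select_masks(sim$masks, s, h)
    pm <- build_probability_map(mk, fwhm_for(s), structure = s, hemisphere = h)
    blobs <- lapply(an$fractions, function(f)
      blob_summary(threshold_map(pm, f)))
    names(blobs) <- sprintf("fraction_%g", an$fractions)
    maps[[paste(s, h, sep = "_")]] <-
      list(structure = s, hemisphere = h, n_subjects = pm$n_subjects,
           smoothing_fwhm = pm$smoothing_fwhm, blobs = blobs)
  }

  vlog(verbose, "stage extrema permutation tests")
  extrema <- list()
  test_i <- 0L
  for (s in sulci) for (h in hemis) for (f in an$fractions) {
    test_i <- test_i + 1L
    mk <- select_masks(sim$masks, s, h)
    labs <- vapply(mk, `[[`, integer(1), "conformation_type")
    if (length(unique(labs)) != 2L) {
      extrema[[sprintf("%s_%s_f%g", s, h, f)]] <-
        list(skipped = "fewer than two conformation types present")
      next
    }
    res <- extrema_permutation_test(mk, fraction = f,
                                    smoothing_fwhm = fwhm_for(s),
                                    n_perm = an$n_perm,
                                    seed = seed + 1000L + test_i)
    extrema[[sprintf("%s_%s_f%g", s, h, f)]] <- lapply(res, function(r)
      list(observed = r$observed, interval = r$interval,
           significant = r$significant, n_perm = r$n_perm))
  }

  vlog(verbose, "stage centroid tests and line fits")
  centroids_df <- mask_centroids(
    sim$masks[vapply(sim$masks, function(m) m$structure %in% SULCI,
                     logical(1))])
  centroid_tests <- list()
  directions <- list()
  test_i <- 0L
  for (s in sulci) for (h in hemis) {
    cd <- centroids_df[centroids_df$structure == s &
                       centroids_df$hemisphere == h, ]
    if (length(unique(cd$conformation_type)) != 2L) next
    per_axis <- list()
    for (ax in c("x", "y", "z")) {
      test_i <- test_i + 1L
      r <- centroid_permutation_test(cd, cd$conformation_type, axis = ax,
                                     n_perm = an$n_perm,
                                     seed = seed + 2000L + test_i)
      per_axis[[ax]] <- list(observed = r$observed, interval = r$interval,
                             significant = r$significant)
    }
    centroid_tests[[paste(s, h, sep = "_")]] <- per_axis
    pts1 <- as.matrix(cd[cd$conformation_type == 1L, c("x", "y", "z")])
    pts2 <- as.matrix(cd[cd$conformation_type == 2L, c("x", "y", "z")])
    if (nrow(pts1) >= 2L && nrow(pts2) >= 2L) {
      f1 <- fit_odr_line(pts1); f2 <- fit_odr_line(pts2)
      cmp <- compare_directions(f1, f2)
      directions[[paste(s, h, sep = "_")]] <-
        list(d_type1 = unname(f1$d), d_type2 = unname(f2$d),
             t = cmp$statistic, p_value = cmp$p_value)
    }
  }

  vlog(verbose, "stage cohort statistics")
  types <- summarize_types(sim$cohort)
  refs <- adult_reference_proportions()
  ztests <- lapply(seq_len(nrow(refs)), function(i) {
    zt <- proportion_test(types$n_type1, types$n_hemispheres,
                          refs$pct_type1[i] / 100)
    list(study = refs$study[i], z = zt$statistic, p_value = zt$p_value)
  })
  covars <- sim$cohort
  covars$sex01 <- as.numeric(covars$sex == "F")
  covar_tests <- lapply(hemis, function(h) {
    tt <- group_ttests(covars[covars$hemisphere == h, ],
                       columns = c("age", "sex01", "hemisphere_volume",
                                   "hemisphere_surface"),
                       fdr_alpha = an$fdr_alpha, na_on_degenerate = TRUE)
    tt$hemisphere <- h
    tt
  })
  covar_tests <- do.call(rbind, covar_tests)
  morpho_tests <- lapply(hemis, function(h) {
    rows <- lapply(sulci, function(s) {
      sub <- sim$morphometry[sim$morphometry$hemisphere == h &
                             sim$morphometry$sulcus == s, ]
      if (length(unique(sub$conformation_type)) != 2L) return(NULL)
      tt <- group_ttests(sub, columns = c("max_depth", "mean_depth"),
                         fdr_alpha = an$fdr_alpha, na_on_degenerate = TRUE)
      tt$sulcus <- s; tt$hemisphere <- h
      tt
    })
    do.call(rbind, rows)
  })
  morpho_tests <- do.call(rbind, morpho_tests)
  phi <- if (length(hemis) == 2L &&
             length(unique(sim$cohort$conformation_type)) == 2L) {
    tryCatch(interhemispheric_type_correlation(sim$cohort)$statistic,
             error = function(e) NA_real_)
  } else NA_real_

  report <- list(
    type_proportions = list(n_hemispheres = types$n_hemispheres,
                            n_type1 = types$n_type1,
                            n_type2 = types$n_type2,
                            pct_type1 = types$pct_type1,
                            pct_type2 = types$pct_type2,
                            interhemispheric_phi = phi,
                            z_tests_vs_adult_literature = ztests),
    covariate_tests = covar_tests,
    morphometry_tests = morpho_tests,
    structure_maps = maps,
    extrema_tests = extrema,
    centroid_tests = centroid_tests,
    direction_comparisons = directions)
  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)

  outputs <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  outputs <- setdiff(outputs, file.path(out_dir, "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("mtlatlas")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = seed,
    stage_seeds = list(simulate = seed,
                       extrema_tests = "seed + 1000 + test index",
                       centroid_tests = "seed + 2000 + test index"),
    config = config,
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report$manifest <- manifest
  invisible(report)
}
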