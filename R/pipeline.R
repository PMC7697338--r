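#' Pipeline run configuration
#'
#' Configures a full reproducible run: optional phantom-imaging stage
#' (generate, segment, measure, and check against ground truth), simulation
#' of a development and a validation cohort, dichotomization of the
#' interface volume, the group-comparison and regression reports, and the
#' conventional-vs-combined model comparison. All randomness flows from the
#' single master seed, split deterministically per stage.
#'
#' @param seed master seed.
#' @param n_dev,n_val development and validation cohort sizes (defaults
#'   1004 and 136, the sizes of the originating cohorts).
#' @param cutoff_policy \code{"derive-on-development"} derives the Youden's J
#'   cutoff on the development cohort and reuses it unchanged for the
#'   validation cohort (never re-derived there); \code{"fixed"} applies
#'   \code{fixed_cutoff_cm3} to both.
#' @param fixed_cutoff_cm3 cutoff used under the fixed policy (default
#'   2.36 cm^3, the published value).
#' @param dev_config,val_config optional \code{cohort_config} overrides;
#'   by default both cohorts share the default generative model, with
#'   per-cohort seeds split from the master seed.
#' @param n_phantoms number of phantom studies for the imaging stage
#'   (0 skips it).
#' @param phantom_base \code{phantom_config} template for the imaging stage;
#'   tumor radius and margin contact are varied per phantom.
#' @param predictors candidate predictors for the univariable screen.
#' @param output_dir if non-NULL, write all report tables (CSV) and a JSON
#'   run log there.
#' @return An object of class \code{run_config}.
#' @export
run_config <- function(seed = 1L, n_dev = 1004L, n_val = 136L,
                       cutoff_policy = c("derive-on-development", "fixed"),
                       fixed_cutoff_cm3 = reported_cutoff_cm3(),
                       dev_config = NULL, val_config = NULL,
                       n_phantoms = 0L,
                       phantom_base = phantom_config(),
                       predictors = c("age", "ct_stage", "cn_stage", "er",
                                      "pr", "her2", "ki67", "menopause",
                                      "subtype", "interface_group"),
                       output_dir = NULL) {
  cutoff_policy <- match.arg(cutoff_policy)
  seed <- as.integer(seed)
  structure(list(seed = seed, n_dev = as.integer(n_dev),
                 n_val = as.integer(n_val),
                 cutoff_policy = cutoff_policy,
                 fixed_cutoff_cm3 = fixed_cutoff_cm3,
                 dev_config = dev_config, val_config = val_config,
                 n_phantoms = as.integer(n_phantoms),
                 phantom_base = phantom_base,
                 predictors = predictors,
                 output_dir = output_dir),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order and returns every intermediate
#' and report. Deterministic for a fixed master seed. Stage failures are
#' re-raised with the stage name (and patient index where applicable).
#'
#' @param config a \code{\link{run_config}}.
#' @return List of class \code{run_report}: \code{phantom_table} (measured
#'   vs ground-truth volumetrics, or NULL), \code{dev}, \code{val}
#'   (dichotomized cohort tables), \code{cutoff} (\code{cutoff_result} or
#'   fixed value), \code{group_comparison_dev}, \code{group_comparison_val},
#'   \code{univariable} (per-predictor OR tables), \code{selected},
#'   \code{vif}, \code{multivariable_dev}, \code{multivariable_val},
#'   \code{model_comparison_dev}, \code{model_comparison_val}, \code{log}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  phantom_table <- NULL
  if (config$n_phantoms > 0) {
    phantom_table <- stage("imaging", {
      rows <- lapply(seq_len(config$n_phantoms), function(i) {
        res <- tryCatch(process_one_phantom(config$phantom_base, seed, i),
                        error = function(e)
                          stop("patient ", i, ": ", conditionMessage(e)))
        cbind(data.frame(patient_id = i), res)
      })
      do.call(rbind, rows)
    })
  }

  dev_cfg <- config$dev_config %||% cohort_config(n_patients = config$n_dev,
                                                  seed = seed + 101L)
  val_cfg <- config$val_config %||% cohort_config(n_patients = config$n_val,
                                                  seed = seed + 202L)
  dev <- stage("simulate-development", simulate_cohort(dev_cfg))
  val <- stage("simulate-validation", simulate_cohort(val_cfg))

  cutoff <- stage("dichotomize", {
    if (config$cutoff_policy == "derive-on-development")
      youden_cutoff(dev$interface_volume_cm3, 1L - dev$pcr)
    else
      structure(list(cutoff = config$fixed_cutoff_cm3, j = NA_real_,
                     sensitivity = NA_real_, specificity = NA_real_),
                class = "cutoff_result")
  })
  dev <- dichotomize_interface(dev, cutoff$cutoff)
  val <- dichotomize_interface(val, cutoff$cutoff)   # development cutoff reused

  gc_dev <- stage("group-comparison", compare_groups(dev, by = "pcr"))
  gc_val <- stage("group-comparison", compare_groups(val, by = "pcr"))

  uni <- stage("univariable", {
    fits <- lapply(config$predictors, function(p) fit_logistic(dev, p))
    names(fits) <- config$predictors
    fits
  })
  selected <- stage("selection", select_multivariable(uni))
  vifs <- if (length(selected) > 1)
    stage("vif", vif(dev, selected)) else NULL
  multi_dev <- if (length(selected))
    stage("multivariable-development", fit_logistic(dev, selected)) else NULL
  multi_val <- if (length(selected))
    stage("multivariable-validation", fit_logistic(val, selected)) else NULL

  conventional <- setdiff(selected, "interface_group")
  mc_dev <- mc_val <- NULL
  if (length(conventional)) {
    mc_dev <- stage("model-comparison-development",
                    compare_models(dev, conventional))
    mc_val <- stage("model-comparison-validation",
                    compare_models(val, conventional))
  }

  report <- structure(list(
    phantom_table = phantom_table, dev = dev, val = val, cutoff = cutoff,
    group_comparison_dev = gc_dev, group_comparison_val = gc_val,
    univariable = uni, selected = selected, vif = vifs,
    multivariable_dev = multi_dev, multivariable_val = multi_val,
    model_comparison_dev = mc_dev, model_comparison_val = mc_val,
    log = list(master_seed = seed,
               stage_seeds = list(development = seed + 101L,
                                  validation = seed + 202L,
                                  phantoms = if (config$n_phantoms > 0)
                                    seed + 1000L + seq_len(config$n_phantoms)
                                  else integer(0)),
               cutoff_policy = config$cutoff_policy,
               cutoff_cm3 = cutoff$cutoff,
               package_version = as.character(utils::packageVersion("tfivolume")),
               r_version = R.version.string)),
    class = "run_report")
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

# one phantom through the measurement front end: generate -> interpolate
# wall -> mask -> cluster -> volumetrics, alongside the ground truth.
# Tumor radius and fat contact vary deterministically per patient index.
process_one_phantom <- function(base, seed, i) {
  pseed <- seed + 1000L + i
  radii <- base$tumor_radius_mm * c(0.7, 0.85, 1, 1.15, 1.3)
  contact <- c(0.2, 0.4, 0.6, 0.8, 1.0)
  cfg <- phantom_config(grid_shape = base$grid_shape,
                        voxel_spacing_mm = base$voxel_spacing_mm,
                        fat_fraction = base$fat_fraction,
                        tumor_radius_mm = radii[(i - 1) %% 5 + 1],
                        tumor_count = base$tumor_count,
                        tumor_margin_contact = contact[((i - 1) %/% 5) %% 5 + 1],
                        intensity_means = base$intensity_means,
                        noise_sd = base$noise_sd, seed = pseed,
                        annotation_step = base$annotation_step,
                        shell_mm = base$shell_mm)
  ph <- generate_phantom(cfg)
  wall <- interpolate_chest_wall(ph$annotation, cfg$grid_shape)
  mask <- build_breast_mask(ph$study, wall)
  labels <- cluster_tissues(ph$study, mask, seed = pseed)
  measured <- summarize_volumes(labels)
  truth <- ph$truth$true_volumes
  names(truth) <- paste0("true_", names(truth))
  cbind(measured, truth)
}

#' Write a pipeline report to disk
#'
#' Writes every tabular component as CSV plus a JSON run log recording the
#' seeds, cutoff policy, cutoff value, and package/R versions.
#' @param report a \code{run_report}.
#' @param dir output directory.
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, nm) if (!is.null(x))
    utils::write.csv(x, file.path(dir, nm), row.names = FALSE)
  wr(report$phantom_table, "phantom_volumetrics.csv")
  wr(report$dev, "cohort_development.csv")
  wr(report$val, "cohort_validation.csv")
  wr(report$group_comparison_dev, "group_comparison_development.csv")
  wr(report$group_comparison_val, "group_comparison_validation.csv")
  uni_tab <- do.call(rbind, lapply(names(report$univariable), function(p) {
    f <- report$univariable[[p]]
    cbind(data.frame(predictor = p, overall_p = f$overall_p), f$or_table)
  }))
  wr(uni_tab, "univariable_development.csv")
  if (!is.null(report$multivariable_dev))
    wr(report$multivariable_dev$or_table, "multivariable_development.csv")
  if (!is.null(report$multivariable_val))
    wr(report$multivariable_val$or_table, "multivariable_validation.csv")
  for (coh in c("dev", "val")) {
    mc <- report[[paste0("model_comparison_", coh)]]
    if (is.null(mc)) next
    tab <- data.frame(auc_conventional = mc$auc_conventional,
                      auc_combined = mc$auc_combined, delong_p = mc$delong_p,
                      nri = mc$nri, nri_lo = mc$nri_ci[1], nri_hi = mc$nri_ci[2],
                      nri_p = mc$nri_p, idi = mc$idi, idi_lo = mc$idi_ci[1],
                      idi_hi = mc$idi_ci[2], idi_p = mc$idi_p,
                      aic_conventional = mc$aic_conventional,
                      aic_combined = mc$aic_combined)
    wr(tab, paste0("model_comparison_",
                   if (coh == "dev") "development" else "validation", ".csv"))
  }
  jsonlite::write_json(report$log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Tumor-fat interface pipeline run\n")
  cat("  cutoff:", format(x$cutoff$cutoff, digits = 4), "cm^3 (policy:",
      x$log$cutoff_policy, ")\n")
  cat("  cohorts: development n =", nrow(x$dev), ", validation n =",
      nrow(x$val), "\n")
  if (!is.null(x$phantom_table))
    cat("  phantoms measured:", nrow(x$phantom_table), "\n")
  cat("  selected predictors:", paste(x$selected, collapse = ", "), "\n")
  if (!is.null(x$model_comparison_dev))
    cat(sprintf("  development AUC %.3f -> %.3f (DeLong p = %.3f), AIC %.1f -> %.1f\n",
                x$model_comparison_dev$auc_conventional,
                x$model_comparison_dev$auc_combined,
                x$model_comparison_dev$delong_p,
                x$model_comparison_dev$aic_conventional,
                x$model_comparison_dev$aic_combined))
  invisible(x)
}
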