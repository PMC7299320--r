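#' Pipeline configuration
#'
#' End-to-end analysis configuration: input cohort, phases to analyze,
#' segmentation morphology, texture configurations, screening, selection
#' and classifier settings. All randomness (phantom generation, LASSO
#' fold assignment) is derived from the single `seed`.
#'
#' @param input a `phantom_config`, an in-memory cohort (output of
#'   [generate_cohort()]), or the path of a cohort manifest CSV written
#'   by [write_cohort()].
#' @param phases subset of `c("pre", "post", "subtraction")`.
#' @param morphology a `morphology_params`.
#' @param glcm_cfg,grlm_cfg,dwt_cfg texture configurations.
#' @param screening a `screening_config`.
#' @param k_folds LASSO cross-validation folds.
#' @param classifiers list of `classifier_spec` objects.
#' @param mode `"paper"` (screen and select once on the full cohort,
#'   LOOCV over the classifier only) or `"leakage_safe"` (screening and
#'   selection re-run inside every LOOCV fold).
#' @param seed integer master seed.
#' @param output_dir optional directory for persisted artifacts.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = phantom_config(),
                            phases = c("pre", "post", "subtraction"),
                            morphology = morphology_params(),
                            glcm_cfg = glcm_config(),
                            grlm_cfg = grlm_config(),
                            dwt_cfg = dwt_config(),
                            screening = screening_config(),
                            k_folds = 10L,
                            classifiers = list(classifier_spec("lra"),
                                               classifier_spec("qda"),
                                               classifier_spec("svm")),
                            mode = c("paper", "leakage_safe"),
                            seed = 7L,
                            output_dir = NULL) {
  mode <- match.arg(mode)
  phases <- match.arg(phases, several.ok = TRUE)
  if (length(phases) < 1) stop("pipeline_config: need >= 1 phase")
  if (length(classifiers) < 1) stop("pipeline_config: need >= 1 classifier")
  stopifnot(all(vapply(classifiers, inherits, logical(1), "classifier_spec")))
  structure(list(input = input, phases = phases, morphology = morphology,
                 glcm_cfg = glcm_cfg, grlm_cfg = grlm_cfg,
                 dwt_cfg = dwt_cfg, screening = screening,
                 k_folds = as.integer(k_folds), classifiers = classifiers,
                 mode = mode, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Read a cohort back from a manifest written by [write_cohort()]
#'
#' The true lesion masks are not stored on disk; cases read from a
#' manifest carry `true_mask = NULL`.
#'
#' @param manifest path of the manifest CSV.
#' @return list of cases as in [generate_cohort()].
#' @export
read_cohort <- function(manifest) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("read_cohort requires the 'tiff' package")
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(man)), function(k) {
    row <- man[k, ]
    pre <- tiff::readTIFF(row$pre_path) *
      max(row$pre_hi - row$pre_lo, 1) + row$pre_lo
    post <- tiff::readTIFF(row$post_path) *
      max(row$post_hi - row$post_lo, 1) + row$post_lo
    v <- jsonlite::read_json(row$roi_path, simplifyVector = TRUE)
    list(patient_id = row$patient_id,
         pre = slice_image(pre, "pre", row$patient_id),
         post = slice_image(post, "post", row$patient_id),
         true_mask = NULL,
         seed_roi = roi_polygon(v),
         label = row$label)
  })
}

resolve_input <- function(input, seed) {
  if (inherits(input, "phantom_config")) {
    input$seed <- as.integer((seed * 131L + input$seed) %% .Machine$integer.max)
    generate_cohort(input)
  } else if (is.character(input)) {
    read_cohort(input)
  } else if (is.list(input)) {
    input
  } else stop("run_pipeline: unresolvable input")
}

#' Extract per-phase feature tables from a cohort
#'
#' Segments every lesion on its subtraction image, transfers the mask to
#' the other phases, normalizes/quantizes each phase independently, and
#' extracts the full texture inventory.
#'
#' @param cohort list of cases.
#' @param config a `pipeline_config`.
#' @param verbose emit progress messages (default `FALSE`).
#' @return named list of `feature_table` objects, one per phase, plus a
#'   `"masks"` attribute with the segmented masks.
#' @export
cohort_features <- function(cohort, config = pipeline_config(),
                            verbose = FALSE) {
  masks <- list()
  rows <- lapply(cohort, function(cs) {
    sub <- subtract_images(cs$post, cs$pre)
    mask <- tryCatch(
      segment_lesion(sub, cs$seed_roi, config$morphology),
      error = function(e) stop(sprintf("segmentation failed for %s: %s",
                                       cs$patient_id, conditionMessage(e)),
                               call. = FALSE))
    masks[[cs$patient_id]] <<- mask
    imgs <- list(pre = cs$pre, post = cs$post, subtraction = sub)
    if (verbose) message("features: ", cs$patient_id)
    lapply(imgs[config$phases], function(img) {
      q <- normalize_quantize(img, transfer_mask(mask, img))
      extract_features(q, config$glcm_cfg, config$grlm_cfg, config$dwt_cfg)
    })
  })
  labels <- vapply(cohort, `[[`, character(1), "label")
  ids <- vapply(cohort, `[[`, character(1), "patient_id")
  out <- lapply(stats::setNames(config$phases, config$phases), function(ph) {
    feature_table(do.call(rbind, lapply(rows, `[[`, ph)), labels, ids, ph)
  })
  attr(out, "masks") <- masks
  out
}

#' Run the full texture-analysis pipeline
#'
#' Phantom (or supplied) cohort -> lesion masks -> per-phase quantized
#' ROIs -> 488 texture features -> univariate screening -> LASSO
#' selection -> LOOCV classification -> ROC report. When `output_dir` is
#' set, all intermediate tables and the resolved configuration are
#' persisted as CSV/JSON.
#'
#' @param config a `pipeline_config`.
#' @param verbose emit progress messages (default `TRUE`).
#' @return list with `features` (per-phase tables), `screening`,
#'   `selection`, `scores` (per phase x classifier), `report`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  log_ <- function(...) if (verbose) message(sprintf(...))
  log_("stage: input")
  cohort <- resolve_input(config$input, config$seed)
  log_("stage: segmentation + texture extraction (%d cases)", length(cohort))
  tables <- cohort_features(cohort, config)
  screening <- list(); selection <- list(); scores <- list()
  for (ph in config$phases) {
    tab <- tables[[ph]]
    log_("stage: screening [%s]", ph)
    scr <- screen_table(tab, config$screening)
    screening[[ph]] <- scr
    kept <- attr(scr, "kept")
    log_("stage: selection [%s] (%d screened features)", ph, length(kept))
    sel <- lasso_select(tab$features[, kept, drop = FALSE],
                        tab$labels, k_folds = config$k_folds,
                        seed = config$seed + 1L)
    selection[[ph]] <- sel
    chosen <- names(sel$nonzero_features)
    for (spec in config$classifiers) {
      log_("stage: LOOCV [%s, %s] (%d selected features)",
           ph, spec$kind, length(chosen))
      model_tab <- if (config$mode == "paper")
        feature_table(tab$features[, chosen, drop = FALSE], tab$labels,
                      tab$patient_ids, ph)
      else tab
      scores[[paste(ph, spec$kind, sep = "_")]] <-
        fit_predict_loocv(model_tab, spec, mode = config$mode,
                          screening = config$screening,
                          k_folds = config$k_folds,
                          seed = config$seed + 1L)
    }
  }
  log_("stage: evaluation")
  report <- run_report(scores)
  result <- list(features = tables, screening = screening,
                 selection = selection, scores = scores, report = report,
                 config = config)
  if (!is.null(config$output_dir)) write_pipeline_outputs(result)
  result
}

write_pipeline_outputs <- function(result) {
  dir <- result$config$output_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ph in names(result$features)) {
    tab <- result$features[[ph]]
    df <- data.frame(patient_id = tab$patient_ids, label = tab$labels,
                     tab$features, check.names = FALSE)
    utils::write.csv(df, file.path(dir, sprintf("features_%s.csv", ph)),
                     row.names = FALSE)
    utils::write.csv(result$screening[[ph]],
                     file.path(dir, sprintf("screening_%s.csv", ph)),
                     row.names = FALSE)
    sel <- result$selection[[ph]]
    jsonlite::write_json(
      list(lambda_chosen = sel$lambda_chosen,
           nonzero_features = as.list(sel$nonzero_features),
           seed = sel$seed),
      file.path(dir, sprintf("selection_%s.json", ph)),
      auto_unbox = TRUE, digits = NA)
  }
  for (nm in names(result$scores))
    utils::write.csv(as.data.frame(result$scores[[nm]]),
                     file.path(dir, sprintf("scores_%s.csv", nm)),
                     row.names = FALSE)
  utils::write.csv(result$report$performance,
                   file.path(dir, "report_performance.csv"),
                   row.names = FALSE)
  jsonlite::write_json(lapply(result$report$comparisons, function(m)
    as.data.frame(m)), file.path(dir, "report_comparisons.json"),
    digits = NA)
  cfg <- result$config
  cfg$input <- if (inherits(cfg$input, "phantom_config"))
    unclass(cfg$input) else "in-memory cohort"
  jsonlite::write_json(rapply(unclass(cfg), unclass, how = "replace"),
                       file.path(dir, "config_resolved.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
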