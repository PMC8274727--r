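# Config-driven orchestration of the experiment grid:
# ROI kind x quantization x pixel distance x classifier family.

#' Experiment configuration
#'
#' Defines the analysis grid. \code{distances} applies to the tumor-core ROI
#' only; margin ROIs always use a pixel distance of 1 because the thin bands
#' do not contain enough pixel pairs at larger offsets. Requesting any other
#' margin distance is rejected at validation.
#'
#' @param cohort A \code{\link{cohort_config}} (synthetic run) or a path to
#'   a cohort directory written by \code{\link{write_cohort}}.
#' @param roi_kinds Subset of \code{c("core","margin5","margin10","margin15")}.
#' @param n_levels_list Subset of \code{c(16, 32, 64, 128, 256)}.
#' @param distances Core-ROI offset distances, subset of
#'   \code{c(1, 2, 3, 4, 5, 10, 15)}.
#' @param families Classifier families to evaluate.
#' @param objective \code{"accuracy"} or \code{"F1"}.
#' @param balanced Use balanced subsampling inside each training fold.
#' @param n_subsets Balanced subsets per fold.
#' @param grids Optional named list of hyperparameter grids per family
#'   (defaults to \code{default_grid}).
#' @param margin_distances Must be 1 (exposed only so misconfiguration fails
#'   loudly rather than silently).
#' @param max_features Largest feature-subset size in the search (default 4).
#' @param seed Integer seed for every stochastic step.
#' @param out_dir Output directory for result artifacts.
#' @return An \code{experiment_config} object.
#' @export
experiment_config <- function(cohort,
                              roi_kinds = c("core", "margin10"),
                              n_levels_list = c(32L, 128L),
                              distances = 1L,
                              families = CLASSIFIER_FAMILIES,
                              objective = "accuracy",
                              balanced = FALSE, n_subsets = 25L,
                              grids = list(),
                              margin_distances = 1L,
                              max_features = 4L,
                              seed = 1L, out_dir = NULL) {
  stopifnot(all(roi_kinds %in% c("core", "margin5", "margin10", "margin15")),
            all(n_levels_list %in% ALLOWED_LEVELS),
            all(distances %in% c(1, 2, 3, 4, 5, 10, 15)),
            all(families %in% CLASSIFIER_FAMILIES))
  if (!identical(as.numeric(margin_distances), 1))
    stop("margin ROIs support a pixel distance of 1 only: thin bands lack ",
         "pixel pairs at larger offsets")
  structure(list(cohort = cohort, roi_kinds = roi_kinds,
                 n_levels_list = as.integer(n_levels_list),
                 distances = as.integer(distances), families = families,
                 objective = objective, balanced = balanced,
                 n_subsets = as.integer(n_subsets), grids = grids,
                 max_features = as.integer(max_features),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "experiment_config")
}

#' Read a cohort directory written by \code{write_cohort}
#'
#' Expects \code{labels.csv} (patient_id, label) plus per-patient NIfTI
#' volumes (\code{<id>.nii.gz}, \code{<id>_core.nii.gz},
#' \code{<id>_breast.nii.gz}) or per-slice TIFF directories.
#'
#' @param dir Cohort directory.
#' @return List of \code{patient_record}s.
#' @export
read_cohort <- function(dir) {
  labels_path <- file.path(dir, "labels.csv")
  if (!file.exists(labels_path))
    stop(sprintf("no labels.csv in '%s'", dir))
  labels <- utils::read.csv(labels_path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(labels)), function(i) {
    id <- labels$patient_id[i]
    nii <- file.path(dir, paste0(id, ".nii.gz"))
    if (file.exists(nii)) {
      read_patient(nii, file.path(dir, paste0(id, "_core.nii.gz")),
                   file.path(dir, paste0(id, "_breast.nii.gz")),
                   labels$label[i], patient_id = id)
    } else {
      read_patient(file.path(dir, id), file.path(dir, paste0(id, "_core")),
                   file.path(dir, paste0(id, "_breast")),
                   labels$label[i], patient_id = id)
    }
  })
}

# Piecewise-linear ROC points from pooled fold predictions.
roc_points <- function(preds) {
  ord <- order(preds$score, decreasing = TRUE)
  truth <- preds$truth[ord]
  tpr <- cumsum(truth == "NR") / sum(truth == "NR")
  fpr <- cumsum(truth == "R") / sum(truth == "R")
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Run the full experiment grid
#'
#' For every (ROI kind, quantization, distance) cell the cohort feature
#' table is extracted once (cached within the run) and each classifier
#' family is tuned by \code{\link{exhaustive_search}}. Failures are isolated
#' per cell: one degenerate ROI must not kill the grid. Identical
#' configuration and seed give identical outputs.
#'
#' Artifacts written to \code{out_dir} (when set): \code{results.csv} in the
#' optimal-classifier table layout (Classifier, Sensitivity, Specificity,
#' Accuracy, AUC, F1, Features, ROI, Quantization, Pixel distance),
#' \code{predictions.json} with per-fold predictions, per-configuration ROC
#' CSVs, the echoed configuration and a run log.
#'
#' @param config An \code{\link{experiment_config}}.
#' @return Invisibly, a list with \code{results} (data.frame),
#'   \code{details} (per-cell eval_result objects) and \code{errors}.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  records <- if (inherits(config$cohort, "cohort_config"))
    generate_cohort(config$cohort)
  else read_cohort(config$cohort)

  log_lines <- c(sprintf("seed: %d", config$seed),
                 sprintf("patients: %d", length(records)),
                 sprintf("config: %s", paste(utils::capture.output(
                   utils::str(config[setdiff(names(config), "cohort")])),
                   collapse = " ")))
  cache <- new.env(parent = emptyenv())
  get_features <- function(roi, levels, d) {
    key <- sprintf("%s|%d|%d", roi, levels, d)
    if (!exists(key, envir = cache, inherits = FALSE))
      assign(key, extract_feature_table(records, roi, levels, d),
             envir = cache)
    get(key, envir = cache, inherits = FALSE)
  }

  cells <- list()
  for (roi in config$roi_kinds)
    for (lev in config$n_levels_list)
      for (d in if (roi == "core") config$distances else 1L)
        cells[[length(cells) + 1L]] <- list(roi = roi, lev = lev, d = d)

  results <- list(); details <- list(); errors <- list()
  for (cell in cells) {
    tab <- tryCatch(get_features(cell$roi, cell$lev, cell$d),
                    error = function(e) e)
    if (inherits(tab, "error")) {
      msg <- sprintf("cell %s/%d/%d: %s", cell$roi, cell$lev, cell$d,
                     conditionMessage(tab))
      errors[[length(errors) + 1L]] <- msg
      log_lines <- c(log_lines, paste("ERROR", msg))
      next
    }
    for (fam in config$families) {
      res <- tryCatch(
        exhaustive_search(tab, fam, objective = config$objective,
                          max_size = config$max_features,
                          grid = config$grids[[fam]],
                          balanced = config$balanced,
                          n_subsets = config$n_subsets, seed = config$seed),
        error = function(e) e)
      key <- sprintf("%s|%s|%d|%d", fam, cell$roi, cell$lev, cell$d)
      if (inherits(res, "error")) {
        msg <- sprintf("%s: %s", key, conditionMessage(res))
        errors[[length(errors) + 1L]] <- msg
        log_lines <- c(log_lines, paste("ERROR", msg))
        next
      }
      details[[key]] <- res
      results[[length(results) + 1L]] <- data.frame(
        Classifier = fam,
        Sensitivity = res$sensitivity, Specificity = res$specificity,
        Accuracy = res$accuracy, AUC = res$AUC, F1 = res$F1,
        Features = paste(res$selected_features, collapse = "+"),
        ROI = cell$roi, Quantization = cell$lev, Pixel_distance = cell$d,
        stringsAsFactors = FALSE)
    }
  }
  if (length(results) == 0L)
    stop(sprintf("all %d grid cells failed; first error: %s", length(cells),
                 if (length(errors)) errors[[1L]] else "none"))
  results <- do.call(rbind, results)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(results, file.path(config$out_dir, "results.csv"),
                     row.names = FALSE)
    preds_json <- lapply(details, function(r)
      list(features = r$selected_features, hyperparams = r$hyperparams,
           predictions = r$preds[, c("patient_id", "truth", "pred",
                                     "score")]))
    jsonlite::write_json(preds_json,
                         file.path(config$out_dir, "predictions.json"),
                         auto_unbox = TRUE, digits = NA)
    for (key in names(details))
      utils::write.csv(roc_points(details[[key]]$preds),
                       file.path(config$out_dir,
                                 paste0("roc_", gsub("[|]", "_", key),
                                        ".csv")),
                       row.names = FALSE)
    writeLines(log_lines, file.path(config$out_dir, "run.log"))
  }
  invisible(list(results = results, details = details, errors = errors))
}

#' Read an experiment configuration from a flat YAML file
#'
#' Keys mirror the arguments of \code{\link{experiment_config}}; the cohort
#' is either \code{cohort_dir: <path>} or a \code{synthetic:} block whose
#' keys mirror \code{\link{cohort_config}}.
#'
#' @param path YAML file.
#' @return An \code{experiment_config}.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort <- if (!is.null(y$cohort_dir)) y$cohort_dir
  else {
    s <- y$synthetic %||% list()
    do.call(cohort_config, s[intersect(names(s),
                                       names(formals(cohort_config)))])
  }
  args <- y[intersect(names(y), names(formals(experiment_config)))]
  args$cohort <- cohort
  do.call(experiment_config, args)
}
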