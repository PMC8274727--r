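# Leave-one-out cross-validation, NR-positive metrics, ROC/AUC from pooled
# LOOCV scores, exhaustive <=4-feature search, per-feature group tests.

#' Leave-one-out cross-validation of one classifier configuration
#'
#' For each patient the model is refit on all other rows and scored on the
#' held-out row. Standardization statistics come from the training fold only.
#' With \code{balanced = TRUE}, \code{n_subsets} balanced subsets of the
#' training fold are drawn (all minority rows plus a matched majority draw),
#' one model is fit per subset — each with its own standardization — and
#' their centered decision scores are averaged; the label is taken from the
#' averaged score against threshold 0.
#'
#' @param rows Data.frame with a \code{label} column (\code{"R"}/\code{"NR"},
#'   >= 2 rows per class), a \code{patient_id} column (optional), and the
#'   feature columns.
#' @param family Classifier family (see \code{\link{default_grid}}).
#' @param features Character vector of 1--4 feature column names.
#' @param params Named list of concrete hyperparameters (C, gamma, k).
#' @param balanced Use balanced subsampling of each training fold.
#' @param n_subsets Number of balanced subsets (default 25).
#' @param seed Optional seed making balanced draws reproducible.
#' @return Data.frame of fold predictions: \code{patient_id}, \code{truth},
#'   \code{pred}, \code{score}; attribute \code{"fold_transforms"} records
#'   each fold's standardization (leakage auditing).
#' @export
loocv <- function(rows, family, features, params = list(),
                  balanced = FALSE, n_subsets = 25L, seed = NULL) {
  stopifnot(is.data.frame(rows), all(features %in% names(rows)),
            length(features) >= 1L)
  y <- as.character(rows$label)
  if (min(table(factor(y, levels = c("R", "NR")))) < 2L)
    stop("need at least 2 rows per class for LOOCV")
  X <- as.matrix(rows[, features, drop = FALSE])
  if (anyNA(X)) stop("missing values in selected features")
  ids <- if ("patient_id" %in% names(rows)) as.character(rows$patient_id)
         else sprintf("row%d", seq_len(nrow(rows)))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(X)
  score <- numeric(n)
  tie_ge <- FALSE
  transforms <- vector("list", n)
  if (family == "kNN" && !balanced) {
    # vectorized fold loop: z-score centering cancels in Euclidean
    # distances, so only the training-fold scale enters
    k <- params$k %||% 1L
    if (k > n - 1L) stop(sprintf("k = %d exceeds %d training rows", k, n - 1L))
    p <- ncol(X)
    for (i in seq_len(n)) {
      tr <- X[-i, , drop = FALSE]
      ctr <- colMeans(tr)
      sdv <- sqrt(colSums((tr - rep(ctr, each = n - 1L))^2) / (n - 2L))
      sdv[sdv == 0] <- 1
      transforms[[i]] <- list(center = ctr, scale = sdv)
      A <- (tr - rep(X[i, ], each = n - 1L)) / rep(sdv, each = n - 1L)
      nn <- order(rowSums(A * A))[seq_len(k)]   # distance ties: lower index
      score[i] <- mean(y[-i][nn] == "NR") - 0.5
    }
    pred <- ifelse(score >= 0, "NR", "R")
    out <- data.frame(patient_id = ids, truth = y, pred = pred,
                      score = score, stringsAsFactors = FALSE)
    attr(out, "fold_transforms") <- transforms
    return(out)
  }
  for (i in seq_len(n)) {
    trX <- X[-i, , drop = FALSE]; trY <- y[-i]
    teX <- X[i, , drop = FALSE]
    if (balanced) {
      subsets <- balance_subsample(trY, n_subsets)
      ss <- vapply(subsets, function(idx) {
        st <- suppressWarnings(standardize(trX[idx, , drop = FALSE], teX))
        m <- fit_family(family, st$train, trY[idx], params)
        m$score(st$apply)
      }, 0)
      score[i] <- mean(ss)
      st1 <- suppressWarnings(standardize(trX[subsets[[1L]], , drop = FALSE]))
      transforms[[i]] <- st1[c("center", "scale")]
    } else {
      st <- suppressWarnings(standardize(trX, teX))
      m <- fit_family(family, st$train, trY, params)
      score[i] <- m$score(st$apply)
      transforms[[i]] <- st[c("center", "scale")]
    }
    if (family == "kNN") tie_ge <- TRUE
  }
  pred <- if (tie_ge) ifelse(score >= 0, "NR", "R")
          else ifelse(score > 0, "NR", "R")
  out <- data.frame(patient_id = ids, truth = y, pred = pred, score = score,
                    stringsAsFactors = FALSE)
  attr(out, "fold_transforms") <- transforms
  out
}

#' Classification metrics with non-responders as the positive class
#'
#' True positives are non-responders predicted non-responder. Sensitivity,
#' specificity and accuracy are reported in percent; F1 as a fraction. When
#' no case is predicted positive, precision is undefined and F1 is reported
#' as 0 with a warning.
#'
#' @param preds Fold predictions from \code{\link{loocv}} (columns
#'   \code{truth}, \code{pred}).
#' @return List: \code{sensitivity}, \code{specificity}, \code{accuracy}
#'   (percent), \code{F1} (fraction), and the confusion counts \code{TP},
#'   \code{FN}, \code{TN}, \code{FP}.
#' @export
compute_metrics <- function(preds) {
  stopifnot(nrow(preds) > 0, all(c("R", "NR") %in% preds$truth))
  tp <- sum(preds$truth == "NR" & preds$pred == "NR")
  fn <- sum(preds$truth == "NR" & preds$pred == "R")
  tn <- sum(preds$truth == "R" & preds$pred == "R")
  fp <- sum(preds$truth == "R" & preds$pred == "NR")
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  acc <- (tp + tn) / nrow(preds)
  f1 <- if (tp + fp == 0) {
    warning("no positive predictions: precision undefined, F1 set to 0")
    0
  } else {
    prec <- tp / (tp + fp)
    if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
  }
  list(sensitivity = 100 * sens, specificity = 100 * spec,
       accuracy = 100 * acc, F1 = f1, TP = tp, FN = fn, TN = tn, FP = fp)
}

#' Area under the ROC curve from pooled LOOCV scores
#'
#' Rank (Mann-Whitney) formulation on the pooled decision scores: the
#' probability that a random non-responder scores above a random responder,
#' ties counting one half. One held-out point per fold makes per-fold ROC
#' curves undefined, so pooling is the only coherent choice for LOOCV.
#'
#' @param preds Fold predictions (columns \code{truth}, \code{score}).
#' @return AUC as a fraction in [0, 1].
#' @export
roc_auc <- function(preds) {
  stopifnot(all(c("R", "NR") %in% preds$truth), all(is.finite(preds$score)))
  if (length(unique(preds$score)) == 1L) {
    warning("all decision scores identical: AUC = 0.5")
    return(0.5)
  }
  r <- rank(preds$score)               # mean ranks: ties contribute 1/2
  n_pos <- sum(preds$truth == "NR")
  n_neg <- sum(preds$truth == "R")
  (sum(r[preds$truth == "NR"]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Enumerate feature subsets of size 1..max_size
#'
#' For the 11 texture features and \code{max_size = 4} this yields
#' 11 + 55 + 165 + 330 = 561 subsets, the search space of
#' \code{\link{exhaustive_search}}.
#'
#' @param features Candidate feature names.
#' @param max_size Largest subset size.
#' @return List of character vectors, ordered by size then lexicographically
#'   in the candidate order.
#' @export
feature_subsets <- function(features = GLCM_FEATURE_NAMES, max_size = 4L) {
  out <- list()
  for (k in seq_len(min(max_size, length(features))))
    out <- c(out, utils::combn(features, k, simplify = FALSE))
  out
}

grid_combos <- function(grid) {
  if (length(grid) == 0L) return(list(list()))
  df <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  # iterate smaller hyperparameters first so ties break toward them
  df <- df[do.call(order, as.list(df)), , drop = FALSE]
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

#' Exhaustive small-subset feature selection with hyperparameter grid search
#'
#' Enumerates every feature subset of size 1..\code{max_size} crossed with
#' the family's hyperparameter grid, runs LOOCV for each configuration and
#' returns the one maximizing the objective (accuracy or F1). Ties break
#' toward the smaller subset, then the earlier subset in canonical feature
#' order, then the smaller hyperparameters. Capping subsets at four features
#' guards against the curse of dimensionality at cohort sizes of ~10^2.
#' Selection happens once on the full table (the LOOCV estimate of the
#' selected subset is therefore optimistically biased; see the vignette).
#'
#' @inheritParams loocv
#' @param objective \code{"accuracy"} or \code{"F1"}.
#' @param candidate_features Feature columns to search over.
#' @param max_size Largest subset size (default 4).
#' @param grid Hyperparameter grid; defaults to \code{default_grid(family)}.
#' @return An \code{eval_result} list: the metrics, AUC, selected features,
#'   hyperparameters, objective, per-fold predictions, and the number of
#'   subsets/configurations enumerated.
#' @export
exhaustive_search <- function(rows, family,
                              objective = c("accuracy", "F1"),
                              candidate_features = GLCM_FEATURE_NAMES,
                              max_size = 4L, grid = NULL,
                              balanced = FALSE, n_subsets = 25L,
                              seed = NULL) {
  objective <- match.arg(objective)
  if (is.null(grid)) grid <- default_grid(family)
  subsets <- feature_subsets(candidate_features, max_size)
  combos <- grid_combos(grid)
  best <- NULL
  n_cells <- 0L
  failures <- list()
  for (fs in subsets) for (par in combos) {
    n_cells <- n_cells + 1L
    preds <- tryCatch(
      loocv(rows, family, fs, params = par, balanced = balanced,
            n_subsets = n_subsets, seed = seed),
      error = function(e) e)
    if (inherits(preds, "error")) {      # skip failed cell, keep the reason
      failures[[length(failures) + 1L]] <-
        list(features = fs, params = par, message = conditionMessage(preds))
      next
    }
    met <- suppressWarnings(compute_metrics(preds))
    obj <- if (objective == "accuracy") met$accuracy else met$F1
    if (is.null(best) || obj > best$objective_value + 1e-12) {
      best <- list(objective_value = obj, features = fs, params = par,
                   preds = preds, metrics = met)
    }
    # strict > plus ordered enumeration implements the tie-break: subsets
    # come smaller-first in canonical order, hyperparameters smaller-first
  }
  if (is.null(best)) stop("every configuration failed during the search")
  structure(list(family = family,
                 sensitivity = best$metrics$sensitivity,
                 specificity = best$metrics$specificity,
                 accuracy = best$metrics$accuracy,
                 F1 = best$metrics$F1,
                 AUC = suppressWarnings(roc_auc(best$preds)),
                 selected_features = best$features,
                 hyperparams = best$params,
                 objective = objective,
                 objective_value = best$objective_value,
                 preds = best$preds,
                 n_feature_subsets = length(subsets),
                 n_configurations = n_cells,
                 failures = failures),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf(
    "%s: sens %.1f%% spec %.1f%% acc %.1f%% F1 %.2f AUC %.2f | %s%s\n",
    x$family, x$sensitivity, x$specificity, x$accuracy, x$F1, x$AUC,
    paste(x$selected_features, collapse = "+"),
    if (length(x$hyperparams))
      paste0(" [", paste(names(x$hyperparams), unlist(x$hyperparams),
                         sep = "=", collapse = ", "), "]")
    else ""))
  invisible(x)
}

#' Per-feature group-difference tests between responders and non-responders
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test per feature; rank tests
#' are robust for skewed radiomic features at 19-vs-83 group sizes. Raw
#' p-values are reported with a p <= 0.05 flag and no multiplicity
#' correction by default; Holm correction is available.
#'
#' @param rows Feature table with \code{label} and feature columns.
#' @param features Feature columns to test.
#' @param adjust \code{"none"} (default) or \code{"holm"}.
#' @return Data.frame: \code{feature}, \code{p}, \code{significant}, sorted
#'   by p-value.
#' @export
group_difference_test <- function(rows, features = GLCM_FEATURE_NAMES,
                                  adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  y <- as.character(rows$label)
  stopifnot(sum(y == "R") >= 2, sum(y == "NR") >= 2)
  p <- vapply(features, function(f) {
    a <- rows[[f]][y == "NR"]; b <- rows[[f]][y == "R"]
    if (length(unique(c(a, b))) == 1L) {
      warning(sprintf("feature %s constant in both groups: p = 1", f))
      return(1)
    }
    suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
  }, 0)
  if (adjust == "holm") p <- stats::p.adjust(p, "holm")
  out <- data.frame(feature = features, p = p, significant = p <= 0.05,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$p), ]
}
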