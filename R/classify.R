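# The four classifier families (FLD, SVM-Lin, SVM-RBF, kNN), feature
# standardization and balanced subsampling. All models expose a centered
# decision score: larger = more non-responder-like, threshold at 0.

CLASSIFIER_FAMILIES <- c("FLD", "SVM-Lin", "SVM-RBF", "kNN")

#' Default hyperparameter grids
#'
#' Cost grid C = 2^1..2^10 and RBF width grid gamma = 2^-15..2^5 for the
#' SVMs; k = 1..5 neighbors for kNN; FLD has no tuning parameter.
#'
#' @param family One of \code{"FLD"}, \code{"SVM-Lin"}, \code{"SVM-RBF"},
#'   \code{"kNN"}.
#' @return A named list of grid vectors (possibly empty for FLD).
#' @export
default_grid <- function(family) {
  switch(family,
         "FLD" = list(),
         "SVM-Lin" = list(C = 2^(1:10)),
         "SVM-RBF" = list(C = 2^(1:10), gamma = 2^(-15:5)),
         "kNN" = list(k = 1:5),
         stop(sprintf("unknown classifier family '%s'", family)))
}

#' Standardize features using training-fold statistics only
#'
#' Per-feature z-score with mean and standard deviation estimated from
#' \code{train_X}; \code{apply_X} is transformed with the SAME statistics
#' (the cross-validation leakage guard). A zero-variance training feature
#' keeps scale 1 (centering only) with a warning.
#'
#' @param train_X Numeric matrix (>= 2 rows) or data.frame.
#' @param apply_X Optional matrix/data.frame to transform with the training
#'   statistics.
#' @return List with \code{train}, \code{apply} (or NULL), \code{center},
#'   \code{scale}.
#' @export
standardize <- function(train_X, apply_X = NULL) {
  train_X <- as.matrix(train_X)
  stopifnot(nrow(train_X) >= 2)
  center <- colMeans(train_X)
  scale <- apply(train_X, 2L, stats::sd)
  if (any(scale == 0)) {
    warning(sprintf("zero-variance feature(s) in training data: %s",
                    paste(colnames(train_X)[scale == 0], collapse = ", ")))
    scale[scale == 0] <- 1
  }
  tr <- sweep(sweep(train_X, 2L, center), 2L, scale, "/")
  ap <- if (!is.null(apply_X)) {
    apply_X <- matrix(as.numeric(as.matrix(apply_X)), ncol = ncol(train_X),
                      dimnames = list(NULL, colnames(train_X)))
    sweep(sweep(apply_X, 2L, center), 2L, scale, "/")
  }
  list(train = tr, apply = ap, center = center, scale = scale)
}

#' Balanced subsampling of an imbalanced cohort
#'
#' Each subset contains every minority-class row plus an equal-size uniform
#' draw of majority-class rows without replacement (for the 83 R / 19 NR
#' cohort this gives 19 R + 19 NR per subset).
#'
#' @param labels Character vector of \code{"R"}/\code{"NR"} labels.
#' @param n_subsets Number of subsets to draw.
#' @return List of integer row-index vectors.
#' @export
balance_subsample <- function(labels, n_subsets = 25L) {
  tab <- table(factor(labels, levels = c("R", "NR")))
  if (any(tab == 0)) stop("both classes must be present for balancing")
  minority <- names(tab)[which.min(tab)]
  min_idx <- which(labels == minority)
  maj_idx <- which(labels != minority)
  lapply(seq_len(n_subsets), function(s)
    sort(c(min_idx, sample(maj_idx, length(min_idx)))))
}

new_model <- function(family, score_fun, tie_ge = FALSE, params = list()) {
  structure(list(family = family, score = score_fun, tie_ge = tie_ge,
                 params = params),
            class = "trained_model")
}

#' Predict labels from a trained model
#'
#' @param object A \code{trained_model}.
#' @param newdata Feature matrix on the model's (standardized) scale.
#' @param ... Unused.
#' @return List with \code{score} (centered decision scores, NR positive)
#'   and \code{label}.
#' @export
predict.trained_model <- function(object, newdata, ...) {
  s <- object$score(as.matrix(newdata))
  lab <- if (object$tie_ge) ifelse(s >= 0, "NR", "R")
         else ifelse(s > 0, "NR", "R")
  list(score = as.numeric(s), label = lab)
}

#' Fisher's linear discriminant
#'
#' Finds the axis maximizing between-class over within-class scatter:
#' w proportional to S_W^-1 (mu_NR - mu_R), with the pooled within-class
#' scatter ridge-regularized as S_W + eps I, eps = 1e-6 tr(S_W)/p (balanced
#' 19-vs-19 fits with up to 4 features can be near-singular). The decision
#' score is the projection centered at the midpoint of the projected class
#' means; score > 0 predicts NR.
#'
#' @param X Standardized feature matrix.
#' @param y Labels (\code{"R"}/\code{"NR"}), one per row.
#' @return A \code{trained_model}.
#' @export
fld_fit <- function(X, y) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), all(y %in% c("R", "NR")),
            length(unique(y)) == 2L)
  p <- ncol(X)
  mu_r <- colMeans(X[y == "R", , drop = FALSE])
  mu_n <- colMeans(X[y == "NR", , drop = FALSE])
  cs <- function(cls) {
    Z <- sweep(X[y == cls, , drop = FALSE], 2L,
               if (cls == "R") mu_r else mu_n)
    crossprod(Z)
  }
  Sw <- cs("R") + cs("NR")
  eps <- 1e-6 * sum(diag(Sw)) / p
  if (eps == 0) eps <- 1e-6
  w <- tryCatch(solve(Sw + diag(eps, p), mu_n - mu_r),
                error = function(e)
                  stop("within-class scatter singular despite regularization"))
  thr <- sum(w * (mu_n + mu_r)) / 2
  new_model("FLD",
            function(M) as.numeric(M %*% w) - thr,
            params = list(w = w, threshold = thr))
}

#' Soft-margin support vector machine (linear or RBF kernel)
#'
#' Thin wrapper around \code{e1071::svm} (libsvm). Features are expected
#' already standardized (\code{scale = FALSE} internally). The decision
#' score is the signed distance to the hyperplane, oriented so the
#' non-responder side is positive.
#'
#' @param X Standardized feature matrix.
#' @param y Labels (\code{"R"}/\code{"NR"}).
#' @param kernel \code{"linear"} or \code{"rbf"}.
#' @param C Misclassification cost.
#' @param gamma RBF kernel width (ignored for the linear kernel).
#' @return A \code{trained_model}.
#' @export
svm_fit <- function(X, y, kernel = c("linear", "rbf"), C = 2, gamma = NULL) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X)
  yf <- factor(y, levels = c("NR", "R"))
  fit <- tryCatch(
    e1071::svm(x = X, y = yf, scale = FALSE,
               kernel = if (kernel == "rbf") "radial" else "linear",
               cost = C, gamma = if (is.null(gamma)) 1 / ncol(X) else gamma),
    error = function(e)
      stop(sprintf("SVM solver failed at C=%g, gamma=%s: %s", C,
                   ifelse(is.null(gamma), "default", format(gamma)),
                   conditionMessage(e))))
  # libsvm's decision value is positive for the first factor level; with
  # levels (NR, R) the sign convention can still flip depending on which
  # class appears first in the data, so read it off the column name.
  dv1 <- attr(stats::predict(fit, X[1, , drop = FALSE],
                             decision.values = TRUE), "decision.values")
  flip <- !startsWith(colnames(dv1)[1L], "NR")
  fam <- if (kernel == "rbf") "SVM-RBF" else "SVM-Lin"
  new_model(fam, function(M) {
    dv <- attr(stats::predict(fit, M, decision.values = TRUE),
               "decision.values")
    s <- as.numeric(dv[, 1L])
    if (flip) -s else s
  }, params = list(C = C, gamma = gamma, fit = fit))
}

#' k-nearest-neighbor classification of one test point
#'
#' Euclidean distances on (already standardized) features; the predicted
#' label is the majority among the k nearest training rows. The decision
#' score is the fraction of non-responders among the k (useful for ROC); a
#' tie in votes predicts NR (the positive class), and ties in distance are
#' broken toward the lower row index.
#'
#' @param train_X Standardized training matrix.
#' @param train_y Labels.
#' @param test_x One test row (vector or 1-row matrix).
#' @param k Number of neighbors, \code{k <= nrow(train_X)}.
#' @return List with \code{label} and \code{score} (fraction NR in 0..1).
#' @export
knn_fit_predict <- function(train_X, train_y, test_x, k) {
  train_X <- as.matrix(train_X)
  if (k > nrow(train_X))
    stop(sprintf("k = %d exceeds %d training rows", k, nrow(train_X)))
  d2 <- colSums((t(train_X) - as.numeric(test_x))^2)
  nn <- order(d2)[seq_len(k)]          # stable: distance ties -> lower index
  frac_nr <- mean(train_y[nn] == "NR")
  list(label = if (frac_nr >= 0.5) "NR" else "R", score = frac_nr)
}

knn_model <- function(train_X, train_y, k) {
  train_X <- as.matrix(train_X)
  new_model("kNN", function(M) {
    apply(as.matrix(M), 1L, function(x)
      knn_fit_predict(train_X, train_y, x, k)$score - 0.5)
  }, tie_ge = TRUE, params = list(k = k))
}

# Dispatch: fit one model of `family` with concrete hyperparameters on
# standardized data.
fit_family <- function(family, X, y, params = list()) {
  switch(family,
         "FLD" = fld_fit(X, y),
         "SVM-Lin" = svm_fit(X, y, "linear", C = params$C %||% 2),
         "SVM-RBF" = svm_fit(X, y, "rbf", C = params$C %||% 2,
                             gamma = params$gamma %||% 1 / ncol(as.matrix(X))),
         "kNN" = knn_model(X, y, params$k %||% 1L),
         stop(sprintf("unknown classifier family '%s'", family)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
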