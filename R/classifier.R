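# Random-forest phenotype classification from baseline features.

#' Random-forest hyperparameters
#'
#' @param ntree Number of trees (default 500).
#' @param mtry Features per split (default `floor(sqrt(p))`).
#' @param min_node Minimum node size (default 1: trees grown to purity).
#' @param class_weighted Use class-frequency-weighted bootstrap sampling
#'   so minority phenotypes are not swamped (default TRUE).
#' @return List of class `ms_rf_params`.
#' @export
rf_params <- function(ntree = 500, mtry = NULL, min_node = 1,
                      class_weighted = TRUE) {
  structure(list(ntree = ntree, mtry = mtry, min_node = min_node,
                 class_weighted = class_weighted),
            class = "ms_rf_params")
}

rf_fit <- function(X, y, params, seed) {
  X <- as.matrix(X)
  classes <- sort(unique(y))
  yi <- match(y, classes) - 1L
  mtry <- if (is.null(params$mtry)) max(1L, floor(sqrt(ncol(X)))) else params$mtry
  cw <- if (params$class_weighted) {
    freq <- table(factor(y, levels = classes))
    as.numeric(1 / freq[y])
  } else rep(1, length(y))
  trees <- with_seed(seed, {
    .rf_train_cpp(X, yi, length(classes), params$ntree, mtry,
                  params$min_node, cw)
  })
  structure(list(trees = trees, classes = classes,
                 feature_names = colnames(X), params = params),
            class = "ms_rf")
}

rf_predict <- function(fit, X, type = c("class", "prob")) {
  type <- match.arg(type)
  X <- as.matrix(X)
  if (!identical(colnames(X), fit$feature_names)) {
    missing <- setdiff(fit$feature_names, colnames(X))
    extra <- setdiff(colnames(X), fit$feature_names)
    stop("schema mismatch: missing features [",
         paste(missing, collapse = ", "), "]; extra features [",
         paste(extra, collapse = ", "), "]")
  }
  P <- .rf_predict_cpp(fit$trees, X, length(fit$classes))
  colnames(P) <- fit$classes
  if (type == "prob") return(P)
  fit$classes[max.col(P, ties.method = "first")]
}

# Stratified split: within each class, a seeded 70/30 partition.
stratified_split <- function(y, split, seed) {
  with_seed(seed, {
    train <- logical(length(y))
    for (cl in unique(y)) {
      idx <- which(y == cl)
      n_tr <- round(split * length(idx))
      if (n_tr < 1 || n_tr >= length(idx)) {
        stop("stratification error: class '", cl,
             "' too small for a ", split, " split")
      }
      train[sample(idx, n_tr)] <- TRUE
    }
    train
  })
}

#' Train a phenotype classifier on baseline features
#'
#' Trains a random forest to predict disability worsening phenotype from
#' baseline clinical and MRI features, using a stratified patient-level
#' 70/30 train/test split, and evaluates accuracy, per-class precision
#' and recall, and permutation importance on the held-out test set.
#'
#' @param baseline Baseline table (one row per patient).
#' @param labels Character phenotype labels aligned with `baseline` rows
#'   (modal posterior assignments of the untreated cohort).
#' @param split Training fraction (default 0.7).
#' @param seed Seed for split, forest, and permutations.
#' @param params [rf_params()].
#' @param importance_repeats Permutations per feature (default 20).
#' @return List of class `ms_classifier`: `fit`, `report`
#'   (accuracy, majority_baseline, per_class, importance, split_seed),
#'   `train_idx`.
#' @export
train_classifier <- function(baseline, labels, split = 0.7, seed = 1L,
                             params = rf_params(), importance_repeats = 20) {
  if (length(unique(labels)) < 2) stop("input error: need >= 2 classes")
  X <- baseline_design(baseline)
  train <- stratified_split(labels, split, seed)
  fit <- rf_fit(X[train, ], labels[train], params, substream_seed(seed, 1L))
  pred <- rf_predict(fit, X[!train, ])
  truth <- labels[!train]
  acc <- mean(pred == truth)
  per_class <- do.call(rbind, lapply(fit$classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    data.frame(class = cl,
               precision = if (sum(pred == cl)) tp / sum(pred == cl) else NA,
               recall = if (sum(truth == cl)) tp / sum(truth == cl) else NA,
               n_test = sum(truth == cl), stringsAsFactors = FALSE)
  }))
  imp <- permutation_importance(fit, X[!train, ], truth,
                                n_repeats = importance_repeats,
                                seed = substream_seed(seed, 2L))
  structure(list(
    fit = fit,
    report = list(accuracy = acc,
                  majority_baseline = max(table(truth)) / length(truth),
                  per_class = per_class,
                  importance = imp,
                  split_seed = seed),
    train_idx = which(train)
  ), class = "ms_classifier")
}

#' @export
print.ms_classifier <- function(x, ...) {
  cat(sprintf("ms_classifier: accuracy %.3f (majority baseline %.3f)\n",
              x$report$accuracy, x$report$majority_baseline))
  invisible(x)
}

#' Permutation-based feature importance
#'
#' For each feature, the mean decrease in held-out accuracy over
#' `n_repeats` independent permutations of that feature's test-set
#' column, expressed as a percentage-point accuracy drop and as a share
#' of total (positive) importance.
#'
#' @param fit An `ms_rf` forest (from inside [train_classifier()]).
#' @param X_test Test-set design matrix / data.frame.
#' @param y_test Test-set labels.
#' @param n_repeats Permutations per feature.
#' @param seed Seed.
#' @return data.frame: `feature`, `importance_pct` (accuracy drop x 100),
#'   `share` (of summed positive importance).
#' @export
permutation_importance <- function(fit, X_test, y_test, n_repeats = 20,
                                   seed = 1L) {
  X_test <- as.matrix(X_test)
  base_acc <- mean(rf_predict(fit, X_test) == y_test)
  drops <- with_seed(seed, {
    vapply(seq_len(ncol(X_test)), function(j) {
      mean(vapply(seq_len(n_repeats), function(r) {
        Xp <- X_test
        Xp[, j] <- Xp[sample.int(nrow(Xp)), j]
        base_acc - mean(rf_predict(fit, Xp) == y_test)
      }, numeric(1)))
    }, numeric(1))
  })
  pos <- pmax(drops, 0)
  data.frame(feature = colnames(X_test),
             importance_pct = 100 * drops,
             share = if (sum(pos) > 0) pos / sum(pos) else rep(0, length(pos)),
             stringsAsFactors = FALSE)
}

#' Assign phenotypes to treated patients
#'
#' Applies the trained classifier to baseline features of (treated)
#' patients not used in training.
#'
#' @param classifier An `ms_classifier`.
#' @param baseline Baseline table with the training feature schema.
#' @return data.frame: `patient_id`, `label`, probability columns
#'   `p_<class>`, plus a `frequencies` attribute (class proportion table).
#' @export
assign_phenotypes <- function(classifier, baseline) {
  X <- baseline_design(baseline)
  P <- rf_predict(classifier$fit, X, type = "prob")
  lab <- classifier$fit$classes[max.col(P, ties.method = "first")]
  out <- data.frame(patient_id = baseline$patient_id, label = lab,
                    stringsAsFactors = FALSE)
  Pd <- as.data.frame(P)
  names(Pd) <- paste0("p_", colnames(P))
  out <- cbind(out, Pd)
  attr(out, "frequencies") <- table(lab) / nrow(out)
  out
}
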