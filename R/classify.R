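# Cross-validated, PCA-reduced classification of subjects from VOI-averaged
# CPC elements. All preprocessing statistics (median imputation,
# standardization, PCA rotation) and hyperparameter selection are computed
# on training folds only; the held-out fold never enters the fit path.

CPC_ML_ELEMENTS <- c("F_gg", "F_cc", "F_gc", "F_cg")

#' Select CPC element features for classification
#'
#' Restricts the wide feature matrix to the requested CPC elements (the four
#' atrophy-related elements `F_gg`, `F_cc`, `F_gc`, `F_cg`, or any subset)
#' across all regions. `"combined"` selects all four. Missing values are left
#' as `NA`; they are imputed from training-fold medians inside
#' [cross_validate()].
#'
#' @param features A [voi_feature_table()].
#' @param elements Character subset of `c("F_gg","F_cc","F_gc","F_cg")`, or
#'   `"combined"`.
#' @return List: `x` (subjects x features numeric matrix), `group` (factor),
#'   `subject_id`.
#' @export
select_features <- function(features, elements = "combined") {
  if (length(elements) == 0L) stopf("empty element selection")
  if (identical(elements, "combined")) elements <- CPC_ML_ELEMENTS
  unknown <- setdiff(elements, CPC_ML_ELEMENTS)
  if (length(unknown) > 0L) {
    stopf("unknown element(s): %s (allowed: %s or \"combined\")",
          paste(unknown, collapse = ", "),
          paste(CPC_ML_ELEMENTS, collapse = ", "))
  }
  missing_el <- setdiff(elements, unique(features$element))
  if (length(missing_el) > 0L) {
    stopf("element(s) absent from the feature table: %s",
          paste(missing_el, collapse = ", "))
  }
  wide <- feature_wide(features[features$element %in% elements, , drop = FALSE])
  x <- as.matrix(wide[, -(1:2), drop = FALSE])
  rownames(x) <- wide$subject_id
  list(x = x, group = factor(wide$group), subject_id = wide$subject_id)
}

#' Classifier and cross-validation specification
#'
#' @param model `"svm_linear"`, `"svm_rbf"`, `"rf"` or `"gbc"`.
#' @param grid Named list of hyperparameter candidate vectors; defaults from
#'   [default_grid()]. Must include `n_components` (PCA dimensions;
#'   `NA` = keep all).
#' @param n_folds Outer stratified folds (default 15); must not exceed the
#'   smallest class size.
#' @param nested If `TRUE` (default) hyperparameters are selected by inner
#'   cross-validation on each training fold; if `FALSE` the first grid point
#'   is used as-is (useful for fixed-parameter runs such as permutation
#'   nulls).
#' @param inner_folds Inner folds for nested selection.
#' @param seed RNG seed controlling fold assignment and stochastic learners.
#' @return Object of class `classifier_spec`.
#' @export
classifier_spec <- function(model = c("svm_linear", "svm_rbf", "rf", "gbc"),
                            grid = NULL, n_folds = 15L, nested = TRUE,
                            inner_folds = 5L, seed = 1L) {
  model <- match.arg(model)
  if (is.null(grid)) grid <- default_grid(model)
  if (is.null(grid$n_components)) grid$n_components <- NA_integer_
  if (n_folds < 2L) stopf("n_folds must be >= 2")
  structure(list(model = model, grid = grid, n_folds = as.integer(n_folds),
                 nested = nested, inner_folds = as.integer(inner_folds),
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Default hyperparameter grids
#'
#' Standard decades around the common defaults: `C` in 10^(-2..2), `gamma`
#' log-spaced in 10^(-4..0), 100-500 trees, depth 2-5, class weights
#' balanced or none, and PCA components in {2, 5, 10, 20, all}.
#'
#' @param model Model name as in [classifier_spec()].
#' @return Named list of candidate vectors.
#' @export
default_grid <- function(model) {
  pca <- c(2L, 5L, 10L, 20L, NA_integer_)
  switch(model,
    svm_linear = list(C = c(0.01, 0.1, 1, 10, 100), n_components = pca),
    svm_rbf = list(C = c(0.01, 0.1, 1, 10, 100), gamma = 10^seq(-4, 0),
                   n_components = pca),
    rf = list(n_estimators = c(100L, 300L, 500L),
              class_weight = c("balanced", "none"), n_components = pca),
    gbc = list(n_estimators = c(100L, 300L, 500L), max_depth = c(2L, 3L, 5L),
               n_components = pca),
    stopf("unknown model '%s'", model))
}

# Stratified fold ids: within each class, shuffled indices are dealt
# round-robin, so every fold holds at least one subject of each class
# whenever k <= min class size.
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# Preprocessing fitted on training rows only: median imputation,
# standardization, PCA truncation.
fit_preproc <- function(x_train, n_components) {
  med <- apply(x_train, 2L, median, na.rm = TRUE)
  med[is.na(med)] <- 0
  impute <- function(x) {
    for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- med[j]
    x
  }
  x_train <- impute(x_train)
  mu <- colMeans(x_train)
  sdev <- apply(x_train, 2L, sd)
  sdev[sdev < 1e-12] <- 1
  xs <- sweep(sweep(x_train, 2L, mu), 2L, sdev, `/`)
  pca <- prcomp(xs, center = FALSE, scale. = FALSE)
  k <- if (is.na(n_components)) ncol(pca$rotation) else
    min(n_components, ncol(pca$rotation))
  rot <- pca$rotation[, seq_len(k), drop = FALSE]
  transform <- function(x) {
    xs <- sweep(sweep(impute(x), 2L, mu), 2L, sdev, `/`)
    xs %*% rot
  }
  list(transform = transform, train_scores = xs %*% rot)
}

fit_model <- function(model, x, y, params, seed) {
  switch(model,
    svm_linear = svm_train(x, y, C = params$C, kernel = "linear"),
    svm_rbf = svm_train(x, y, C = params$C, kernel = "rbf",
                        gamma = params$gamma),
    rf = rf_train(x, y, n_estimators = params$n_estimators,
                  class_weight = params$class_weight, seed = seed),
    gbc = gbc_train(x, y, n_estimators = params$n_estimators,
                    max_depth = params$max_depth))
}

grid_points <- function(grid) {
  g <- expand.grid(grid, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(g)), function(i) as.list(g[i, , drop = FALSE]))
}

#' Classification metrics from a confusion matrix
#'
#' `ACC = (TP+TN)/(TP+TN+FP+FN)`, `SEN = TP/(TP+FN)` (true-positive rate on
#' the clinically positive class), `SPE = TN/(TN+FP)`.
#'
#' @param tp,fn,tn,fp Confusion matrix counts.
#' @return Named numeric vector `c(acc, sen, spe)`.
#' @export
classification_metrics <- function(tp, fn, tn, fp) {
  c(acc = (tp + tn) / (tp + tn + fp + fn),
    sen = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    spe = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

confusion_counts <- function(truth, pred, positive) {
  c(tp = sum(truth == positive & pred == positive),
    fn = sum(truth == positive & pred != positive),
    tn = sum(truth != positive & pred != positive),
    fp = sum(truth != positive & pred == positive))
}

# Mean accuracy of one grid point under inner CV on the training fold.
inner_cv_acc <- function(x, y, model, params, inner_folds, seed) {
  k <- min(inner_folds, min(table(y)))
  if (k < 2L) return(NA_real_)
  fold <- stratified_folds(y, k, seed)
  accs <- vapply(seq_len(k), function(f) {
    tr <- fold != f
    pp <- fit_preproc(x[tr, , drop = FALSE], params$n_components)
    fit <- fit_model(model, pp$train_scores, y[tr], params, seed)
    pred <- predict(fit, pp$transform(x[!tr, , drop = FALSE]))
    mean(pred == y[!tr])
  }, numeric(1))
  mean(accs)
}

#' Cross-validated classification of a two-class cohort
#'
#' Stratified `n_folds`-fold cross-validation. Per outer fold the training
#' data alone drive imputation, standardization, PCA, and (when `nested`)
#' inner-CV grid search; the selected model is refitted on the full training
#' fold and evaluated on the held-out subjects. Reported ACC/SEN/SPE are
#' means over folds; sensitivity is computed on the positive class (the
#' second factor level, conventionally the clinical group).
#'
#' @param x Feature matrix (e.g. `select_features()$x`).
#' @param y Two-level factor; second level = positive class.
#' @param spec A [classifier_spec()].
#' @return Object of class `classification_report`: fields `acc`, `sen`,
#'   `spe`, `per_fold`, `fold_assignments`, `selected` (chosen grid point
#'   per fold), `pooled` (metrics over pooled predictions), `model`, `seed`.
#' @export
cross_validate <- function(x, y, spec) {
  stopifnot(inherits(spec, "classifier_spec"))
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2L) stopf("cross_validate requires exactly 2 classes")
  if (spec$n_folds > min(table(y))) {
    stopf("n_folds (%d) exceeds the smallest class size (%d)",
          spec$n_folds, min(table(y)))
  }
  positive <- levels(y)[2L]
  fold <- stratified_folds(y, spec$n_folds, spec$seed)
  points <- grid_points(spec$grid)
  per_fold <- vector("list", spec$n_folds)
  selected <- vector("list", spec$n_folds)
  pred_all <- factor(rep(NA_character_, length(y)), levels = levels(y))
  for (f in seq_len(spec$n_folds)) {
    tr <- fold != f
    x_tr <- x[tr, , drop = FALSE]
    y_tr <- y[tr]
    fold_seed <- spec$seed + 1009L * f
    best <- points[[1L]]
    if (spec$nested && length(points) > 1L) {
      accs <- vapply(points, function(p) {
        inner_cv_acc(x_tr, y_tr, spec$model, p, spec$inner_folds, fold_seed)
      }, numeric(1))
      best <- points[[which.max(accs)]]  # ties: first grid point
    }
    pp <- fit_preproc(x_tr, best$n_components)
    fit <- fit_model(spec$model, pp$train_scores, y_tr, best, fold_seed)
    pred <- predict(fit, pp$transform(x[!tr, , drop = FALSE]))
    pred_all[!tr] <- pred
    cc <- confusion_counts(y[!tr], pred, positive)
    per_fold[[f]] <- c(fold = f, cc, classification_metrics(
      cc["tp"], cc["fn"], cc["tn"], cc["fp"]))
    selected[[f]] <- best
  }
  per_fold <- as.data.frame(do.call(rbind, per_fold))
  cc_all <- confusion_counts(y, pred_all, positive)
  structure(list(
    model = spec$model,
    acc = mean(per_fold$acc), sen = mean(per_fold$sen, na.rm = TRUE),
    spe = mean(per_fold$spe, na.rm = TRUE),
    pooled = classification_metrics(cc_all["tp"], cc_all["fn"],
                                    cc_all["tn"], cc_all["fp"]),
    per_fold = per_fold, fold_assignments = fold, selected = selected,
    positive = positive, seed = spec$seed, nested = spec$nested),
    class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("%s (%s CV): ACC %.3f  SEN %.3f  SPE %.3f\n",
              x$model, if (x$nested) "nested" else "plain",
              x$acc, x$sen, x$spe))
  invisible(x)
}

#' Permutation null of cross-validated accuracy
#'
#' Repeats [cross_validate()] with the group labels randomly permuted. To
#' keep the null affordable the spec is run as given (use a singleton grid
#' and `nested = FALSE` for a fixed-parameter null).
#'
#' @param x Feature matrix.
#' @param y Two-level factor.
#' @param spec A [classifier_spec()].
#' @param n_perm Number of permutations.
#' @param seed Seed for the permutations.
#' @return Numeric vector of per-permutation mean fold accuracies.
#' @export
permutation_null <- function(x, y, spec, n_perm = 200L, seed = 1L) {
  y <- droplevels(as.factor(y))
  perm_seeds <- derive_seeds(seed, n_perm)
  vapply(seq_len(n_perm), function(i) {
    y_perm <- with_seed(perm_seeds[i], sample(y))
    spec$seed <- perm_seeds[i] %% 100000L
    cross_validate(x, y_perm, spec)$acc
  }, numeric(1))
}
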