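# Gaussian two-class feature table: n subjects per group, `p` regions, the
# four ML elements; class separation `delta` on every region's F_gc (the
# spatially distributed signature real atrophy produces).
gaussian_features <- function(n, p = 3L, delta = 0, sd = 1, seed = 1) {
  regions <- sprintf("reg%02d", seq_len(p))
  elements <- c("F_gg", "F_cc", "F_gc", "F_cg")
  with_seed(seed, {
    rows <- list()
    for (grp in c("NL", "AD")) for (i in seq_len(n)) {
      shift <- ifelse(grp == "AD", delta, 0)
      for (r in seq_along(regions)) for (el in elements) {
        mu <- if (el == "F_gc") shift else 0
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sprintf("%s%03d", grp, i), group = grp,
          region = regions[r], element = el,
          value = rnorm(1, mu, sd), n_voxels = 10L,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}
with_seed <- cpcmorph:::with_seed

test_that("select_features counts columns and validates names", {
  tab <- gaussian_features(3L, p = 5L)
  one <- select_features(tab, "F_cc")
  expect_identical(dim(one$x), c(6L, 5L))
  all4 <- select_features(tab, "combined")
  expect_identical(dim(all4$x), c(6L, 20L))
  expect_identical(levels(all4$group), c("AD", "NL"))
  expect_error(select_features(tab, "F_zz"), "unknown element")
  expect_error(select_features(tab, character(0)), "empty")
})

test_that("metric arithmetic matches the confusion-matrix definitions", {
  m <- classification_metrics(tp = 8, fn = 2, tn = 9, fp = 1)
  expect_equal(unname(m), c(0.85, 0.8, 0.9))
  expect_true(is.na(classification_metrics(0, 0, 5, 1)[["sen"]]))
})

test_that("SVM solves separable and soft-margin problems", {
  x <- rbind(matrix(rnorm(40, -3, 0.3), 20, 2), matrix(rnorm(40, 3, 0.3), 20, 2))
  y <- factor(rep(c("a", "b"), each = 20))
  fit <- svm_train(x, y, C = 1, kernel = "linear")
  expect_identical(predict(fit, x), y)
  # decision boundary of the symmetric pair sits at the midpoint
  fit2 <- svm_train(rbind(c(-1, 0), c(1, 0)), factor(c("a", "b")), C = 10)
  expect_equal(predict(fit2, rbind(c(-0.1, 5)), type = "decision"), -0.1,
               tolerance = 1e-4)
  # rbf kernel separates a circle-in-ring layout that is not linear
  set.seed(5)
  r <- c(runif(25, 0, 0.5), runif(25, 2, 2.5))
  th <- runif(50, 0, 2 * pi)
  xc <- cbind(r * cos(th), r * sin(th))
  yc <- factor(rep(c("in", "out"), each = 25))
  rfit <- svm_train(xc, yc, C = 10, kernel = "rbf", gamma = 1)
  expect_gt(mean(predict(rfit, xc) == yc), 0.95)
  lfit <- svm_train(xc, yc, C = 10, kernel = "linear")
  expect_lt(mean(predict(lfit, xc) == yc), 0.8)
})

test_that("random forest and gradient boosting learn nonlinear labels", {
  set.seed(6)
  x <- matrix(runif(300, -1, 1), 150, 2)
  y <- factor(ifelse(x[, 1] * x[, 2] > 0, "pos", "neg"),
              levels = c("neg", "pos"))  # XOR: not linearly separable
  rf <- rf_train(x, y, n_estimators = 60L, seed = 3L)
  expect_gt(mean(predict(rf, x) == y), 0.95)
  rf2 <- rf_train(x, y, n_estimators = 60L, seed = 3L)
  expect_identical(predict(rf, x, type = "prob"), predict(rf2, x, type = "prob"))
  gb <- gbc_train(x, y, n_estimators = 80L, max_depth = 3L)
  expect_gt(mean(predict(gb, x) == y), 0.95)
  p <- predict(gb, x, type = "prob")
  expect_true(all(p >= 0 & p <= 1))
})

test_that("stratified folds partition subjects and keep both classes", {
  y <- factor(rep(c("NL", "AD"), c(20, 20)))
  fold <- cpcmorph:::stratified_folds(y, 15L, seed = 9L)
  expect_identical(sort(unique(fold)), 1:15)
  for (f in 1:15) {
    expect_identical(nlevels(droplevels(y[fold == f])), 2L)
  }
  expect_identical(length(fold), 40L)  # every subject in exactly one fold
})

test_that("cross-validation separates a separable cohort perfectly", {
  tab <- gaussian_features(20L, delta = 12, sd = 0.5, seed = 2)
  sel <- select_features(tab, "combined")
  grp <- factor(sel$group, levels = c("NL", "AD"))
  spec <- classifier_spec("svm_linear", n_folds = 15L, seed = 4L,
                          grid = list(C = c(0.1, 1), n_components = c(2L, NA)))
  rep1 <- cross_validate(sel$x, grp, spec)
  expect_equal(rep1$acc, 1)
  expect_equal(rep1$sen, 1)
  expect_equal(rep1$spe, 1)
  expect_identical(rep1$positive, "AD")
  rep2 <- cross_validate(sel$x, grp, spec)
  expect_identical(rep1$fold_assignments, rep2$fold_assignments)
  expect_identical(rep1$per_fold, rep2$per_fold)
  expect_error(cross_validate(sel$x, grp,
                              classifier_spec("svm_linear", n_folds = 30L)),
               "smallest class")
})

test_that("training folds never see test-fold information", {
  # canary: a feature equal to the label is learned perfectly
  tab <- gaussian_features(10L, delta = 0, sd = 1, seed = 8)
  sel <- select_features(tab, "combined")
  grp <- factor(sel$group, levels = c("NL", "AD"))
  canary <- cbind(sel$x, canary = as.numeric(grp == "AD"))
  spec <- classifier_spec("svm_linear", n_folds = 5L, nested = FALSE,
                          grid = list(C = 10, n_components = NA), seed = 1L)
  expect_equal(cross_validate(canary, grp, spec)$acc, 1)
  # fold-1 confusion counts must equal a hand-built train-only pipeline:
  # median-impute, standardize and fit on the training rows alone
  rep0 <- cross_validate(sel$x, grp, spec)
  fold <- cpcmorph:::stratified_folds(grp, 5L, seed = 1L)
  tr <- fold != 1L
  mu <- colMeans(sel$x[tr, ])
  sdev <- apply(sel$x[tr, ], 2, sd)
  sdev[sdev < 1e-12] <- 1
  scale_rows <- function(m) sweep(sweep(m, 2, mu), 2, sdev, `/`)
  fit <- svm_train(scale_rows(sel$x[tr, ]), grp[tr], C = 10)
  pred <- predict(fit, scale_rows(sel$x[!tr, , drop = FALSE]))
  expect_equal(rep0$per_fold$tp[1], sum(pred == "AD" & grp[!tr] == "AD"))
  expect_equal(rep0$per_fold$tn[1], sum(pred == "NL" & grp[!tr] == "NL"))
})

test_that("imputation is leakage-safe and median-based", {
  tab <- gaussian_features(10L, delta = 12, sd = 0.5, seed = 12)
  sel <- select_features(tab, "combined")
  x <- sel$x
  # missing entries in uninformative columns only: imputation must not
  # disturb the separable signal carried by reg01|F_gc
  x[1, "reg02|F_cc"] <- NA
  x[15, "reg03|F_gg"] <- NA
  grp <- factor(sel$group, levels = c("NL", "AD"))
  spec <- classifier_spec("svm_linear", n_folds = 5L, nested = FALSE,
                          grid = list(C = 1, n_components = NA), seed = 2L)
  expect_equal(cross_validate(x, grp, spec)$acc, 1)
})

test_that("permuted labels drive accuracy to chance", {
  tab <- gaussian_features(20L, delta = 12, sd = 0.5, seed = 3)
  sel <- select_features(tab, "combined")
  grp <- factor(sel$group, levels = c("NL", "AD"))
  spec <- classifier_spec("svm_linear", n_folds = 10L, nested = FALSE,
                          grid = list(C = 1, n_components = 5L), seed = 5L)
  accs <- permutation_null(sel$x, grp, spec, n_perm = 40L, seed = 6L)
  expect_lt(abs(mean(accs) - 0.5), 0.08)
})

test_that("nested grid search tunes the rbf and tree models", {
  tab <- gaussian_features(16L, delta = 10, sd = 0.5, seed = 10)
  sel <- select_features(tab, "combined")
  grp <- factor(sel$group, levels = c("NL", "AD"))
  for (model in c("svm_rbf", "rf", "gbc")) {
    grid <- switch(model,
      svm_rbf = list(C = c(1, 10), gamma = c(0.01, 0.1), n_components = 3L),
      rf = list(n_estimators = 30L, class_weight = c("balanced", "none"),
                n_components = 3L),
      gbc = list(n_estimators = 30L, max_depth = c(2L, 3L), n_components = 3L))
    spec <- classifier_spec(model, grid = grid, n_folds = 4L,
                            inner_folds = 3L, seed = 11L)
    rep <- cross_validate(sel$x, grp, spec)
    expect_gt(rep$acc, 0.8)
    expect_length(rep$selected, 4L)
  }
})
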