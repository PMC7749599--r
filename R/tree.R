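# Small CART-style trees and the ensembles built on them: bagged trees with
# feature subsampling (random forest) and logistic gradient boosting. Pure
# R, exhaustive axis-aligned split search; intended for the modest sample
# sizes of VOI feature tables.

# Best threshold split of x for weighted two-class gini ("class", y in {0,1})
# or weighted squared error ("reg", y numeric). Returns NULL if no split.
best_split <- function(x, y, w, type) {
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]; ws <- w[ord]
  n <- length(xs)
  cuts <- which(diff(xs) > 0)
  if (length(cuts) == 0L) return(NULL)
  cw <- cumsum(ws)
  W <- cw[n]
  if (type == "class") {
    cw1 <- cumsum(ws * ys)
    imp <- function(wt, w1) {
      p <- w1 / wt
      wt * (1 - p^2 - (1 - p)^2)
    }
    score <- imp(cw[cuts], cw1[cuts]) + imp(W - cw[cuts], cw1[n] - cw1[cuts])
  } else {
    cwy <- cumsum(ws * ys)
    cwy2 <- cumsum(ws * ys^2)
    sse <- function(wt, wy, wy2) wy2 - wy^2 / wt
    score <- sse(cw[cuts], cwy[cuts], cwy2[cuts]) +
      sse(W - cw[cuts], cwy[n] - cwy[cuts], cwy2[n] - cwy2[cuts])
  }
  k <- cuts[which.min(score)]
  list(cut = (xs[k] + xs[k + 1]) / 2, score = min(score))
}

# Recursive CART. y: 0/1 for classification, numeric for regression.
# mtry features are drawn per node when mtry < p (random forest).
cart_fit <- function(x, y, w = NULL, type = c("class", "reg"),
                     max_depth = 10L, min_split = 2L, mtry = ncol(x)) {
  type <- match.arg(type)
  x <- as.matrix(x)
  if (is.null(w)) w <- rep(1, nrow(x))
  grow <- function(idx, depth) {
    yy <- y[idx]; ww <- w[idx]
    pred <- if (type == "class") sum(ww * yy) / sum(ww) else
      sum(ww * yy) / sum(ww)
    node <- list(leaf = TRUE, pred = pred, n = length(idx), idx = idx)
    if (depth >= max_depth || length(idx) < min_split ||
        length(unique(yy)) == 1L) {
      return(node)
    }
    feats <- if (mtry < ncol(x)) sample.int(ncol(x), mtry) else seq_len(ncol(x))
    best <- NULL
    for (j in feats) {
      s <- best_split(x[idx, j], yy, ww, type)
      if (!is.null(s) && (is.null(best) || s$score < best$score)) {
        best <- c(s, var = j)
      }
    }
    if (is.null(best)) return(node)
    left <- idx[x[idx, best$var] <= best$cut]
    right <- setdiff(idx, left)
    if (length(left) == 0L || length(right) == 0L) return(node)
    list(leaf = FALSE, var = best$var, cut = best$cut,
         left = grow(left, depth + 1L), right = grow(right, depth + 1L))
  }
  structure(list(root = grow(seq_len(nrow(x)), 0L), type = type),
            class = "cpc_cart")
}

# Per-row predictions: class-1 probability (class) or leaf mean (reg).
cart_predict <- function(tree, x) {
  x <- as.matrix(x)
  one <- function(row) {
    node <- tree$root
    while (!node$leaf) {
      node <- if (row[node$var] <= node$cut) node$left else node$right
    }
    node$pred
  }
  apply(x, 1L, one)
}

# Leaf membership ids, for per-leaf Newton steps in boosting.
cart_leaf_ids <- function(tree, x) {
  x <- as.matrix(x)
  one <- function(row) {
    node <- tree$root
    path <- "r"
    while (!node$leaf) {
      go_left <- row[node$var] <= node$cut
      path <- paste0(path, if (go_left) "L" else "R")
      node <- if (go_left) node$left else node$right
    }
    path
  }
  apply(x, 1L, one)
}

#' Train a random forest classifier
#'
#' Bagged CART trees with per-node feature subsampling and majority vote.
#' With `class_weight = "balanced"` sample weights inversely proportional to
#' class frequency are used in the split criterion and leaf estimates.
#'
#' @param x Numeric feature matrix.
#' @param y Factor with 2 levels (second level = positive class).
#' @param n_estimators Number of trees.
#' @param mtry Features drawn per node; default `floor(sqrt(p))`.
#' @param max_depth Maximum tree depth.
#' @param class_weight `"none"` or `"balanced"`.
#' @param seed RNG seed (forest growth is stochastic).
#' @return Object of class `cpc_rf`.
#' @export
rf_train <- function(x, y, n_estimators = 100L, mtry = NULL, max_depth = 10L,
                     class_weight = "none", seed = 1L) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2L) stopf("rf_train requires exactly 2 classes")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  y01 <- as.numeric(y == levels(y)[2L])
  w <- rep(1, nrow(x))
  if (identical(class_weight, "balanced")) {
    tab <- table(y01)
    w <- nrow(x) / (2 * as.numeric(tab[as.character(y01)]))
  }
  trees <- with_seed(seed, {
    lapply(seq_len(n_estimators), function(i) {
      idx <- sample.int(nrow(x), replace = TRUE)
      cart_fit(x[idx, , drop = FALSE], y01[idx], w[idx], type = "class",
               max_depth = max_depth, mtry = mtry)
    })
  })
  structure(list(trees = trees, levels = levels(y)), class = "cpc_rf")
}

#' @export
predict.cpc_rf <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  p <- rowMeans(vapply(object$trees, cart_predict, numeric(nrow(as.matrix(newdata))),
                       x = newdata))
  if (type == "prob") return(p)
  factor(ifelse(p >= 0.5, object$levels[2L], object$levels[1L]),
         levels = object$levels)
}

#' Train a gradient boosting classifier
#'
#' Logistic-loss gradient boosting with depth-limited regression trees and
#' per-leaf Newton steps; deterministic given the data (no subsampling).
#'
#' @param x Numeric feature matrix.
#' @param y Factor with 2 levels (second level = positive class).
#' @param n_estimators Boosting rounds.
#' @param max_depth Depth of each tree.
#' @param learning_rate Shrinkage applied to each round.
#' @return Object of class `cpc_gbc`.
#' @export
gbc_train <- function(x, y, n_estimators = 100L, max_depth = 3L,
                      learning_rate = 0.1) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2L) stopf("gbc_train requires exactly 2 classes")
  y01 <- as.numeric(y == levels(y)[2L])
  p0 <- mean(y01)
  p0 <- min(max(p0, 1e-6), 1 - 1e-6)
  f0 <- log(p0 / (1 - p0))
  f <- rep(f0, nrow(x))
  rounds <- vector("list", n_estimators)
  for (m in seq_len(n_estimators)) {
    p <- 1 / (1 + exp(-f))
    resid <- y01 - p
    tree <- cart_fit(x, resid, type = "reg", max_depth = max_depth)
    ids <- cart_leaf_ids(tree, x)
    h <- pmax(p * (1 - p), 1e-12)
    gamma <- tapply(resid, ids, sum) / tapply(h, ids, sum)
    f <- f + learning_rate * as.numeric(gamma[ids])
    rounds[[m]] <- list(tree = tree, gamma = gamma)
    if (all(abs(resid) < 1e-10)) {
      rounds <- rounds[seq_len(m)]
      break
    }
  }
  structure(list(f0 = f0, rounds = rounds, learning_rate = learning_rate,
                 levels = levels(y)), class = "cpc_gbc")
}

#' @export
predict.cpc_gbc <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  f <- rep(object$f0, nrow(newdata))
  for (rd in object$rounds) {
    ids <- cart_leaf_ids(rd$tree, newdata)
    g <- rd$gamma[ids]
    g[is.na(g)] <- 0  # unseen leaf path: no contribution
    f <- f + object$learning_rate * as.numeric(g)
  }
  p <- 1 / (1 + exp(-f))
  if (type == "prob") return(p)
  factor(ifelse(p >= 0.5, object$levels[2L], object$levels[1L]),
         levels = object$levels)
}
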