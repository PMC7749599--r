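# Soft-margin support vector machine solved exactly through its dual
# quadratic program (quadprog). Adequate for the cohort sizes this package
# targets (tens of subjects); linear and RBF kernels.

svm_kernel <- function(X1, X2, kernel, gamma) {
  if (kernel == "linear") {
    X1 %*% t(X2)
  } else {
    d2 <- outer(rowSums(X1^2), rowSums(X2^2), `+`) - 2 * X1 %*% t(X2)
    exp(-gamma * pmax(d2, 0))
  }
}

#' Train a two-class support vector machine
#'
#' Maximizes the dual of the soft-margin SVM with [quadprog::solve.QP()];
#' a small ridge is added to the kernel matrix for numerical positive
#' definiteness. With `class_weight = "balanced"` each class's box
#' constraint is scaled inversely to its frequency.
#'
#' @param x Numeric feature matrix (rows = samples).
#' @param y Factor with exactly 2 levels; the second level is the positive
#'   class.
#' @param C Soft-margin cost.
#' @param kernel `"linear"` or `"rbf"`.
#' @param gamma RBF width; default `1 / ncol(x)`.
#' @param class_weight `"none"` or `"balanced"`.
#' @return Object of class `cpc_svm`.
#' @export
svm_train <- function(x, y, C = 1, kernel = c("linear", "rbf"),
                      gamma = NULL, class_weight = "none") {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2L) stopf("svm_train requires exactly 2 classes")
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  ysign <- ifelse(y == levels(y)[2L], 1, -1)
  n <- nrow(x)
  Cvec <- rep(C, n)
  if (identical(class_weight, "balanced")) {
    tab <- table(ysign)
    Cvec <- C * n / (2 * as.numeric(tab[as.character(ysign)]))
  }
  K <- svm_kernel(x, x, kernel, gamma)
  Q <- (ysign %o% ysign) * K
  # ridge for positive definiteness; grown when solve.QP reports numerical
  # trouble on ill-conditioned kernels (solution is capped by the box anyway)
  ridge <- 1e-8 * max(1, mean(diag(Q)))
  sol <- NULL
  for (i in 1:6) {
    sol <- tryCatch(
      quadprog::solve.QP(Dmat = Q + diag(ridge, n), dvec = rep(1, n),
                         Amat = cbind(ysign, diag(n), -diag(n)),
                         bvec = c(0, rep(0, n), -Cvec), meq = 1),
      error = function(e) NULL)
    if (!is.null(sol)) break
    ridge <- ridge * 100
  }
  if (is.null(sol)) stopf("SVM dual QP failed to solve")
  alpha <- pmin(pmax(sol$solution, 0), Cvec)
  f0 <- as.numeric(K %*% (alpha * ysign))
  margin <- alpha > 1e-6 & alpha < Cvec - 1e-6
  b <- if (any(margin)) mean(ysign[margin] - f0[margin]) else {
    lo <- suppressWarnings(max(f0[ysign == -1]))
    hi <- suppressWarnings(min(f0[ysign == 1]))
    if (is.finite(lo) && is.finite(hi)) -(lo + hi) / 2 else 0
  }
  sv <- alpha > 1e-8
  structure(list(x = x[sv, , drop = FALSE], coef = (alpha * ysign)[sv],
                 b = b, kernel = kernel, gamma = gamma, levels = levels(y)),
            class = "cpc_svm")
}

#' @export
predict.cpc_svm <- function(object, newdata, type = c("class", "decision"), ...) {
  type <- match.arg(type)
  K <- svm_kernel(as.matrix(newdata), object$x, object$kernel, object$gamma)
  f <- as.numeric(K %*% object$coef) + object$b
  if (type == "decision") return(f)
  factor(ifelse(f >= 0, object$levels[2L], object$levels[1L]),
         levels = object$levels)
}
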