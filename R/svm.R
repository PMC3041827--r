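# Soft-margin SVM with a radial-basis kernel, trained by an in-package SMO
# solver (no external SVM library is assumed). The solver works on the
# precomputed kernel matrix; problem sizes here (hundreds to a few thousand
# rows) fit it comfortably.

#' RBF kernel matrix
#'
#' `exp(-gamma * ||x - y||^2)` between the rows of two matrices.
#'
#' @param X,Y numeric matrices with the same number of columns.
#' @param gamma positive kernel width parameter.
#' @return `nrow(X)` x `nrow(Y)` kernel matrix.
#' @export
rbf_kernel <- function(X, Y = X, gamma) {
  stopifnot(ncol(X) == ncol(Y), gamma > 0)
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  exp(-gamma * pmax(d2, 0))
}

#' Fit a soft-margin RBF-kernel SVM
#'
#' @param X numeric training matrix (rows = samples), already scaled.
#' @param y class labels (+1/-1 after coercion); both classes required.
#' @param C soft-margin cost (> 0).
#' @param gamma RBF kernel width (> 0).
#' @param class_weight optional named vector `c(positive = , negative = )`
#'   multiplying `C` per class; default unweighted.
#' @param eps SMO duality-gap stopping tolerance.
#' @return `rbf_svm` object: support-vector coefficients (`alpha * y`),
#'   support vectors, intercept `b`, `C`, `gamma`.
#' @export
rbf_svm_fit <- function(X, y, C, gamma, class_weight = NULL, eps = 1e-3) {
  stopifnot(is.matrix(X), C > 0, gamma > 0)
  y <- as_class_labels(y)
  stopifnot(length(y) == nrow(X))
  if (length(unique(y)) < 2L) stop("training data contain a single class")
  wpos <- wneg <- 1
  if (!is.null(class_weight)) {
    wpos <- class_weight[["positive"]]
    wneg <- class_weight[["negative"]]
  }
  K <- rbf_kernel(X, X, gamma)
  sol <- .smo_solve(K, as.integer(y), C * wpos, C * wneg)
  sv <- sol$alpha > 1e-8
  structure(list(coef = sol$alpha[sv] * y[sv], sv = X[sv, , drop = FALSE],
                 b = sol$b, C = C, gamma = gamma,
                 iterations = sol$iterations),
            class = "rbf_svm")
}

#' Decision values of a fitted RBF SVM
#'
#' @param fit an `rbf_svm` object.
#' @param X matrix of rows to score (same columns/scaling as training).
#' @return numeric decision scores; the predicted label is +1 for
#'   `score >= 0`, -1 otherwise.
#' @export
rbf_svm_decision <- function(fit, X) {
  stopifnot(inherits(fit, "rbf_svm"), is.matrix(X), ncol(X) == ncol(fit$sv))
  drop(rbf_kernel(X, fit$sv, fit$gamma) %*% fit$coef) + fit$b
}

#' @export
print.rbf_svm <- function(x, ...) {
  cat(sprintf("<rbf_svm> C=%g gamma=%g, %d support vectors\n",
              x$C, x$gamma, nrow(x$sv)))
  invisible(x)
}

# min-max or z-score scaling fitted on training data only
fit_scaler <- function(X, method = c("minmax", "zscore", "none")) {
  method <- match.arg(method)
  if (method == "none") {
    par <- list(center = rep(0, ncol(X)), scale = rep(1, ncol(X)))
  } else if (method == "minmax") {
    lo <- apply(X, 2, min)
    hi <- apply(X, 2, max)
    rng <- hi - lo
    rng[rng == 0] <- 1  # constant feature maps to 0
    par <- list(center = lo, scale = rng)
  } else {
    mu <- colMeans(X)
    sd <- apply(X, 2, stats::sd)
    sd[sd == 0] <- 1
    par <- list(center = mu, scale = sd)
  }
  par$method <- method
  par
}

apply_scaler <- function(scaler, X) {
  sweep(sweep(X, 2, scaler$center, "-"), 2, scaler$scale, "/")
}
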