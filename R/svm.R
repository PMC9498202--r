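#' Train a Gaussian-kernel soft-margin SVM
#'
#' Solves the C-classification dual with kernel
#' `K(x, z) = exp(-||x - z||^2 / sigma^2)` where `sigma` is the kernel
#' scale, and regularisation `C` the box constraint. The quadratic program
#' is solved by libsvm (via e1071); features are expected to be
#' standardised upstream, so internal rescaling is disabled.
#'
#' @param train_X Numeric matrix of training rows.
#' @param train_y `"healthy"` / `"septic"` per row; both classes required.
#' @param kernel_scale Positive kernel width `sigma`.
#' @param box_constraint Positive box constraint `C`.
#' @return An object of class `svm_model` wrapping the fit.
#' @export
svm_train <- function(train_X, train_y, kernel_scale = 1,
                      box_constraint = 1) {
  train_X <- as.matrix(train_X)
  if (!all(is.finite(train_X))) stop("non-finite features", call. = FALSE)
  if (length(unique(train_y)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  if (kernel_scale <= 0 || box_constraint <= 0) {
    stop("kernel_scale and box_constraint must be positive", call. = FALSE)
  }
  fit <- e1071::svm(
    x = train_X, y = factor(train_y, levels = c("healthy", "septic")),
    type = "C-classification", kernel = "radial",
    gamma = 1 / kernel_scale^2, cost = box_constraint, scale = FALSE
  )
  structure(
    list(fit = fit, kernel_scale = kernel_scale,
         box_constraint = box_constraint, n_features = ncol(train_X)),
    class = "svm_model"
  )
}

#' @export
predict.svm_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features) {
    stop("query dimensionality differs from training", call. = FALSE)
  }
  as.character(predict(object$fit, newdata))
}

#' Gaussian kernel matrix
#'
#' `K[i, j] = exp(-||x_i - z_j||^2 / sigma^2)`; exposed for kernel
#' diagnostics (e.g. positive-semidefiniteness checks).
#'
#' @param X,Z Row-wise data matrices (Z defaults to X).
#' @param kernel_scale Kernel width `sigma`.
#' @return `nrow(X) x nrow(Z)` kernel matrix.
#' @export
gaussian_kernel <- function(X, Z = X, kernel_scale = 1) {
  X <- as.matrix(X); Z <- as.matrix(Z)
  d2 <- outer(rowSums(X^2), rowSums(Z^2), `+`) - 2 * X %*% t(Z)
  exp(-pmax(d2, 0) / kernel_scale^2)
}
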