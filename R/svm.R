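# Linear maximum-margin classifier: L2-regularized squared-hinge SVM.
# Convex objective solved by BFGS with analytic gradients -> deterministic
# for a fixed input, which the cross-validation determinism contract needs.

#' Fit a linear maximum-margin classifier
#'
#' Minimizes 0.5 ||w||^2 + C sum_i max(0, 1 - y_i (x_i w + b))^2 — the
#' squared-hinge soft-margin linear SVM.
#'
#' @param x Samples x features numeric matrix.
#' @param y Labels in \{-1, +1\}.
#' @param cost Regularization constant C > 0 (default 1).
#' @return Object of class `linear_svm` with weights `w` (named by
#'   feature) and intercept `b`.
#' @export
linear_svm <- function(x, y, cost = 1) {
  x <- as.matrix(x)
  if (!all(y %in% c(-1, 1))) abort("labels must be -1 / +1")
  if (length(unique(y)) < 2L) abort("need both classes to fit a classifier")
  if (!is_scalar_num(cost) || cost <= 0) abort("cost must be > 0")
  d <- ncol(x)
  obj <- function(th) {
    w <- th[seq_len(d)]; b <- th[d + 1L]
    m <- pmax(0, 1 - y * (drop(x %*% w) + b))
    0.5 * sum(w^2) + cost * sum(m^2)
  }
  grad <- function(th) {
    w <- th[seq_len(d)]; b <- th[d + 1L]
    m <- pmax(0, 1 - y * (drop(x %*% w) + b))
    gw <- w - 2 * cost * drop(crossprod(x, y * m))
    gb <- -2 * cost * sum(y * m)
    c(gw, gb)
  }
  fit <- stats::optim(rep(0, d + 1L), obj, grad, method = "BFGS",
                      control = list(maxit = 500L, reltol = 1e-12))
  w <- fit$par[seq_len(d)]
  names(w) <- colnames(x)
  structure(list(w = w, b = fit$par[d + 1L], cost = cost,
                 converged = fit$convergence == 0L),
            class = "linear_svm")
}

#' Decision values of a fitted linear classifier
#' @param object A `linear_svm` fit.
#' @param newdata Samples x features matrix with the training features.
#' @param ... Unused.
#' @return Numeric decision values; positive favors class +1.
#' @export
predict.linear_svm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  drop(newdata[, names(object$w), drop = FALSE] %*% object$w) + object$b
}

#' @export
print.linear_svm <- function(x, ...) {
  cat(sprintf("linear_svm: %d feature(s), cost = %g\n", length(x$w), x$cost))
  invisible(x)
}
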