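#' Remove additive batch effects from expression
#'
#' Fits, per gene, an additive linear model with intercept, the prognosis
#' class as a protected covariate (when present with two levels), and
#' sum-to-zero batch terms; then subtracts the fitted batch terms only,
#' leaving class-associated signal untouched. Equivalent to
#' `limma::removeBatchEffect` with the class in the protected design.
#'
#' @param expr Genes x samples matrix.
#' @param pheno Phenotype table with a `batch` column (>= 2 levels, each
#'   with >= 2 samples) aligned to `expr` (see [harmonize()]).
#' @return List: `expr` (corrected matrix) and `model` (class
#'   `batch_model`) with per-gene, per-level batch coefficients that sum
#'   to zero across levels.
#' @export
remove_batch <- function(expr, pheno) {
  validate_expression(expr)
  if (!"batch" %in% names(pheno)) abort("phenotype has no 'batch' column")
  if (!identical(colnames(expr), pheno$sample))
    abort("expression and phenotype samples are not aligned; run harmonize() first")
  batch <- factor(pheno$batch)
  if (nlevels(batch) < 2L) abort("need >= 2 batch levels")
  small <- table(batch) < 2L
  if (any(small))
    abort("batch level '%s' has < 2 samples", names(which(small))[1L])
  n <- ncol(expr)
  contr <- stats::contr.sum(nlevels(batch))
  B <- contr[as.integer(batch), , drop = FALSE]  # n x (nb-1), sum-to-zero coding
  design <- cbind(intercept = rep(1, n))
  if ("class" %in% names(pheno) && length(unique(pheno$class)) == 2L)
    design <- cbind(design, class = as.numeric(pheno$class))
  X <- cbind(design, B)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    abort("batch is aliased with the protected design (rank-deficient model); cannot separate batch from class")
  # per-gene least squares for all genes at once: coef = (X'X)^-1 X' y
  coefs <- t(qr.coef(qx, t(expr)))            # genes x ncol(X)
  bcoef <- coefs[, seq_len(ncol(B)) + ncol(design), drop = FALSE]
  fitted_batch <- bcoef %*% t(B)              # genes x samples
  corrected <- expr - fitted_batch
  per_level <- bcoef %*% t(contr)             # genes x levels, rows sum to 0
  colnames(per_level) <- levels(batch)
  model <- structure(list(batches = levels(batch), coefficients = per_level),
                     class = "batch_model")
  list(expr = corrected, model = model)
}

#' @export
print.batch_model <- function(x, ...) {
  cat(sprintf("batch_model: %d level(s) [%s], %d gene(s)\n",
              length(x$batches), paste(x$batches, collapse = ", "),
              nrow(x$coefficients)))
  invisible(x)
}

#' Standardize each gene to mean 0, sd 1
#'
#' Sample standard deviation (n - 1 denominator). Constant genes become
#' all-zero rows with a warning. Idempotent to numerical tolerance.
#'
#' @param expr Genes x samples matrix with >= 2 samples.
#' @return Standardized matrix of the same shape.
#' @export
standardize <- function(expr) {
  validate_expression(expr)
  if (ncol(expr) < 2L) abort("standardize needs >= 2 samples")
  mu <- rowMeans(expr)
  sdv <- apply(expr, 1L, stats::sd)
  const <- sdv == 0
  if (any(const)) {
    warnf("%d constant gene(s) set to all-zero rows", sum(const))
    sdv[const] <- 1
  }
  out <- (expr - mu) / sdv
  out[const, ] <- 0
  out
}
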