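#' Rank-based AUC (Mann-Whitney)
#'
#' Probability that a random positive-class (+1) sample scores above a
#' random negative-class (-1) sample; ties count one half. Equals
#' U / (n+ * n-).
#'
#' @param scores Numeric classifier scores, higher = more positive.
#' @param labels Labels in \{-1, +1\}; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  if (!all(labels %in% c(-1, 1))) abort("labels must be -1 / +1")
  npos <- sum(labels == 1); nneg <- sum(labels == -1)
  if (npos == 0L || nneg == 0L) abort("auc needs both classes present")
  r <- rank(scores)                       # average ranks handle ties as 1/2
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

# Train the full selector + classifier on a sample subset.
# Feature selection and classifier fitting see only `train_samples`
# (phenotype rows outside that set are never touched), which is the
# no-leakage contract run_cv and its tests rely on.
#' Fit the smoothed selector plus linear classifier on given samples
#'
#' @param expr Full genes x samples matrix (unstandardized).
#' @param pheno Aligned phenotype table.
#' @param kernel A prebuilt [build_kernel()] on the same genes.
#' @param train_samples Sample ids to train on.
#' @param top_frac,min_abs_logfc Selection gates, see [select_signature()].
#' @param cost Classifier regularization, see [linear_svm()].
#' @return List: `signature` (gene_list), `model` (`linear_svm` or NULL),
#'   `center`,`scale` (per-gene standardization parameters learned on the
#'   training samples).
#' @export
fit_signature_model <- function(expr, pheno, kernel, train_samples,
                                top_frac = 0.1, min_abs_logfc = 0.5,
                                cost = 1) {
  idx <- match(train_samples, colnames(expr))
  if (anyNA(idx)) abort("unknown training sample id")
  xtr <- expr[, idx, drop = FALSE]
  ptr <- pheno[match(train_samples, pheno$sample), , drop = FALSE]
  mu <- rowMeans(xtr)
  sdv <- apply(xtr, 1L, stats::sd)
  sdv[sdv == 0] <- 1
  xs <- (xtr - mu) / sdv
  st <- differential_stats(xs, ptr)
  tbl <- smooth_scores(st, kernel)
  sig <- suppressWarnings(select_signature(tbl, top_frac, min_abs_logfc))
  model <- NULL
  if (length(sig) > 0L) {
    model <- linear_svm(t(xs[as.character(sig), , drop = FALSE]),
                        as.numeric(ptr$class), cost = cost)
  }
  list(signature = sig, model = model, center = mu, scale = sdv)
}

#' Repeated stratified k-fold cross-validation of the selector pipeline
#'
#' For each repeat, samples are assigned to stratified folds from the
#' seeded generator. Within each training fold only: per-gene
#' standardization, differential statistics, network smoothing, signature
#' selection and classifier training; held-out decision values are scored
#' by [auc()]. Test samples never influence selection or training. A fold
#' with an empty signature scores AUC 0.5 with a warning.
#'
#' @param expr Genes x samples matrix.
#' @param pheno Aligned phenotype with `class` in \{-1, +1\}.
#' @param net A [gene_network()] (kernel is built once; it depends only on
#'   the network).
#' @param a,p Kernel parameters, see [build_kernel()].
#' @param top_frac,min_abs_logfc Selection gates.
#' @param cost Classifier regularization constant.
#' @param repeats,folds CV schedule (default 10 x 5).
#' @param seed Single integer seed controlling all fold randomness.
#' @return Object of class `cv_result`: `per_fold` data.frame (repeat,
#'   fold, auc, n_selected), `signatures` (list of gene vectors per fold),
#'   `median_auc`, and the parameters.
#' @export
run_cv <- function(expr, pheno, net, a = 2, p = 3, top_frac = 0.1,
                   min_abs_logfc = 0.5, cost = 1, repeats = 10, folds = 5,
                   seed = 1) {
  h <- harmonize(expr, pheno, net)
  expr <- h$expr; pheno <- h$pheno; net <- h$net
  cls <- pheno$class
  if (!all(cls %in% c(-1, 1))) abort("class labels must be -1 / +1")
  if (min(table(cls)) < folds)
    abort("each class needs >= %d samples for %d-fold CV", folds, folds)
  kernel <- build_kernel(net, a = a, p = p)
  old <- .Random.seed.exists()
  set.seed(seed)
  on.exit(old())
  per <- vector("list", repeats * folds)
  sigs <- vector("list", repeats * folds)
  k <- 0L
  for (r in seq_len(repeats)) {
    fold_id <- integer(length(cls))
    for (cl in c(-1, 1)) {                      # stratified assignment
      idx <- which(cls == cl)
      fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    for (f in seq_len(folds)) {
      k <- k + 1L
      tr <- pheno$sample[fold_id != f]
      te <- pheno$sample[fold_id == f]
      fit <- suppressWarnings(
        fit_signature_model(expr, pheno, kernel, tr,
                            top_frac = top_frac,
                            min_abs_logfc = min_abs_logfc, cost = cost))
      if (is.null(fit$model)) {
        warnf("repeat %d fold %d: empty signature, AUC set to 0.5", r, f)
        fold_auc <- 0.5
      } else {
        xte <- (expr[, te, drop = FALSE] - fit$center) / fit$scale
        dv <- predict(fit$model, t(xte))
        fold_auc <- auc(dv, pheno$class[match(te, pheno$sample)])
      }
      per[[k]] <- data.frame(repeat_ = r, fold = f, auc = fold_auc,
                             n_selected = length(fit$signature))
      sigs[[k]] <- as.character(fit$signature)
    }
  }
  per_fold <- do.call(rbind, per)
  structure(list(per_fold = per_fold, signatures = sigs,
                 median_auc = stats::median(per_fold$auc),
                 params = list(a = a, p = p, top_frac = top_frac,
                               min_abs_logfc = min_abs_logfc, cost = cost,
                               repeats = repeats, folds = folds,
                               seed = seed)),
            class = "cv_result")
}

# restore-RNG helper: returns a function that puts .Random.seed back
.Random.seed.exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    saved <- get(".Random.seed", envir = globalenv())
    function() assign(".Random.seed", saved, envir = globalenv())
  } else {
    function() suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %d repeat(s) x %d fold(s), median AUC = %.3f\n",
              x$params$repeats, x$params$folds, x$median_auc))
  invisible(x)
}

#' Consensus signature across cross-validation folds
#'
#' Genes selected in at least `min_freq` of all folds, ordered by
#' decreasing selection frequency, ties alphabetical.
#'
#' @param result A [run_cv()] result.
#' @param min_freq Frequency threshold in (0, 1\], boundary inclusive.
#'   Default 0.5.
#' @return A [gene_list()]; empty with a warning when nothing clears the
#'   threshold.
#' @export
consensus <- function(result, min_freq = 0.5) {
  stopifnot(inherits(result, "cv_result"))
  if (!is_scalar_num(min_freq) || min_freq <= 0 || min_freq > 1)
    abort("min_freq must be in (0, 1]")
  nfold <- length(result$signatures)
  tab <- table(unlist(result$signatures)) / nfold
  keep <- tab[tab >= min_freq]
  if (length(keep) == 0L) {
    warnf("no gene reaches consensus frequency %g", min_freq)
    return(gene_list(character(), label = "consensus"))
  }
  ord <- order(-as.numeric(keep), names(keep))
  out <- gene_list(names(keep)[ord], label = sprintf("consensus >= %g", min_freq))
  attr(out, "frequency") <- as.numeric(keep)[ord]
  out
}
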