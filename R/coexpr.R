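# WGCNA-style co-expression analysis on a candidate gene set:
# soft-threshold scan against approximate scale-free topology, unsigned
# topological overlap, average-linkage module detection with a static
# tree cut, module eigengenes and module-trait correlation.

# standard module color order, largest module first
wgcna_colors <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
  "paleturquoise", "violet", "darkolivegreen", "darkmagenta")

# unsigned adjacency |cor|^beta with zero diagonal
adjacency_matrix <- function(expr, beta) {
  sdv <- apply(expr, 1L, stats::sd)
  if (any(sdv == 0)) abort("constant gene rows; standardize/filter first")
  A <- abs(stats::cor(t(expr)))^beta
  diag(A) <- 0
  A
}

# signed scale-free fit index of a connectivity vector (WGCNA convention:
# -sign(slope) * R^2, positive when the log-log degree fit slopes down)
scale_free_fit <- function(k, n_bins = 10L) {
  brk <- seq(min(k), max(k), length.out = n_bins + 1L)
  brk[length(brk)] <- brk[length(brk)] + 1e-12
  bin <- cut(k, breaks = brk, include.lowest = TRUE)
  cnt <- tabulate(bin, nbins = n_bins)
  mk <- tapply(k, bin, mean)
  keep <- which(cnt > 0 & !is.na(mk) & mk > 0)
  if (length(keep) < 3L) return(list(r2 = NA_real_, slope = NA_real_))
  x <- log10(as.numeric(mk[keep]))
  y <- log10(cnt[keep] / length(k))
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- fit$coefficients[2L]
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  list(r2 = -sign(slope) * r2, slope = slope)
}

#' Scan soft-threshold powers for approximate scale-free topology
#'
#' For each candidate power beta, forms the unsigned adjacency
#' a_ij = |cor(x_i, x_j)|^beta, computes connectivities k_i = sum_j a_ij,
#' and the signed scale-free fit index (R-squared of the log10 frequency
#' vs log10 connectivity regression over equal-width bins, signed so that
#' a downward slope is positive). The chosen power is the smallest beta
#' whose fit reaches `r2_cut`; if none does, the argmax with a warning.
#'
#' @param expr Genes x samples matrix, >= 20 genes, no constant rows.
#' @param betas Candidate integer powers (default 1:20).
#' @param r2_cut Fit threshold (default 0.85).
#' @param n_bins Equal-width connectivity bins (default 10; empty bins
#'   dropped).
#' @return Object of class `soft_threshold_scan`: data.frame `scan`
#'   (beta, fit_r2, mean_k) plus `chosen_beta`.
#' @export
scan_soft_threshold <- function(expr, betas = 1:20, r2_cut = 0.85,
                                n_bins = 10L) {
  validate_expression(expr)
  if (nrow(expr) < 20L) abort("need >= 20 genes for a meaningful scan")
  if (any(apply(expr, 1L, stats::sd) == 0))
    abort("constant gene rows; standardize/filter first")
  C <- abs(stats::cor(t(expr)))
  diag(C) <- 0
  rows <- lapply(betas, function(b) {
    A <- C^b
    k <- rowSums(A)
    f <- scale_free_fit(k, n_bins)
    data.frame(beta = b, fit_r2 = f$r2, mean_k = mean(k))
  })
  scan <- do.call(rbind, rows)
  ok <- which(!is.na(scan$fit_r2) & scan$fit_r2 >= r2_cut)
  if (length(ok) > 0L) {
    chosen <- scan$beta[ok[1L]]
  } else {
    warnf("no power reaches fit %g; taking argmax fit", r2_cut)
    chosen <- scan$beta[which.max(scan$fit_r2)]
  }
  structure(list(scan = scan, chosen_beta = chosen, r2_cut = r2_cut),
            class = "soft_threshold_scan")
}

#' @export
print.soft_threshold_scan <- function(x, ...) {
  cat(sprintf("soft_threshold_scan: chosen beta = %d (cut %g)\n",
              x$chosen_beta, x$r2_cut))
  print(x$scan, row.names = FALSE)
  invisible(x)
}

# dense TOM matrix; exported via tom() as a weighted network
tom_matrix <- function(expr, beta) {
  A <- adjacency_matrix(expr, beta)
  k <- rowSums(A)
  L <- A %*% A                         # shared-neighbor term (diag(A)=0)
  denom <- outer(k, k, pmin) + 1 - A
  T <- (L + A) / denom
  diag(T) <- 1
  T[T < 0] <- 0
  T[T > 1] <- 1
  dimnames(T) <- list(rownames(expr), rownames(expr))
  T
}

#' Unsigned topological overlap network
#'
#' TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij) with
#' l_ij = sum_u a_iu a_uj over u != i, j; diagonal 1. Returned as a fully
#' weighted [gene_network()] (zero-weight pairs omitted from the edge
#' table).
#'
#' @param expr Genes x samples matrix.
#' @param beta Soft-threshold power (>= 1), e.g. from
#'   [scan_soft_threshold()].
#' @return Weighted `gene_network` with attribute `"tom"` holding the
#'   dense matrix.
#' @export
tom <- function(expr, beta) {
  validate_expression(expr)
  if (!is_count(beta) || beta < 1) abort("beta must be an integer >= 1")
  T <- tom_matrix(expr, beta)
  ut <- which(upper.tri(T) & T > 0, arr.ind = TRUE)
  net <- gene_network(
    data.frame(from = rownames(T)[ut[, 1L]], to = colnames(T)[ut[, 2L]],
               weight = T[ut], stringsAsFactors = FALSE),
    nodes = rownames(T))
  attr(net, "tom") <- T
  net
}

net_as_matrix <- function(net) {
  m <- attr(net, "tom")
  if (!is.null(m)) return(m)
  genes <- net$nodes
  A <- matrix(0, length(genes), length(genes), dimnames = list(genes, genes))
  if (nrow(net$edges) > 0L) {
    i <- match(net$edges$from, genes); j <- match(net$edges$to, genes)
    A[cbind(i, j)] <- net$edges$weight
    A[cbind(j, i)] <- net$edges$weight
  }
  A
}

#' Detect co-expression modules by hierarchical clustering of 1 - TOM
#'
#' Average-linkage clustering of the topological-overlap dissimilarity
#' with a static cut at `cut_height`; clusters smaller than `min_size`
#' are relabeled "grey" (unassigned). Modules are named by decreasing
#' size using the conventional color order (turquoise first). When
#' `expr` is supplied, module eigengenes (first principal component per
#' module, unit norm, sign-oriented to correlate positively with its
#' genes) are computed as well.
#'
#' @param tomnet Output of [tom()] (or any weighted similarity network
#'   with entries in \[0, 1\]).
#' @param cut_height Static tree-cut height in (0, 1), default 0.8.
#' @param min_size Minimum module size, default 10.
#' @param expr Optional genes x samples matrix for eigengene computation.
#' @return Object of class `module_set`: `assignment` (named character),
#'   `sizes`, optional `eigengenes` (samples x modules matrix).
#' @export
detect_modules <- function(tomnet, cut_height = 0.8, min_size = 10,
                           expr = NULL) {
  if (!is_scalar_num(cut_height) || cut_height <= 0 || cut_height >= 1)
    abort("cut_height must be in (0, 1)")
  T <- net_as_matrix(tomnet)
  genes <- rownames(T)
  hc <- stats::hclust(stats::as.dist(1 - T), method = "average")
  raw <- stats::cutree(hc, h = cut_height)
  sizes <- table(raw)
  ok_ids <- names(sizes)[sizes >= min_size]
  # order surviving clusters by decreasing size, ties by smallest member
  ord <- order(-as.numeric(sizes[ok_ids]),
               vapply(ok_ids, function(id) min(genes[raw == id]), character(1)))
  ok_ids <- ok_ids[ord]
  if (length(ok_ids) > length(wgcna_colors))
    abort("more modules than available color labels")
  lab <- rep("grey", length(genes))
  for (i in seq_along(ok_ids)) lab[raw == as.integer(ok_ids[i])] <- wgcna_colors[i]
  names(lab) <- genes
  lev <- c(wgcna_colors[seq_along(ok_ids)], "grey")
  out <- structure(list(assignment = lab,
                        sizes = table(factor(lab, levels = lev[lev %in% lab])),
                        eigengenes = NULL, trait_cor = NULL),
                   class = "module_set")
  if (!is.null(expr)) {
    if (length(ok_ids) == 0L) {
      warnf("all genes unassigned (grey); no eigengenes computed")
    } else {
      out$eigengenes <- module_eigengenes(out, expr)
    }
  }
  out
}

#' @export
print.module_set <- function(x, ...) {
  cat("module_set:\n")
  print(x$sizes)
  invisible(x)
}

#' Module eigengenes
#'
#' First principal component of each module's standardized expression
#' submatrix: a unit-norm per-sample vector, sign-oriented so that its
#' mean correlation with the module's gene profiles is non-negative.
#' The grey (unassigned) pseudo-module is skipped.
#'
#' @param modules A `module_set`.
#' @param expr Genes x samples matrix covering the module genes.
#' @return Samples x modules matrix of eigengenes.
#' @export
module_eigengenes <- function(modules, expr) {
  validate_expression(expr)
  labs <- setdiff(unique(modules$assignment), "grey")
  labs <- labs[order(match(labs, wgcna_colors))]
  if (length(labs) == 0L) abort("no non-grey modules")
  me <- sapply(labs, function(m) {
    g <- names(modules$assignment)[modules$assignment == m]
    xs <- standardize(expr[g, , drop = FALSE])
    sv <- svd(xs, nu = 0L, nv = 1L)
    v <- sv$v[, 1L]
    if (mean(stats::cor(v, t(xs))) < 0) v <- -v
    v
  })
  rownames(me) <- colnames(expr)
  me
}

#' Correlate module eigengenes with sample traits
#'
#' Pearson correlation of each eigengene with each (numeric or
#' binary-coded) trait; two-sided p-value from the t transform with n - 2
#' degrees of freedom. Constant traits are recorded as missing with a
#' warning.
#'
#' @param modules A `module_set` with eigengenes (see [detect_modules()]
#'   with `expr`, or [module_eigengenes()]).
#' @param pheno Phenotype table aligned to the eigengene samples.
#' @param traits Column names of `pheno` to correlate.
#' @return The `module_set` with `trait_cor`: list of matrices `r` and
#'   `p` (modules x traits).
#' @export
module_trait <- function(modules, pheno, traits) {
  me <- modules$eigengenes
  if (is.null(me)) abort("modules carry no eigengenes; pass expr to detect_modules()")
  if (!all(traits %in% names(pheno))) abort("unknown trait column")
  n <- nrow(me)
  r <- matrix(NA_real_, ncol(me), length(traits),
              dimnames = list(colnames(me), traits))
  p <- r
  for (tr in traits) {
    v <- as.numeric(pheno[[tr]])
    if (stats::sd(v) == 0) {
      warnf("trait '%s' is constant; correlation undefined", tr)
      next
    }
    rv <- as.numeric(stats::cor(me, v))
    tv <- rv * sqrt((n - 2) / pmax(1 - rv^2, .Machine$double.eps))
    r[, tr] <- rv
    p[, tr] <- 2 * stats::pt(-abs(tv), df = n - 2)
  }
  modules$trait_cor <- list(r = r, p = p)
  modules
}
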