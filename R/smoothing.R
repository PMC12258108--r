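#' Per-gene two-sample differential statistics
#'
#' Pooled-variance two-sample t-statistic and log fold change for each
#' gene, comparing the poor-prognosis class (-1) against the favorable
#' class (+1). Sign convention: positive t (and logfc) means higher
#' expression in the poor-prognosis class. Genes with zero pooled
#' variance get t = 0 with a warning.
#'
#' @param expr Genes x samples matrix (log scale).
#' @param pheno Aligned phenotype table with `class` in \{-1, +1\}, both
#'   classes with >= 2 samples.
#' @return `data.frame` with columns gene, t, logfc.
#' @export
differential_stats <- function(expr, pheno) {
  validate_expression(expr)
  if (!identical(colnames(expr), pheno$sample))
    abort("expression and phenotype samples are not aligned")
  cls <- pheno$class
  if (!all(cls %in% c(-1, 1))) abort("class labels must be -1 / +1")
  n1 <- sum(cls == -1); n2 <- sum(cls == 1)
  if (n1 < 2L || n2 < 2L) abort("each class needs >= 2 samples (got %d / %d)", n1, n2)
  x1 <- expr[, cls == -1, drop = FALSE]
  x2 <- expr[, cls == 1, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss1 <- rowSums((x1 - m1)^2)
  ss2 <- rowSums((x2 - m2)^2)
  sp2 <- (ss1 + ss2) / (n1 + n2 - 2L)
  denom <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tval <- (m1 - m2) / denom
  zero <- sp2 == 0
  if (any(zero)) {
    warnf("%d gene(s) with zero pooled variance: t set to 0", sum(zero))
    tval[zero] <- 0
  }
  data.frame(gene = rownames(expr), t = tval, logfc = m1 - m2,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Build a p-step random-walk kernel on a gene network
#'
#' Forms the symmetric normalized Laplacian L = I - D^(-1/2) A D^(-1/2)
#' (diagonal 1 everywhere; isolated nodes contribute a zero normalized
#' adjacency row) and returns K = (a I - L)^p. For a >= 2 the spectrum of
#' L lies in \[0, 2\], so a I - L is positive semi-definite and so is any
#' power of it. p = 0 gives the identity; an isolated node's diagonal
#' entry is (a - 1)^p.
#'
#' @param net A [gene_network()]; edge weights feed the weighted degree.
#' @param a Kernel offset, must be >= 2 (PSD guarantee). Default 2.
#' @param p Non-negative integer step count. Default 3.
#' @return Object of class `rw_kernel`: list with `K` (dense symmetric
#'   matrix, dimnames = genes), `a`, `p`, `genes`.
#' @export
build_kernel <- function(net, a = 2, p = 3) {
  stopifnot(inherits(net, "gene_network"))
  if (!is_scalar_num(a) || a < 2) abort("kernel offset a must be >= 2 (PSD guarantee lost below 2)")
  if (!is_count(p) || p < 0) abort("step count p must be a non-negative integer")
  genes <- net$nodes
  n <- length(genes)
  A <- matrix(0, n, n, dimnames = list(genes, genes))
  if (nrow(net$edges) > 0L) {
    i <- match(net$edges$from, genes)
    j <- match(net$edges$to, genes)
    A[cbind(i, j)] <- net$edges$weight
    A[cbind(j, i)] <- net$edges$weight
  }
  deg <- rowSums(A)
  dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  An <- A * tcrossprod(dinv)          # D^(-1/2) A D^(-1/2)
  M <- (a - 1) * diag(n) + An         # a I - L  with  L = I - An
  K <- diag(n)
  if (p > 0L) {
    base <- M
    pp <- p
    while (pp > 0L) {                 # exponentiation by squaring
      if (pp %% 2L == 1L) K <- K %*% base
      pp <- pp %/% 2L
      if (pp > 0L) base <- base %*% base
    }
  }
  K <- (K + t(K)) / 2                 # kill asymmetric round-off
  dimnames(K) <- list(genes, genes)
  structure(list(K = K, a = a, p = p, genes = genes), class = "rw_kernel")
}

#' @export
print.rw_kernel <- function(x, ...) {
  cat(sprintf("rw_kernel: %d genes, a = %g, p = %d\n",
              length(x$genes), x$a, x$p))
  invisible(x)
}

#' Smooth absolute t-statistics over the network kernel
#'
#' Computes s = K' |t| where K' is, by default, the degree-normalized
#' kernel S^(-1/2) K S^(-1/2) with S = diag(row sums of K). The
#' normalization is a congruence transform, so K' stays symmetric,
#' positive semi-definite and entry-wise non-negative, and it removes the
#' raw kernel's hub bias (row sums of (a I - L)^p grow with node degree,
#' so unnormalized smoothing ranks hubs highly regardless of their
#' statistics). On regular graphs and isolated nodes the two choices give
#' identical rankings; `normalize = FALSE` applies K itself. Scores are
#' rescaled by the maximum (report readability only; order-preserving)
#' and ranks assigned descending with alphabetical tie-break.
#'
#' @param stats Output of [differential_stats()]; the gene set must equal
#'   the kernel's gene set.
#' @param kernel Output of [build_kernel()].
#' @param normalize Degree-normalize the kernel before smoothing
#'   (default `TRUE`).
#' @return `data.frame` (smoothed score table) with columns gene, raw
#'   (= |t|), logfc, smoothed (in \[0, 1\]), rank.
#' @export
smooth_scores <- function(stats, kernel, normalize = TRUE) {
  stopifnot(inherits(kernel, "rw_kernel"))
  if (!setequal(stats$gene, kernel$genes))
    abort("gene sets of stats and kernel differ; run harmonize() first")
  stats <- stats[match(kernel$genes, stats$gene), , drop = FALSE]
  absmt <- abs(stats$t)
  K <- kernel$K
  if (normalize) {
    rs <- rowSums(K)
    rs[rs <= 0] <- 1
    K <- K / sqrt(outer(rs, rs))
  }
  s <- as.numeric(K %*% absmt)
  if (max(s) > 0) {
    s <- s / max(s)
  } else {
    warnf("all t-statistics are zero: all smoothed scores zero, ranks tied")
  }
  ord <- order(-s, stats$gene)
  rnk <- integer(length(s))
  rnk[ord] <- seq_along(s)
  data.frame(gene = stats$gene, raw = absmt, logfc = stats$logfc,
             smoothed = s, rank = rnk, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Select a gene signature from a smoothed score table
#'
#' Keeps genes ranked in the top `top_frac` fraction (ceiling rule) whose
#' absolute log fold change clears `min_abs_logfc` — the conjunction of
#' both gates — ordered by rank.
#'
#' @param tbl Output of [smooth_scores()].
#' @param top_frac Fraction of genes to keep by rank, in (0, 1\]. Default
#'   0.1.
#' @param min_abs_logfc Log-fold-change gate, >= 0. Default 0.5.
#' @return A [gene_list()] (possibly empty, with a warning).
#' @export
select_signature <- function(tbl, top_frac = 0.1, min_abs_logfc = 0.5) {
  if (!is_scalar_num(top_frac) || top_frac <= 0 || top_frac > 1)
    abort("top_frac must be in (0, 1]")
  if (!is_scalar_num(min_abs_logfc) || min_abs_logfc < 0)
    abort("min_abs_logfc must be >= 0")
  k <- ceiling(top_frac * nrow(tbl))
  passed <- tbl$rank <= k & abs(tbl$logfc) >= min_abs_logfc
  sel <- tbl[passed, , drop = FALSE]
  sel <- sel[order(sel$rank), , drop = FALSE]
  if (nrow(sel) == 0L) warnf("signature selection returned no genes")
  out <- gene_list(sel$gene, label = sprintf("top %.3g%% & |logFC| >= %g",
                                             100 * top_frac, min_abs_logfc))
  attr(out, "table") <- transform(tbl, passed_logfc = abs(tbl$logfc) >= min_abs_logfc)
  out
}
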