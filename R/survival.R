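#' Kaplan-Meier product-limit estimator
#'
#' Nonparametric survival curve. At each distinct event time t_j, with
#' n_j subjects at risk and d_j deaths, S(t_j) = prod_{k<=j} (1 - d_k/n_k).
#' Events precede censorings at tied times (the censored subject is still
#' at risk at its own time).
#'
#' @param time Non-negative follow-up times.
#' @param event 1 = death observed, 0 = censored.
#' @return Object of class `km_curve`: `times` (distinct event times),
#'   `at_risk`, `events`, `survival`.
#' @export
km_fit <- function(time, event) {
  if (length(time) == 0L) abort("empty survival input")
  if (length(time) != length(event)) abort("time and event lengths differ")
  if (any(time < 0)) abort("negative survival time")
  if (!all(event %in% c(0, 1))) abort("event must be 0/1")
  et <- sort(unique(time[event == 1]))
  if (length(et) == 0L) {
    out <- list(times = numeric(), at_risk = integer(), events = integer(),
                survival = numeric())
    return(structure(out, class = "km_curve"))
  }
  n_risk <- vapply(et, function(t) sum(time >= t), numeric(1))
  d <- vapply(et, function(t) sum(time == t & event == 1), numeric(1))
  surv <- cumprod(1 - d / n_risk)
  structure(list(times = et, at_risk = as.integer(n_risk),
                 events = as.integer(d), survival = surv),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  if (length(x$times) == 0L) {
    cat("km_curve: no events (survival = 1 throughout)\n")
  } else {
    print(data.frame(time = x$times, at_risk = x$at_risk,
                     events = x$events, survival = x$survival),
          row.names = FALSE)
  }
  invisible(x)
}

#' Evaluate a Kaplan-Meier curve at given times
#' @param fit A `km_curve`.
#' @param t Times at which to evaluate S(t).
#' @return Step-function values (1 before the first event).
#' @export
km_survival_at <- function(fit, t) {
  stopifnot(inherits(fit, "km_curve"))
  vapply(t, function(tt) {
    j <- sum(fit$times <= tt)
    if (j == 0L) 1 else fit$survival[j]
  }, numeric(1))
}

#' Split samples at a gene's median expression
#'
#' High group: expression strictly above the median (computed over all
#' samples); low group: at or below (median ties go low). Constant genes
#' cannot be split and raise an error.
#'
#' @param expr Genes x samples matrix.
#' @param gene Gene symbol.
#' @return Named factor over samples with levels `low`, `high`.
#' @export
median_split <- function(expr, gene) {
  validate_expression(expr)
  if (!gene %in% rownames(expr)) abort("gene '%s' not in expression matrix", gene)
  v <- expr[gene, ]
  med <- stats::median(v)
  if (all(v == v[1L])) abort("gene '%s' is constant; no split possible", gene)
  grp <- factor(ifelse(v > med, "high", "low"), levels = c("low", "high"))
  names(grp) <- colnames(expr)
  msgf("median_split '%s': %d low, %d high", gene, sum(grp == "low"),
       sum(grp == "high"))
  grp
}

#' Two-group survival comparison (Gehan-Wilcoxon / log-rank)
#'
#' Weighted log-rank test. At each distinct event time of the pooled
#' sample, the observed minus expected events in group A are weighted by
#' w_j: the total number at risk (Gehan-Breslow-Wilcoxon, which
#' emphasizes early differences) or 1 (log-rank). The statistic
#' (sum w_j (O_j - E_j))^2 / sum w_j^2 V_j is referred to chi-squared
#' with 1 df. Symmetric in group order.
#'
#' @param groupA,groupB Lists or data.frames with elements `time` and
#'   `event`; each group needs at least one observed event.
#' @param method `"gehan_wilcoxon"` (default) or `"logrank"`.
#' @return Object of class `two_group_test`: `statistic`, `p_value`,
#'   `method`.
#' @export
compare_survival <- function(groupA, groupB,
                             method = c("gehan_wilcoxon", "logrank")) {
  method <- match.arg(method)
  ta <- groupA$time; ea <- groupA$event
  tb <- groupB$time; eb <- groupB$event
  if (sum(ea) < 1 || sum(eb) < 1) abort("each group needs >= 1 observed event")
  time <- c(ta, tb)
  event <- c(ea, eb)
  grp <- rep(c(1L, 2L), c(length(ta), length(tb)))
  et <- sort(unique(time[event == 1]))
  U <- 0; VarU <- 0
  for (t in et) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & grp == 1L)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & grp == 1L)
    E1 <- d * n1 / n
    V <- if (n > 1) n1 * (n - n1) * d * (n - d) / (n^2 * (n - 1)) else 0
    w <- if (method == "gehan_wilcoxon") n else 1
    U <- U + w * (d1 - E1)
    VarU <- VarU + w^2 * V
  }
  if (VarU == 0) abort("zero variance: groups cannot be compared")
  stat <- U^2 / VarU
  structure(list(statistic = stat,
                 p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 method = method),
            class = "two_group_test")
}

#' @export
print.two_group_test <- function(x, ...) {
  cat(sprintf("%s: chi-squared = %.4g, p = %.4g\n", x$method, x$statistic,
              x$p_value))
  invisible(x)
}

#' Median-split survival screen over a set of genes
#'
#' For each gene: split samples at the median, fit Kaplan-Meier curves
#' per group and test the difference. Raw p-values are reported together
#' with Benjamini-Hochberg adjusted values.
#'
#' @param expr Genes x samples matrix.
#' @param pheno Aligned phenotype with `time` and `event`.
#' @param genes Genes to screen (default: all rows).
#' @param method Passed to [compare_survival()].
#' @return `data.frame`: gene, n_low, n_high, statistic, p, p_bh.
#' @export
survival_screen <- function(expr, pheno, genes = rownames(expr),
                            method = c("gehan_wilcoxon", "logrank")) {
  method <- match.arg(method)
  if (!identical(colnames(expr), pheno$sample))
    abort("expression and phenotype samples are not aligned")
  rows <- lapply(genes, function(g) {
    grp <- suppressMessages(median_split(expr, g))
    lo <- grp == "low"
    res <- tryCatch(
      compare_survival(list(time = pheno$time[lo], event = pheno$event[lo]),
                       list(time = pheno$time[!lo], event = pheno$event[!lo]),
                       method = method),
      error = function(e) NULL)
    data.frame(gene = g, n_low = sum(lo), n_high = sum(!lo),
               statistic = if (is.null(res)) NA_real_ else res$statistic,
               p = if (is.null(res)) NA_real_ else res$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- bh_adjust(out$p)
  out
}

#' Correlation with a two-sided t-based p-value
#'
#' Pearson or Spearman (Pearson on average-tie ranks) correlation between
#' two vectors, with p from t = r sqrt((n-2)/(1-r^2)) on n - 2 degrees of
#' freedom. Used for expression-score association (e.g. drug-sensitivity
#' style analyses).
#'
#' @param x,y Numeric vectors of equal length >= 3; neither constant.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List: `r`, `p`, `method`, `n`.
#' @export
associate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) abort("x and y lengths differ")
  n <- length(x)
  if (n < 3L) abort("need >= 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) abort("constant vector: correlation undefined")
  if (method == "spearman") {
    x <- rank(x); y <- rank(y)   # average ranks for ties
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tv <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tv), df = n - 2)
  }
  list(r = r, p = p, method = method, n = n)
}
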