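#' Read a gene-by-sample expression matrix
#'
#' Loads a delimited text file (tab by default) with a header row and an id
#' column into a validated genes x samples numeric matrix. Duplicate gene
#' rows are collapsed by keeping the row with the highest mean expression
#' (the usual microarray convention); duplicate sample ids are an error.
#' Missing or non-numeric cells are an error naming the offending cell
#' unless `impute = "median"`, in which case missing values are replaced by
#' the gene's median across samples.
#'
#' @param path Path to a TSV/CSV file. The first column holds row ids.
#' @param orientation `"genes_rows"` (default) if rows are genes,
#'   `"samples_rows"` if the matrix is transposed on disk.
#' @param sep Field separator, default tab.
#' @param impute `"none"` (fail on missing cells) or `"median"`.
#' @return Numeric matrix, genes as rows, unique rownames/colnames.
#' @export
read_expression <- function(path, orientation = c("genes_rows", "samples_rows"),
                            sep = "\t", impute = c("none", "median")) {
  orientation <- match.arg(orientation)
  impute <- match.arg(impute)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "")
  if (ncol(df) < 2L) abort("expression file '%s' needs an id column plus data", path)
  ids <- df[[1L]]
  cn <- names(df)[-1L]             # before subsetting: `[.data.frame`
  vals <- as.matrix(df[, -1L, drop = FALSE])  # would mangle duplicates
  colnames(vals) <- cn
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) & !(vals %in% c("NA", "", "NaN")), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    abort("malformed numeric cell '%s' at row '%s', column '%s'",
          vals[bad[1L, 1L], bad[1L, 2L]], ids[bad[1L, 1L]],
          colnames(vals)[bad[1L, 2L]])
  }
  rownames(num) <- ids
  colnames(num) <- colnames(vals)
  if (orientation == "samples_rows") num <- t(num)
  if (anyNA(num)) {
    if (impute == "none") {
      miss <- which(is.na(num), arr.ind = TRUE)
      abort("missing value at gene '%s', sample '%s' (set impute='median' to impute)",
            rownames(num)[miss[1L, 1L]], colnames(num)[miss[1L, 2L]])
    }
    for (i in which(rowSums(is.na(num)) > 0L)) {
      med <- stats::median(num[i, ], na.rm = TRUE)
      num[i, is.na(num[i, ])] <- med
    }
    msgf("imputed missing values by gene median")
  }
  if (anyDuplicated(colnames(num))) {
    abort("duplicate sample id '%s'", colnames(num)[duplicated(colnames(num))][1L])
  }
  if (anyDuplicated(rownames(num))) {
    dup <- unique(rownames(num)[duplicated(rownames(num))])
    warnf("collapsing %d duplicated gene id(s) by max mean expression: %s",
          length(dup), paste(utils::head(dup, 5L), collapse = ", "))
    keep <- order(-rowMeans(num))
    num <- num[keep, , drop = FALSE]
    num <- num[!duplicated(rownames(num)), , drop = FALSE]
    num <- num[order(match(rownames(num), unique(ids))), , drop = FALSE]
  }
  validate_expression(num)
  num
}

validate_expression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) abort("expression must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    abort("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(x))) abort("duplicate gene ids")
  if (anyDuplicated(colnames(x))) abort("duplicate sample ids")
  if (anyNA(x) || any(!is.finite(x))) abort("expression matrix contains missing/non-finite values")
  invisible(x)
}

#' Write an expression matrix as TSV
#'
#' Full-precision (`%.17g`) formatting so that read -> write -> read
#' round-trips are bit-exact.
#'
#' @param x Genes x samples numeric matrix.
#' @param path Output path.
#' @export
write_expression <- function(x, path) {
  validate_expression(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene", colnames(x)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], fmt_num(x[i, ])), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read a per-sample phenotype table
#'
#' Expects columns `sample`, optional `class` (-1 poor / +1 favorable
#' prognosis), a survival time column whose unit is declared in the header
#' (`time`, `time_days`, `time_months` or `time_years`), `event`
#' (1 = death observed, 0 = censored) and optional `batch`. Times are
#' converted to the canonical internal unit, days.
#'
#' @param path Path to TSV.
#' @param sep Field separator.
#' @return `data.frame` with columns sample, class, time (days), event,
#'   batch (when present).
#' @export
read_phenotype <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  if (!"sample" %in% names(df)) abort("phenotype table needs a 'sample' column")
  tcol <- grep("^time(_(days|months|years))?$", names(df), value = TRUE)
  if (length(tcol) == 1L) {
    unit <- sub("^time_?", "", tcol)
    mult <- switch(unit, days = 1, months = 30.4375, years = 365.25, 1)
    df$time <- df[[tcol]] * mult
    if (tcol != "time") df[[tcol]] <- NULL
  }
  validate_phenotype(df)
  df
}

validate_phenotype <- function(p) {
  if (!is.data.frame(p) || !"sample" %in% names(p)) abort("phenotype must have a 'sample' column")
  if (anyDuplicated(p$sample)) abort("duplicate sample ids in phenotype table")
  if ("class" %in% names(p) && !all(p$class %in% c(-1, 1, NA)))
    abort("class must be -1 (poor) or +1 (favorable)")
  if ("event" %in% names(p) && !all(p$event %in% c(0, 1, NA)))
    abort("event must be 0 (censored) or 1 (death)")
  if ("time" %in% names(p) && any(p$time < 0, na.rm = TRUE))
    abort("survival times must be non-negative")
  invisible(p)
}

#' Write a phenotype table as TSV
#' @param p Phenotype `data.frame`.
#' @param path Output path.
#' @export
write_phenotype <- function(p, path) {
  validate_phenotype(p)
  q <- p
  for (j in seq_along(q)) if (is.double(q[[j]])) q[[j]] <- fmt_num(q[[j]])
  utils::write.table(q, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a gene network from an edge table
#'
#' Canonical in-memory form of an undirected weighted graph on gene
#' symbols: a sorted node vector plus an edge table with `from < to`
#' lexicographically, no self-loops, no duplicates, finite non-negative
#' weights.
#'
#' @param edges `data.frame` with columns from, to and optional weight
#'   (default 1).
#' @param nodes Optional extra node names kept as isolated nodes.
#' @return Object of class `gene_network` with elements `nodes` and
#'   `edges`.
#' @export
gene_network <- function(edges, nodes = character()) {
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(from = character(), to = character(), weight = numeric())
  }
  if (!"weight" %in% names(edges)) edges$weight <- 1
  if (any(!is.finite(edges$weight)) || any(edges$weight < 0))
    abort("edge weights must be finite and non-negative")
  loops <- edges$from == edges$to
  if (any(loops)) {
    msgf("dropped %d self-loop(s)", sum(loops))
    edges <- edges[!loops, , drop = FALSE]
  }
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  edges <- data.frame(from = a, to = b, weight = edges$weight,
                      stringsAsFactors = FALSE)
  key <- paste(edges$from, edges$to, sep = "\r")
  if (anyDuplicated(key)) {
    edges$weight <- stats::ave(edges$weight, key, FUN = max)
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  all_nodes <- sort(unique(c(edges$from, edges$to, nodes)))
  structure(list(nodes = all_nodes, edges = edges), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Read an undirected network from an edge-list file
#'
#' Two or three whitespace/tab-separated columns: geneA, geneB, optional
#' weight (default 1). Self-loops are dropped (count logged), duplicate
#' edges merged by maximum weight, negative weights rejected.
#'
#' @param path Path to edge-list file.
#' @param header Logical; set `TRUE` if the first line is a header.
#' @return A [gene_network()].
#' @export
read_network <- function(path, header = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (header) lines <- lines[-1L]
  if (length(lines) == 0L) abort("network file '%s' has no edges", path)
  parts <- strsplit(trimws(lines), "[\t ]+")
  n <- lengths(parts)
  if (any(n < 2L)) abort("edge line %d has fewer than two fields", which(n < 2L)[1L])
  from <- vapply(parts, `[[`, character(1), 1L)
  to <- vapply(parts, `[[`, character(1), 2L)
  w <- rep(1, length(parts))
  has_w <- n >= 3L
  if (any(has_w)) {
    ws <- suppressWarnings(as.numeric(vapply(parts[has_w], `[[`, character(1), 3L)))
    if (anyNA(ws)) abort("non-numeric edge weight on line %d", which(has_w)[which(is.na(ws))[1L]])
    w[has_w] <- ws
  }
  if (any(w < 0)) abort("negative edge weight on line %d", which(w < 0)[1L])
  gene_network(data.frame(from = from, to = to, weight = w,
                          stringsAsFactors = FALSE))
}

#' Write a gene network as an edge-list TSV
#' @param net A [gene_network()].
#' @param path Output path.
#' @param keep_isolated Also emit isolated nodes as single-field lines.
#' @export
write_network <- function(net, path, keep_isolated = FALSE) {
  stopifnot(inherits(net, "gene_network"))
  e <- net$edges
  lines <- paste(e$from, e$to, fmt_num(e$weight), sep = "\t")
  if (keep_isolated) {
    iso <- setdiff(net$nodes, unique(c(e$from, e$to)))
    lines <- c(lines, iso)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a one-gene-per-line list
#' @param path Path to plain-text file.
#' @param label Free-text label attached to the list.
#' @return A `gene_list`: character vector of unique symbols.
#' @export
read_gene_list <- function(path, label = basename(path)) {
  g <- trimws(readLines(path))
  gene_list(g[nzchar(g)], label = label)
}

#' Construct a gene list (ordered, unique)
#' @param genes Character vector of symbols.
#' @param label Free-text label.
#' @export
gene_list <- function(genes, label = "") {
  structure(unique(as.character(genes)), class = "gene_list", label = label)
}

#' @export
print.gene_list <- function(x, ...) {
  cat(sprintf("gene_list '%s': %d gene(s)\n", attr(x, "label") %||% "",
              length(x)))
  if (length(x)) cat(" ", paste(utils::head(unclass(x), 10L), collapse = ", "),
                     if (length(x) > 10L) "..." else "", "\n")
  invisible(x)
}

#' Write a gene list, one symbol per line
#' @param genes Character vector / `gene_list`.
#' @param path Output path.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' @param path GMT file: set name, description, then member genes,
#'   tab-separated.
#' @return Named list of `gene_list` objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(strsplit(lines, "\t"), function(f) {
    if (length(f) < 3L) abort("GMT line needs name, description and >= 1 gene")
    gene_list(f[-(1:2)], label = f[1L])
  })
  names(sets) <- vapply(sets, attr, character(1), "label")
  sets
}

#' Align expression, phenotype and network to a common universe
#'
#' Samples are restricted to the intersection of expression and phenotype
#' (order taken from the expression matrix); network nodes are restricted
#' to measured genes; measured genes absent from the network are retained
#' as isolated nodes so that smoothing degenerates to the raw statistic
#' for them. Idempotent.
#'
#' @param expr Genes x samples matrix.
#' @param pheno Phenotype `data.frame`.
#' @param net A [gene_network()] or `NULL`.
#' @return List with elements `expr`, `pheno`, `net`.
#' @export
harmonize <- function(expr, pheno, net = NULL) {
  validate_expression(expr)
  validate_phenotype(pheno)
  keep <- intersect(colnames(expr), pheno$sample)
  if (length(keep) == 0L) abort("no samples shared between expression and phenotype")
  d_expr <- ncol(expr) - length(keep)
  d_ph <- nrow(pheno) - length(keep)
  if (d_expr + d_ph > 0L)
    msgf("harmonize: dropped %d expression and %d phenotype sample(s)", d_expr, d_ph)
  expr <- expr[, keep, drop = FALSE]
  pheno <- pheno[match(keep, pheno$sample), , drop = FALSE]
  rownames(pheno) <- NULL
  if (!is.null(net)) {
    genes <- rownames(expr)
    e <- net$edges
    in_expr <- e$from %in% genes & e$to %in% genes
    dropped_nodes <- length(setdiff(net$nodes, genes))
    if (dropped_nodes > 0L || any(!in_expr))
      msgf("harmonize: dropped %d network node(s) and %d edge(s) not measured",
           dropped_nodes, sum(!in_expr))
    net <- gene_network(e[in_expr, , drop = FALSE], nodes = genes)
  }
  list(expr = expr, pheno = pheno, net = net)
}

#' Dichotomize survival at a cutoff into prognosis classes
#'
#' Class -1 (poor prognosis): death observed before the cutoff. Class +1
#' (favorable): survival time at or past the cutoff, regardless of event
#' status. Samples censored before the cutoff have unknowable class and
#' are excluded (count logged).
#'
#' @param pheno Phenotype `data.frame` with `time` (days) and `event`.
#' @param cutoff_years Positive cutoff in years (5 is the usual choice).
#' @return Phenotype table with a `class` column, indeterminate rows
#'   removed.
#' @export
dichotomize_survival <- function(pheno, cutoff_years = 5) {
  validate_phenotype(pheno)
  if (!all(c("time", "event") %in% names(pheno)))
    abort("dichotomize_survival needs 'time' and 'event' columns")
  if (!is_scalar_num(cutoff_years) || cutoff_years <= 0)
    abort("cutoff_years must be positive")
  cut_days <- cutoff_years * 365.25
  cls <- ifelse(pheno$time >= cut_days, 1,
                ifelse(pheno$event == 1, -1, NA))
  n_excl <- sum(is.na(cls))
  if (n_excl > 0L)
    msgf("dichotomize_survival: excluded %d sample(s) censored before cutoff", n_excl)
  out <- pheno[!is.na(cls), , drop = FALSE]
  out$class <- cls[!is.na(cls)]
  rownames(out) <- NULL
  out
}
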