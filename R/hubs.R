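#' Keep the strongest fraction of network edges
#'
#' Retains the `ceiling(top_frac * |E|)` edges of highest weight; ties are
#' broken by lexicographic (from, to) node pair so the result is
#' deterministic. Nodes left without edges are dropped.
#'
#' @param net A [gene_network()] with at least one edge.
#' @param top_frac Fraction of edges to keep, in (0, 1\]. The study-style
#'   choice is 0.3.
#' @return Filtered `gene_network`.
#' @export
filter_edges <- function(net, top_frac = 0.3) {
  stopifnot(inherits(net, "gene_network"))
  if (!is_scalar_num(top_frac) || top_frac <= 0 || top_frac > 1)
    abort("top_frac must be in (0, 1]")
  e <- net$edges
  if (nrow(e) == 0L) abort("cannot filter an empty graph")
  keep_n <- ceiling(top_frac * nrow(e))
  ord <- order(-e$weight, e$from, e$to)
  kept <- e[ord[seq_len(keep_n)], , drop = FALSE]
  out <- gene_network(kept)
  msgf("filter_edges: kept %d/%d edge(s), %d/%d node(s)",
       nrow(out$edges), nrow(e), length(out$nodes), length(net$nodes))
  out
}

# deterministic Kruskal on (distance, from, to)-sorted edges; returns the
# minimum spanning forest as an edge index vector
kruskal_forest <- function(nodes, from, to, dist) {
  idx <- seq_along(nodes); names(idx) <- nodes
  parent <- idx
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ord <- order(dist, from, to)
  chosen <- integer(0)
  for (k in ord) {
    ri <- find(idx[[from[k]]]); rj <- find(idx[[to[k]]])
    if (ri != rj) {
      parent[rj] <- ri
      chosen <- c(chosen, k)
      if (length(chosen) == length(nodes) - 1L) break
    }
  }
  chosen
}

#' Minimum-spanning-tree hub genes
#'
#' Transforms edge weights (similarities) to distances d = 1 - w / max(w),
#' builds the minimum spanning forest (deterministic Kruskal; exactly
#' nodes - 1 edges per connected component), scores every node by its
#' forest degree, and returns the `n_hubs` highest-scoring genes (ties
#' alphabetical). `score = "betweenness"` ranks instead by shortest-path
#' betweenness within the forest.
#'
#' @param net Weighted `gene_network` (e.g. a filtered TOM network).
#' @param n_hubs Number of hubs to return; if it exceeds the node count
#'   all nodes are returned with a warning.
#' @param score `"degree"` (default) or `"betweenness"`.
#' @return Object of class `hub_result`: `mst` (forest as
#'   `gene_network` carrying the distances), `hub_scores` (named numeric),
#'   `hubs` (a [gene_list()]).
#' @export
mst_hubs <- function(net, n_hubs = 30, score = c("degree", "betweenness")) {
  stopifnot(inherits(net, "gene_network"))
  score <- match.arg(score)
  e <- net$edges
  if (nrow(e) == 0L) abort("network has no edges")
  d <- 1 - e$weight / max(e$weight)
  sel <- kruskal_forest(net$nodes, e$from, e$to, d)
  forest <- data.frame(from = e$from[sel], to = e$to[sel], weight = d[sel],
                       stringsAsFactors = FALSE)
  mst_net <- gene_network(forest, nodes = net$nodes)
  deg <- table(factor(c(forest$from, forest$to), levels = net$nodes))
  scores <- if (score == "degree") {
    stats::setNames(as.numeric(deg), net$nodes)
  } else {
    tree_betweenness(net$nodes, forest$from, forest$to)
  }
  if (n_hubs > length(net$nodes)) {
    warnf("n_hubs exceeds node count; returning all nodes")
    n_hubs <- length(net$nodes)
  }
  ord <- order(-scores, names(scores))
  hubs <- gene_list(names(scores)[ord[seq_len(n_hubs)]], label = "mst hubs")
  structure(list(mst = mst_net, hub_scores = scores, hubs = hubs,
                 score = score),
            class = "hub_result")
}

# betweenness in a forest: for each edge of each tree, removing it splits
# the tree into parts of size s and n - s contributing pair counts to the
# path through each internal node; computed by BFS path counting (trees
# are tiny here)
tree_betweenness <- function(nodes, from, to) {
  adj <- lapply(stats::setNames(seq_along(nodes), nodes), function(i) character(0))
  for (k in seq_along(from)) {
    adj[[from[k]]] <- c(adj[[from[k]]], to[k])
    adj[[to[k]]] <- c(adj[[to[k]]], from[k])
  }
  bw <- stats::setNames(numeric(length(nodes)), nodes)
  path_between <- function(a, b) {        # unique tree path via BFS
    prev <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
    seen <- stats::setNames(logical(length(nodes)), nodes)
    q <- a; seen[a] <- TRUE
    while (length(q) > 0L && !seen[b]) {
      cur <- q[1L]; q <- q[-1L]
      for (nb in adj[[cur]]) if (!seen[nb]) {
        seen[nb] <- TRUE; prev[nb] <- cur; q <- c(q, nb)
      }
    }
    if (!seen[b]) return(NULL)
    path <- b
    while (!is.na(prev[path[1L]])) path <- c(prev[path[1L]], path)
    path
  }
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (i < j) {
      pth <- path_between(nodes[i], nodes[j])
      if (!is.null(pth) && length(pth) > 2L) {
        mid <- pth[-c(1L, length(pth))]
        bw[mid] <- bw[mid] + 1
      }
    }
  }
  bw
}

#' @export
print.hub_result <- function(x, ...) {
  cat(sprintf("hub_result (%s): %d node(s), %d forest edge(s), %d hub(s)\n",
              x$score, length(x$hub_scores), nrow(x$mst$edges),
              length(x$hubs)))
  invisible(x)
}

#' Order-preserving intersection of two gene lists
#'
#' Genes of `a` that also occur in `b`, in `a`'s order. `b` may be a
#' `gene_list`, a character vector, or a named list of gene sets (e.g.
#' from [read_gmt()]), in which case the union of the sets is used.
#'
#' @param a,b Gene lists.
#' @return A [gene_list()].
#' @export
intersect_lists <- function(a, b) {
  if (is.list(b)) b <- unique(unlist(lapply(b, as.character)))
  a <- as.character(a); b <- as.character(b)
  out <- a[a %in% b]
  msgf("intersect_lists: %d of %d gene(s) retained", length(out), length(a))
  gene_list(out, label = "intersection")
}
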