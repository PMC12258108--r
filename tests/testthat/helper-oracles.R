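# Independent oracles and small fixture builders. These deliberately use
# brute-force formulations (loops, enumeration) so they cannot share a
# code path with the implementation they check.

# all-pairs AUC: count wins and half-ties over positive x negative pairs
auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == -1]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# triple-loop unsigned TOM from an adjacency matrix with zero diagonal
tom_oracle <- function(A) {
  n <- nrow(A)
  k <- rowSums(A)
  T <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) {
      l <- 0
      for (u in seq_len(n)) if (u != i && u != j) l <- l + A[i, u] * A[u, j]
      T[i, j] <- (l + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
    }
  }
  dimnames(T) <- dimnames(A)
  T
}

# exhaustive minimum spanning tree: enumerate all (n-1)-edge subsets,
# keep those forming a spanning tree, return the minimal total distance
mst_total_oracle <- function(nodes, from, to, dist) {
  n <- length(nodes)
  m <- length(from)
  best <- Inf
  combos <- utils::combn(m, n - 1L)
  for (c_i in seq_len(ncol(combos))) {
    sel <- combos[, c_i]
    memb <- prognet:::components_of(nodes, from[sel], to[sel])
    if (max(memb) == 1L) best <- min(best, sum(dist[sel]))
  }
  best
}

# independent product-limit loop
km_oracle <- function(time, event) {
  et <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(et))
  for (j in seq_along(et)) {
    n_j <- sum(time >= et[j])
    d_j <- sum(time == et[j] & event == 1)
    s <- s * (1 - d_j / n_j)
    out[j] <- s
  }
  list(times = et, survival = out)
}

# adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Erdos-Renyi gene_network for property tests
random_graph <- function(n, p_edge = 0.05, weighted = FALSE, seed = 1) {
  set.seed(seed)
  genes <- sprintf("n%03d", seq_len(n))
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  on_e <- runif(nrow(ut)) < p_edge
  if (!any(on_e)) on_e[1L] <- TRUE
  gene_network(data.frame(
    from = genes[ut[on_e, 1L]], to = genes[ut[on_e, 2L]],
    weight = if (weighted) runif(sum(on_e), 0.1, 1) else 1,
    stringsAsFactors = FALSE), nodes = genes)
}

# small two-class expression fixture with known per-gene values
toy_expression <- function() {
  x <- rbind(gA = c(2, 4, 0, 2),
             gB = c(1, 1, 1, 2),
             gC = c(0, 1, 2, 3))
  colnames(x) <- paste0("s", 1:4)
  x
}

toy_pheno <- function() {
  data.frame(sample = paste0("s", 1:4), class = c(-1, -1, 1, 1),
             stringsAsFactors = FALSE)
}

# fast vectorized Gehan statistic for permutation nulls: fixed survival
# data, many group assignments at once (columns of G are 0/1 indicators)
gehan_stats_many <- function(time, event, G) {
  et <- sort(unique(time[event == 1]))
  AR <- vapply(et, function(t) as.numeric(time >= t), numeric(length(time)))
  DM <- vapply(et, function(t) as.numeric(time == t & event == 1),
               numeric(length(time)))
  AR <- t(AR); DM <- t(DM)                    # events x subjects
  n_j <- rowSums(AR)
  d_j <- rowSums(DM)
  N1 <- AR %*% G                              # events x perms
  D1 <- DM %*% G
  E1 <- d_j * N1 / n_j
  V <- N1 * (n_j - N1) * d_j * (n_j - d_j) / (n_j^2 * pmax(n_j - 1, 1))
  w <- n_j
  U <- colSums(w * (D1 - E1))
  VU <- colSums(w^2 * V)
  U^2 / VU
}
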