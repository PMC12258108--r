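test_that("pooled t and logFC match hand-derived values and conventions", {
  x <- matrix(c(2, 4, 0, 2), 1, 4,
              dimnames = list("gA", paste0("s", 1:4)))
  st <- differential_stats(x, toy_pheno())
  # means 3 vs 1, pooled variance (2+2)/2 = 2: t = 2 / sqrt(2 * (1/2+1/2))
  expect_equal(st$t, 2 / sqrt(2))
  expect_equal(st$logfc, 2)
  expect_gt(st$t, 0)                           # higher in poor class => positive
  xn <- matrix(c(1, 2, 1, 2), 1, 4,
               dimnames = list("gB", paste0("s", 1:4)))
  stn <- differential_stats(xn, toy_pheno())
  expect_equal(stn$t, 0)
  expect_equal(stn$logfc, 0)
  xz <- matrix(c(1, 1, 2, 2), 1, 4,
               dimnames = list("gC", paste0("s", 1:4)))
  expect_warning(stz <- differential_stats(xz, toy_pheno()), "zero pooled")
  expect_equal(stz$t, 0)
  p1 <- data.frame(sample = paste0("s", 1:4), class = c(-1, 1, 1, 1))
  expect_error(differential_stats(x, p1), ">= 2 samples")
})

test_that("kernel worked examples: identity, isolated node, two-node pair", {
  net <- gene_network(data.frame(from = "A", to = "B"), nodes = c("A", "B", "C"))
  k0 <- build_kernel(net, a = 2, p = 0)
  expect_equal(k0$K, diag(3), ignore_attr = TRUE)
  for (p in c(1L, 3L, 5L)) {
    kp <- build_kernel(net, a = 2, p = p)
    expect_equal(kp$K["C", "C"], 1)            # isolated: (a-1)^p = 1
    expect_equal(kp$K["C", "A"], 0)
  }
  net2 <- gene_network(data.frame(from = "A", to = "B"))
  k1 <- build_kernel(net2, a = 2, p = 1)
  expect_equal(k1$K, matrix(1, 2, 2), ignore_attr = TRUE)
  expect_error(build_kernel(net2, a = 1.5, p = 1), "a must be >= 2")
  expect_error(build_kernel(net2, a = 2, p = -1), "non-negative")
})

test_that("kernel is symmetric PSD with non-negative entries on random graphs", {
  for (seed in 1:10) {
    n <- sample(10:100, 1)
    net <- random_graph(n, p_edge = 0.08, weighted = seed %% 2 == 0,
                        seed = seed)
    K <- build_kernel(net, a = 2, p = 3)$K
    expect_equal(K, t(K))
    expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
               -1e-9)
    expect_gte(min(K), 0)
  }
})

test_that("p = 0 reduces the selector to raw |t| ranking with the logFC gate", {
  d <- simulate_dataset(sim_config(n_genes = 60, n_samples = 40,
                                   signature_size = 6, seed = 4))
  st <- differential_stats(standardize(d$expr), d$pheno)
  k0 <- build_kernel(d$net, a = 2, p = 0)
  tbl <- smooth_scores(st, k0)
  raw_order <- order(-abs(st$t), st$gene)
  expect_equal(tbl$gene[order(tbl$rank)], st$gene[raw_order])
  sel <- select_signature(tbl, top_frac = 0.2, min_abs_logfc = 0.1)
  k_top <- ceiling(0.2 * nrow(tbl))
  manual <- st$gene[raw_order][seq_len(k_top)]
  manual <- manual[abs(st$logfc[match(manual, st$gene)]) >= 0.1]
  expect_equal(as.character(sel), manual)
})

test_that("two-node smoothing ties break alphabetically; equivariance holds", {
  net <- gene_network(data.frame(from = "A", to = "B"))
  k <- build_kernel(net, a = 2, p = 1)
  st <- data.frame(gene = c("A", "B"), t = c(3, 1), logfc = c(1, 1))
  tbl <- smooth_scores(st, k)
  expect_equal(tbl$smoothed, c(1, 1))          # s = (4, 4) rescaled
  expect_equal(tbl$rank[tbl$gene == "A"], 1L)  # alphabetical tie-break
  # permuting gene labels permutes scores identically
  net3 <- random_graph(15, p_edge = 0.2, seed = 7)
  set.seed(8)
  tvals <- rnorm(15)
  st3 <- data.frame(gene = net3$nodes, t = tvals, logfc = tvals)
  s1 <- smooth_scores(st3, build_kernel(net3))
  perm <- setNames(sprintf("z%03d", sample(15)), net3$nodes)
  e <- net3$edges
  netp <- gene_network(data.frame(from = unname(perm[e$from]),
                                  to = unname(perm[e$to]),
                                  weight = e$weight),
                       nodes = unname(perm))
  stp <- st3
  stp$gene <- unname(perm[st3$gene])
  s2 <- smooth_scores(stp, build_kernel(netp))
  expect_equal(s2$smoothed[match(perm[s1$gene], s2$gene)], s1$smoothed,
               tolerance = 1e-12)
})

test_that("raising a gene's |t| never lowers its own (unscaled) score", {
  net <- random_graph(30, p_edge = 0.1, seed = 5)
  K <- build_kernel(net, a = 2, p = 3)$K
  expect_gte(min(K), 0)                        # guards the monotonicity claim
  set.seed(6)
  tv <- abs(rnorm(30))
  s0 <- as.numeric(K %*% tv)
  for (g in c(1, 10, 30)) {
    tv2 <- tv
    tv2[g] <- tv[g] + 1
    s1 <- as.numeric(K %*% tv2)
    expect_gte(s1[g], s0[g])
  }
})

test_that("selection gates: ceiling rule, conjunction, no-gate limit, empty", {
  tbl <- data.frame(gene = letters[1:10], raw = 10:1, logfc = rep(1, 10),
                    smoothed = seq(1, 0.1, by = -0.1), rank = 1:10)
  expect_length(select_signature(tbl, top_frac = 1, min_abs_logfc = 0), 10L)
  expect_length(select_signature(tbl, top_frac = 0.3, min_abs_logfc = 0), 3L)
  tbl$logfc[1] <- 0.1                          # rank-1 gene fails the gate
  sel <- select_signature(tbl, top_frac = 0.3, min_abs_logfc = 0.5)
  expect_false("a" %in% sel)
  expect_equal(as.character(sel), c("b", "c"))
  expect_warning(sel0 <- select_signature(tbl, 0.1, 99), "no genes")
  expect_length(sel0, 0L)
  expect_error(select_signature(tbl, 0, 0.5), "top_frac")
})

test_that("network smoothing beats raw |t| at the default effect size", {
  # planted connected signature, generator defaults (delta = 0.5): over 30
  # replicates the smoothed top-k recalls strictly more planted genes on
  # average than the raw-|t| top-k
  recalls <- vapply(1:30, function(seed) {
    d <- simulate_dataset(sim_config(n_genes = 1000, n_samples = 200,
                                     signature_size = 20, seed = 100 + seed))
    st <- differential_stats(standardize(d$expr), d$pheno)
    kern <- build_kernel(d$net, a = 2, p = 3)
    tbl <- smooth_scores(st, kern)
    k_top <- ceiling(0.05 * nrow(tbl))
    sm <- tbl$gene[order(tbl$rank)][seq_len(k_top)]
    raw <- st$gene[order(-abs(st$t), st$gene)][seq_len(k_top)]
    truth <- d$truth$signature
    c(mean(truth %in% sm), mean(truth %in% raw))
  }, numeric(2))
  expect_gt(mean(recalls[1, ]), mean(recalls[2, ]))
})
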