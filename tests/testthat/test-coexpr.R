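test_that("TOM worked examples and triple-loop oracle agreement", {
  # 3-gene clique with |cor| = 1 everywhere: TOM = 1 for every pair
  v <- c(1, 3, 2, 5, 4)
  x <- rbind(a = v, b = 2 * v, c = v - 3)
  colnames(x) <- paste0("s", 1:5)
  tn <- tom(x, beta = 1)
  expect_equal(attr(tn, "tom"), matrix(1, 3, 3), ignore_attr = TRUE)
  # orthogonal pair, no shared neighbors: TOM = 0 off-diagonal
  y <- rbind(a = c(1, -1, 1, -1), b = c(1, 1, -1, -1))
  colnames(y) <- paste0("s", 1:4)
  ty <- attr(tom(y, 1), "tom")
  expect_equal(ty["a", "b"], 0)
  # random 6-gene matrix vs independent oracle
  set.seed(14)
  z <- matrix(rnorm(60), 6, 10,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  for (beta in c(1L, 3L)) {
    A <- abs(cor(t(z)))^beta
    diag(A) <- 0
    expect_equal(attr(tom(z, beta), "tom"), tom_oracle(A),
                 tolerance = 1e-12)
  }
  T <- attr(tom(z, 2), "tom")
  expect_equal(T, t(T))
  expect_true(all(T >= 0 & T <= 1))
  expect_equal(unname(diag(T)), rep(1, 6))
})

test_that("module detection: perfect blocks, empty structure, size labels", {
  genes <- c(paste0("a", 1:4), paste0("b", 1:3))
  block <- rep(c("A", "B"), c(4, 3))
  pairs <- t(combn(genes, 2))
  same <- block[match(pairs[, 1], genes)] == block[match(pairs[, 2], genes)]
  net <- gene_network(data.frame(from = pairs[same, 1], to = pairs[same, 2],
                                 weight = 1), nodes = genes)
  mods <- detect_modules(net, cut_height = 0.8, min_size = 3)
  expect_equal(unname(mods$assignment[paste0("a", 1:4)]),
               rep("turquoise", 4))            # larger block first
  expect_equal(unname(mods$assignment[paste0("b", 1:3)]), rep("blue", 3))
  empty <- gene_network(data.frame(from = character(), to = character()),
                        nodes = genes)
  mods0 <- detect_modules(empty, 0.8, 3)
  expect_true(all(mods0$assignment == "grey"))
})

test_that("planted 3-block data are recovered with high adjusted Rand index", {
  for (seed in 1:5) {
    d <- simulate_dataset(sim_config(n_genes = 90, n_samples = 80,
                                     signature_size = 10, module_blocks = 3,
                                     seed = 40 + seed))
    xs <- standardize(d$expr)
    mods <- detect_modules(tom(xs, beta = 2), cut_height = 0.8,
                           min_size = 10)
    expect_gte(ari(mods$assignment, d$truth$blocks[names(mods$assignment)]),
               0.9)
  }
})

test_that("module assignment is invariant to gene input order", {
  d <- simulate_dataset(sim_config(n_genes = 60, n_samples = 50,
                                   signature_size = 8, seed = 46))
  xs <- standardize(d$expr)
  m1 <- detect_modules(tom(xs, 2), 0.8, 5)
  set.seed(1)
  m2 <- detect_modules(tom(xs[sample(nrow(xs)), ], 2), 0.8, 5)
  expect_equal(m1$assignment[sort(names(m1$assignment))],
               m2$assignment[sort(names(m2$assignment))])
})

test_that("eigengenes: perfectly correlated module reproduces the member profile", {
  v <- rnorm(12)
  x <- rbind(a = v, b = 3 * v + 1, c = -2 * v)
  colnames(x) <- paste0("s", 1:12)
  mods <- structure(list(assignment = c(a = "turquoise", b = "turquoise",
                                        c = "turquoise")),
                    class = "module_set")
  me <- module_eigengenes(mods, x)
  expect_equal(sum(me[, 1]^2), 1)              # unit norm
  expect_equal(abs(cor(me[, 1], v)), 1, tolerance = 1e-8)
  # sign orientation: mean correlation with module genes is non-negative
  expect_gte(mean(cor(me[, 1], t(standardize(x)))), 0)
})

test_that("module-trait correlation matches the direct formula", {
  d <- simulate_dataset(sim_config(n_genes = 60, n_samples = 50,
                                   signature_size = 8, seed = 47))
  xs <- standardize(d$expr)
  mods <- detect_modules(tom(xs, 2), 0.8, 5, expr = xs)
  mods <- module_trait(mods, d$pheno, c("class", "time"))
  me <- mods$eigengenes
  n <- nrow(me)
  for (m in colnames(me)) for (tr in c("class", "time")) {
    r <- cor(me[, m], as.numeric(d$pheno[[tr]]))
    tv <- r * sqrt((n - 2) / (1 - r^2))
    expect_equal(mods$trait_cor$r[m, tr], r, tolerance = 1e-12)
    expect_equal(mods$trait_cor$p[m, tr], 2 * pt(-abs(tv), n - 2),
                 tolerance = 1e-12)
  }
  # self-correlation and constructed orthogonality
  ph <- d$pheno
  ph$me_copy <- me[, 1]
  ph$ortho <- rnorm(n)
  ph$ortho <- resid(lm(ph$ortho ~ me[, 1]))
  mods2 <- module_trait(mods, ph, c("me_copy", "ortho"))
  expect_equal(mods2$trait_cor$r[1, "me_copy"], 1, tolerance = 1e-12)
  expect_lt(mods2$trait_cor$p[1, "me_copy"], 1e-12)
  expect_equal(mods2$trait_cor$r[1, "ortho"], 0, tolerance = 1e-12)
  ph$flat <- 1
  expect_warning(module_trait(mods, ph, "flat"), "constant")
})

test_that("soft-threshold scan: scale-free positive control and noise null", {
  x <- simulate_scalefree_expression(400, 100, seed = 2)
  scan <- scan_soft_threshold(x, betas = 1:20, r2_cut = 0.85)
  expect_lte(scan$chosen_beta, 20L)
  expect_gte(scan$scan$fit_r2[scan$scan$beta == scan$chosen_beta], 0.85)
  set.seed(77)
  noise <- matrix(rnorm(500 * 60), 500, 60,
                  dimnames = list(sprintf("g%03d", 1:500),
                                  sprintf("s%02d", 1:60)))
  sn <- suppressWarnings(scan_soft_threshold(noise, betas = 1L, r2_cut = 0.85))
  expect_lt(abs(sn$scan$fit_r2[1]), 0.3)
  # correlation scale invariance
  s1 <- scan_soft_threshold(x, betas = 1:6, r2_cut = 0.85)
  s2 <- scan_soft_threshold(2 * x, betas = 1:6, r2_cut = 0.85)
  expect_equal(s1$scan, s2$scan, tolerance = 1e-12)
  const <- rbind(x[1:20, ], flat = rep(1, 100))
  expect_error(scan_soft_threshold(const, 1:3), "constant")
})
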