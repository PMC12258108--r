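#' Configuration for the synthetic-data generator
#'
#' The generator emulates the statistical structure the pipeline assumes:
#' two prognosis classes with a differential signature planted on a
#' connected subgraph of a scale-free interaction network,
#' block-correlated co-expression (the signature occupies block 1),
#' optional additive batch shifts, and exponential survival whose hazard
#' increases with mean signature expression.
#'
#' Default choices: 1000 genes x 200 samples (two balanced classes of
#' 100); preferential-attachment graph with m = 2; signature of 20 genes;
#' standardized effect size delta = 0.5 (a moderate effect that leaves
#' the selection problem genuinely hard at n = 200 — per-gene |t| around
#' 3.5 against a 1000-gene noise floor of about 3.2); within-block
#' correlation rho = 0.6 over 3 blocks; baseline hazard 3e-4 per day
#' (median survival around 6 years at the signature mean); hazard
#' coefficient 1 per unit mean signature expression; 30% target censoring.
#'
#' @param n_genes Number of genes (>= 10).
#' @param n_samples Number of samples (balanced classes).
#' @param graph_model `"preferential_attachment"` or `"stochastic_block"`.
#' @param pa_m Edges added per node for preferential attachment.
#' @param p_in,p_out Within/between-community edge probabilities for the
#'   stochastic block graph.
#' @param signature_size Planted signature size (connected subgraph).
#' @param effect_size Standardized mean shift added to signature genes in
#'   the poor-prognosis class.
#' @param module_blocks Number of co-expression blocks (signature genes
#'   all sit in block 1).
#' @param rho Within-block correlation in \[0, 1).
#' @param batch_shift Additive shift applied to a random half of samples
#'   (0 disables the batch variable).
#' @param baseline_hazard Baseline exponential hazard per day.
#' @param hazard_coef Log-hazard increase per unit mean signature
#'   expression.
#' @param censor_frac Target fraction of censored samples.
#' @param seed Integer seed; the entire dataset is a pure function of
#'   this configuration.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000, n_samples = 200,
                       graph_model = c("preferential_attachment",
                                       "stochastic_block"),
                       pa_m = 2, p_in = 0.05, p_out = 0.005,
                       signature_size = 20, effect_size = 0.5,
                       module_blocks = 3, rho = 0.6, batch_shift = 0,
                       baseline_hazard = 3e-4, hazard_coef = 1,
                       censor_frac = 0.3, seed = 1) {
  graph_model <- match.arg(graph_model)
  if (!is_count(n_genes) || n_genes < 10) abort("n_genes must be >= 10")
  if (!is_count(n_samples) || n_samples < 4) abort("n_samples must be >= 4")
  if (!is_count(signature_size) || signature_size > n_genes)
    abort("signature_size must be an integer <= n_genes")
  if (!is_scalar_num(rho) || rho < 0 || rho >= 1) abort("rho must be in [0, 1)")
  if (!is_scalar_num(censor_frac) || censor_frac < 0 || censor_frac >= 1)
    abort("censor_frac must be in [0, 1)")
  if (!is_count(module_blocks) || module_blocks < 1) abort("module_blocks must be >= 1")
  if (!is_count(seed)) abort("seed must be an integer")
  structure(list(n_genes = as.integer(n_genes),
                 n_samples = as.integer(n_samples),
                 graph_model = graph_model, pa_m = as.integer(pa_m),
                 p_in = p_in, p_out = p_out,
                 signature_size = as.integer(signature_size),
                 effect_size = effect_size,
                 module_blocks = as.integer(module_blocks), rho = rho,
                 batch_shift = batch_shift,
                 baseline_hazard = baseline_hazard,
                 hazard_coef = hazard_coef, censor_frac = censor_frac,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config: %d genes x %d samples, %s graph, ",
                     "signature %d @ delta %g, seed %d\n"),
              x$n_genes, x$n_samples, x$graph_model, x$signature_size,
              x$effect_size, x$seed))
  invisible(x)
}

sim_gene_names <- function(n) sprintf("g%04d", seq_len(n))

#' Simulate a gene interaction network with a planted connected signature
#'
#' Preferential attachment (the default) starts from a single edge and
#' attaches each new node to `pa_m` distinct existing nodes with
#' probability proportional to degree, giving exactly
#' 1 + sum_t min(pa_m, t - 1) edges and a connected scale-free graph.
#' The signature is a connected subgraph collected by breadth-first
#' search from a random seed node and stored in attribute `"signature"`.
#'
#' @param cfg A [sim_config()].
#' @return A [gene_network()] with attribute `signature`.
#' @export
simulate_network <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  restore <- .Random.seed.exists()
  on.exit(restore())
  set.seed(cfg$seed)
  genes <- sim_gene_names(cfg$n_genes)
  n <- cfg$n_genes
  if (cfg$graph_model == "preferential_attachment") {
    deg <- numeric(n)
    from_i <- integer(0); to_i <- integer(0)
    from_i <- 1L; to_i <- 2L
    deg[1:2] <- 1
    for (t in 3:n) {
      m <- min(cfg$pa_m, t - 1L)
      targets <- sample(seq_len(t - 1L), size = m, prob = deg[seq_len(t - 1L)])
      from_i <- c(from_i, rep(t, m)); to_i <- c(to_i, targets)
      deg[t] <- deg[t] + m
      deg[targets] <- deg[targets] + 1
    }
    edges <- data.frame(from = genes[pmin(from_i, to_i)],
                        to = genes[pmax(from_i, to_i)],
                        weight = 1, stringsAsFactors = FALSE)
  } else {
    comm <- rep_len(seq_len(cfg$module_blocks), n)
    ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    pr <- ifelse(comm[ut[, 1L]] == comm[ut[, 2L]], cfg$p_in, cfg$p_out)
    on_edge <- stats::runif(nrow(ut)) < pr
    edges <- data.frame(from = genes[ut[on_edge, 1L]],
                        to = genes[ut[on_edge, 2L]],
                        weight = 1, stringsAsFactors = FALSE)
  }
  net <- gene_network(edges, nodes = genes)
  # breadth-first signature from a random seed node in a large-enough
  # component
  adj <- split(c(net$edges$to, net$edges$from),
               c(net$edges$from, net$edges$to))
  memb <- components_of(net$nodes, net$edges$from, net$edges$to)
  comp_sizes <- table(memb)
  big <- as.integer(names(comp_sizes)[comp_sizes >= cfg$signature_size])
  if (length(big) == 0L)
    abort("no connected component holds %d genes", cfg$signature_size)
  pool <- net$nodes[memb %in% big]
  start <- sample(pool, 1L)
  seen <- start; queue <- start
  while (length(seen) < cfg$signature_size && length(queue) > 0L) {
    cur <- queue[1L]; queue <- queue[-1L]
    nbr <- sort(setdiff(adj[[cur]] %||% character(0), seen))
    take <- utils::head(nbr, cfg$signature_size - length(seen))
    seen <- c(seen, take)
    queue <- c(queue, take)
  }
  attr(net, "signature") <- sort(seen)
  net
}

#' Simulate expression, phenotype and survival over a network
#'
#' Block factor model x_gi = sqrt(rho) f_b(g),i + sqrt(1 - rho) eps_gi
#' with standard normal factors and noise; balanced class labels drawn
#' first; the poor-prognosis class (-1) gets `effect_size` added on the
#' planted signature genes; an optional batch shift is added to a random
#' half of the samples (after survival is generated, so the batch is pure
#' nuisance); survival times are exponential with hazard
#' `baseline_hazard * exp(hazard_coef * z_i)` where z_i is the mean
#' signature expression, and censoring times are exponential with a rate
#' calibrated analytically to the target censoring fraction.
#'
#' @param cfg A [sim_config()].
#' @param net Network from [simulate_network()] (carries the signature).
#' @return List: `expr`, `pheno` (sample, class, time, event, batch),
#'   `truth` (signature, blocks, config).
#' @export
simulate_expression <- function(cfg, net) {
  stopifnot(inherits(cfg, "sim_config"), inherits(net, "gene_network"))
  signature <- attr(net, "signature")
  if (is.null(signature)) abort("network carries no planted signature")
  restore <- .Random.seed.exists()
  on.exit(restore())
  set.seed(cfg$seed + 1L)
  genes <- net$nodes
  G <- length(genes); n <- cfg$n_samples; B <- cfg$module_blocks
  samples <- sprintf("s%04d", seq_len(n))
  # block assignment: signature genes fill block 1 first, the rest
  # round-robin for near-equal sizes
  blocks <- integer(G); names(blocks) <- genes
  blocks[signature] <- 1L
  rest <- setdiff(genes, signature)
  target <- ceiling(G / B)
  take1 <- min(max(0L, target - length(signature)), length(rest))
  if (take1 > 0L) blocks[rest[seq_len(take1)]] <- 1L
  remaining <- if (take1 > 0L) rest[-seq_len(take1)] else rest
  if (length(remaining) > 0L && B > 1L)
    blocks[remaining] <- rep_len(seq_len(B - 1L) + 1L, length(remaining))
  if (B == 1L) blocks[] <- 1L
  cls <- sample(rep_len(c(-1, 1), n))
  f <- matrix(stats::rnorm(B * n), B, n)
  eps <- matrix(stats::rnorm(G * n), G, n)
  x <- sqrt(cfg$rho) * f[blocks, , drop = FALSE] +
    sqrt(1 - cfg$rho) * eps
  dimnames(x) <- list(genes, samples)
  x[signature, cls == -1] <- x[signature, cls == -1] + cfg$effect_size
  z <- colMeans(x[signature, , drop = FALSE])
  rate <- cfg$baseline_hazard * exp(cfg$hazard_coef * z)
  T_event <- stats::rexp(n, rate = rate)
  if (cfg$censor_frac > 0) {
    # P(C < T | z_i) = lc / (lc + rate_i); calibrate lc so the mean hits
    # the target censoring fraction
    lc <- stats::uniroot(function(loglc) {
      mean(exp(loglc) / (exp(loglc) + rate)) - cfg$censor_frac
    }, interval = log(c(1e-12, 1e6)))$root
    C_time <- stats::rexp(n, rate = exp(lc))
  } else {
    C_time <- rep(Inf, n)
  }
  time <- pmin(T_event, C_time)
  event <- as.integer(T_event <= C_time)
  if (cfg$batch_shift != 0) {
    batch <- rep("b1", n)
    batch[sample(n, floor(n / 2))] <- "b2"
    x[, batch == "b2"] <- x[, batch == "b2"] + cfg$batch_shift
  } else {
    batch <- rep("b1", n)
  }
  pheno <- data.frame(sample = samples, class = cls, time = time,
                      event = event, batch = batch,
                      stringsAsFactors = FALSE)
  list(expr = x, pheno = pheno,
       truth = list(signature = signature, blocks = blocks,
                    config = unclass(cfg)))
}

#' Simulate a complete dataset (network + expression + phenotype)
#' @param cfg A [sim_config()].
#' @return List: `expr`, `pheno`, `net`, `truth`.
#' @export
simulate_dataset <- function(cfg) {
  net <- simulate_network(cfg)
  out <- simulate_expression(cfg, net)
  out$net <- net
  out
}

#' Simulate expression with scale-free co-expression topology
#'
#' Single-latent-factor model with heterogeneous membership: gene i is
#' x_i = m_i f + sqrt(1 - m_i^2) eps_i with m_i ~ Uniform(0, 1), so the
#' soft-thresholded connectivity k_i proportional to m_i^beta follows a
#' power law and the scale-free fit index of [scan_soft_threshold()] is
#' high at moderate powers. This is the positive-control world for the
#' soft-threshold scan (block-correlated data, by design, are not
#' scale-free).
#'
#' @param n_genes,n_samples Dimensions.
#' @param seed Integer seed.
#' @return Genes x samples matrix.
#' @export
simulate_scalefree_expression <- function(n_genes = 500, n_samples = 100,
                                          seed = 1) {
  restore <- .Random.seed.exists()
  on.exit(restore())
  set.seed(seed)
  m <- stats::runif(n_genes)
  f <- stats::rnorm(n_samples)
  eps <- matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples)
  x <- outer(m, f) + sqrt(1 - m^2) * eps
  dimnames(x) <- list(sim_gene_names(n_genes),
                      sprintf("s%04d", seq_len(n_samples)))
  x
}
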