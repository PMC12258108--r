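make_batch_data <- function(n_genes = 5, shift = 2, class_effect = 0,
                            seed = 11) {
  set.seed(seed)
  n <- 20
  x <- matrix(rnorm(n_genes * n), n_genes, n,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n))))
  batch <- rep(c("b1", "b2"), each = n / 2)
  cls <- rep(c(-1, 1), times = n / 2)          # class balanced across batches
  x[, batch == "b2"] <- x[, batch == "b2"] + shift
  x[, cls == -1] <- x[, cls == -1] + class_effect
  list(expr = x,
       pheno = data.frame(sample = colnames(x), class = cls, batch = batch,
                          stringsAsFactors = FALSE))
}

test_that("remove_batch recovers a constant two-batch shift exactly", {
  # noiseless toy design: every gene constant within batch, batches differ
  # by +2; closed-form least squares gives sum-to-zero coefficients -1/+1
  # and the corrected matrix equals the batch-mean-centered one
  base <- matrix(rep(c(3, 7, -1, 0, 2), 20), 5, 20,
                 dimnames = list(sprintf("g%02d", 1:5),
                                 sprintf("s%02d", 1:20)))
  batch <- rep(c("b1", "b2"), each = 10)
  base[, batch == "b2"] <- base[, batch == "b2"] + 2
  d <- list(expr = base,
            pheno = data.frame(sample = colnames(base),
                               class = rep(c(-1, 1), times = 10),
                               batch = batch, stringsAsFactors = FALSE))
  res <- remove_batch(d$expr, d$pheno)
  expect_equal(unname(res$model$coefficients[1, ]), c(-1, 1),
               tolerance = 1e-9)
  centered <- d$expr
  for (b in unique(d$pheno$batch)) {
    cols <- d$pheno$batch == b
    centered[, cols] <- d$expr[, cols] -
      rowMeans(d$expr[, cols]) + rowMeans(d$expr)
  }
  expect_equal(res$expr, centered, tolerance = 1e-9)
  expect_equal(rowSums(res$model$coefficients), rep(0, 5),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("identical batches give zero coefficients and unchanged data", {
  set.seed(3)
  x <- matrix(rnorm(40), 4, 10,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  x[, 6:10] <- x[, 1:5]                        # duplicate distribution
  p <- data.frame(sample = colnames(x), class = rep(c(-1, 1), 5),
                  batch = rep(c("b1", "b2"), each = 5))
  res <- remove_batch(x, p)
  expect_equal(max(abs(res$model$coefficients)), 0, tolerance = 1e-12)
  expect_equal(res$expr, x, tolerance = 1e-12)
})

test_that("class fully confounded with batch is rejected", {
  d <- make_batch_data()
  d$pheno$class <- ifelse(d$pheno$batch == "b1", -1, 1)
  expect_error(remove_batch(d$expr, d$pheno), "aliased|rank")
  d$pheno$batch[1] <- "b3"                     # singleton batch level
  expect_error(remove_batch(d$expr, d$pheno), "< 2 samples")
})

test_that("class signal survives correction and batch means equalize", {
  # clean data + batch shift: correction must reproduce the clean logFC
  # exactly (class is balanced within batches, so the subtracted per-batch
  # constants cancel between classes) and equalize per-gene batch means
  set.seed(21)
  clean <- matrix(rnorm(100), 5, 20,
                  dimnames = list(sprintf("g%02d", 1:5),
                                  sprintf("s%02d", 1:20)))
  batch <- rep(c("b1", "b2"), each = 10)
  cls <- rep(c(-1, 1), times = 10)
  clean[, cls == -1] <- clean[, cls == -1] + 1.5
  pheno <- data.frame(sample = colnames(clean), class = cls, batch = batch,
                      stringsAsFactors = FALSE)
  shifted <- clean
  shifted[, batch == "b2"] <- shifted[, batch == "b2"] + 3
  res <- remove_batch(shifted, pheno)
  for (g in rownames(clean)) {
    m1 <- mean(res$expr[g, batch == "b1"])
    m2 <- mean(res$expr[g, batch == "b2"])
    expect_equal(m1, m2, tolerance = 1e-9)     # class balanced across batches
  }
  st_clean <- differential_stats(clean, pheno)
  st_corr <- differential_stats(res$expr, pheno)
  expect_equal(st_corr$logfc, st_clean$logfc, tolerance = 1e-9)
})

test_that("remove_batch agrees with the reference limma implementation", {
  skip_if_not_installed("limma")
  d <- make_batch_data(shift = 2.5, class_effect = 1, seed = 31)
  res <- remove_batch(d$expr, d$pheno)
  ref <- limma::removeBatchEffect(
    d$expr, batch = d$pheno$batch,
    design = stats::model.matrix(~cls, data.frame(cls = d$pheno$class)))
  expect_equal(res$expr, ref, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("standardize: exact rows, degenerate rows, idempotence", {
  x <- rbind(a = c(1, 2, 3), b = c(5, 5, 5))
  colnames(x) <- paste0("s", 1:3)
  expect_warning(z <- standardize(x), "constant")
  expect_equal(unname(z["a", ]), c(-1, 0, 1))
  expect_equal(unname(z["b", ]), c(0, 0, 0))
  set.seed(9)
  y <- matrix(rnorm(50), 5, 10,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  z1 <- standardize(y)
  expect_equal(standardize(z1), z1, tolerance = 1e-12)
  expect_error(standardize(y[, 1, drop = FALSE]), ">= 2 samples")
})
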