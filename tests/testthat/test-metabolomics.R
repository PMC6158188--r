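# Pool-table preprocessing, PCA, heatmap ordering, NIPALS PLS and VIP.

make_small_pools <- function() {
  set.seed(42)
  vals <- matrix(rlnorm(5 * 6, 1, 0.4), 5, 6,
                 dimnames = list(paste0("m", 1:5), NULL))
  pool_table(vals, time_h = rep(c(10, 20, 30), each = 2),
             replicate = rep(1:2, 3))
}

test_that("preprocessing imputes, centers, scales and drops constants", {
  tab <- make_small_pools()
  tab$values[2, 3] <- NA
  tab$values[5, ] <- 7                         # constant row
  expect_warning(prep <- preprocess_pools(tab), "constant")
  expect_false("m5" %in% rownames(prep$values))
  expect_equal(attr(prep, "dropped"), "m5")
  expect_equal(unname(rowMeans(prep$values)), rep(0, 4), tolerance = 1e-10)
  expect_equal(unname(apply(prep$values, 1, sd)), rep(1, 4), tolerance = 1e-10)
  # imputed cell was min/2 of its row before scaling
  raw <- tab$values[2, ]
  imputed <- min(raw, na.rm = TRUE) / 2
  centered <- (imputed - mean(replace(raw, 3, imputed))) /
    sd(replace(raw, 3, imputed))
  expect_equal(unname(prep$values[2, 3]), unname(centered))
  # pareto scaling divides by sqrt(sd)
  tab2 <- make_small_pools()
  prep2 <- preprocess_pools(tab2, scale = "pareto")
  sds <- apply(tab2$values - rowMeans(tab2$values), 1, sd)
  expect_equal(unname(apply(prep2$values, 1, sd)), unname(sqrt(sds)),
               tolerance = 1e-10)
  # too many missing values is an error
  tab3 <- make_small_pools()
  tab3$values[1, 1:3] <- NA
  expect_error(preprocess_pools(tab3), "missing")
})

test_that("PCA reproduces the covariance eigendecomposition", {
  set.seed(7)
  X <- matrix(rnorm(20), 5, 4)          # 5 samples x 4 variables
  pca <- run_pca(X)
  ev <- eigen(cov(scale(X, scale = FALSE)))
  lam <- ev$values[ev$values > 1e-12]
  expect_equal(pca$explained_variance_fraction, lam / sum(lam),
               tolerance = 1e-8)
  # loadings match eigenvectors up to sign
  for (a in seq_along(lam))
    expect_equal(abs(sum(pca$loadings[, a] * ev$vectors[, a])), 1,
                 tolerance = 1e-8)
  # scores are orthogonal and reconstruct the centered matrix
  G <- crossprod(pca$scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
  Xc <- scale(X, scale = FALSE)
  expect_lt(norm(Xc - pca$scores %*% t(pca$loadings), "F"), 1e-8)
})

test_that("single-axis data loads one component; rank truncation notices", {
  t_vec <- seq(0, 1, length.out = 6)
  X <- outer(t_vec, c(1, 2, -1))        # rank 1
  pca <- run_pca(X)
  expect_equal(pca$explained_variance_fraction[1], 1, tolerance = 1e-10)
  expect_message(run_pca(X, n_components = 3), "truncating")
})

test_that("planted three-group pools are recovered from PC1-2", {
  skip_if_no("mclust")
  syn <- make_synthetic_pools(n_informative = 15, n_trend = 15, seed = 11)
  pca <- run_pca(preprocess_pools(syn$table))
  km <- kmeans(pca$scores[, 1:2], centers = 3, nstart = 20)
  expect_gte(mclust::adjustedRandIndex(km$cluster, syn$group), 0.9)
})

test_that("heatmap ordering agrees with brute-force agglomeration", {
  set.seed(3)
  X <- matrix(rnorm(24), 6, 4, dimnames = list(paste0("r", 1:6), paste0("c", 1:4)))
  ord <- heatmap_order(X)
  expect_setequal(ord$row_order, rownames(X))
  hc <- hclust(dist(X), method = "complete")
  orc <- agglomerate_oracle(X)
  expect_equal(hc$height, orc$heights, tolerance = 1e-10)
  # partitions after each merge coincide
  for (k in seq_len(nrow(X) - 1)) {
    cut_groups <- split(seq_len(nrow(X)), cutree(hc, k = nrow(X) - k))
    expect_equal(canonical_partition(cut_groups),
                 canonical_partition(orc$partitions[[k]]))
  }
  # identical rows sit on adjacent leaves; a single row is a singleton order
  X2 <- rbind(X, r7 = X["r2", ])
  ord2 <- heatmap_order(X2)
  expect_equal(abs(diff(match(c("r2", "r7"), ord2$row_order))), 1)
  expect_equal(heatmap_order(X["r1", , drop = FALSE])$row_order, "r1")
})

test_that("pool tables round-trip through the two-header TSV layout", {
  tab <- make_small_pools()
  p <- tempfile(fileext = ".tsv")
  write_pool_table(tab, p)
  tab2 <- read_pool_table(p)
  expect_equal(tab2$values, tab$values, tolerance = 1e-9)
  expect_equal(tab2$samples$time_h, tab$samples$time_h)
})

## ---- PLS / VIP -----------------------------------------------------------

test_that("the first PLS weight concentrates on an exactly predictive column", {
  # y equals column 3; with enough samples the chance covariance of the
  # other columns with y vanishes and the first weight is all column 3
  set.seed(5)
  X <- matrix(rnorm(400 * 8), 400, 8)
  y <- X[, 3]
  fit <- fit_pls(scale(X), scale(y)[, 1], n_components = 1)
  w <- fit$weights[, 1]
  expect_gt(abs(w[3]), 0.99)
})

test_that("a saturated fit drives the training residual to zero", {
  # with more variables than samples the centered X spans the centered
  # response space, so the full-rank fit interpolates
  set.seed(6)
  X <- matrix(rnorm(8 * 12), 8, 12)
  y <- rnorm(8)
  fit <- fit_pls(X, y, n_components = 7)
  expect_lt(max(abs(fit$residual_y)), 1e-8)
  expect_equal(fit$fitted, y, tolerance = 1e-8)
})

test_that("VIP normalization identity holds and p = 1 gives VIP = 1", {
  set.seed(8)
  for (s in 1:5) {
    X <- matrix(rnorm(12 * 10), 12, 10)
    y <- X %*% rnorm(10) + rnorm(12, 0, 0.3)
    vip <- compute_vip(fit_pls(scale(X), y[, 1] - mean(y), 3))
    expect_equal(mean(vip$vip^2), 1, tolerance = 1e-8)
  }
  X1 <- matrix(rnorm(10), 10, 1)
  vip1 <- compute_vip(fit_pls(X1, X1[, 1] * 2 + rnorm(10, 0, 0.1), 1))
  expect_equal(unname(vip1$vip), 1, tolerance = 1e-10)
})

test_that("zero-variance response and empty models raise errors", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(fit_pls(X, rep(1, 10)), "zero variance")
})

test_that("planted informative metabolites all exceed VIP 1 (seeds 1-10)", {
  for (s in 1:10) {
    syn <- make_synthetic_pools(seed = s)     # 5 informative in 50
    prep <- preprocess_pools(syn$table)
    vip <- compute_vip(fit_pls(t(prep$values), syn$q_O2, n_components = 2))
    expect_true(all(vip$vip[syn$informative] > 1),
                label = paste("seed", s, "informative VIP > 1"))
  }
})

test_that("PLS recovers planted weights and beats permuted responses", {
  set.seed(9)
  cors <- replicate(20, {
    w_true <- rnorm(30); w_true <- w_true / sqrt(sum(w_true^2))
    Tt <- rnorm(16)
    X <- outer(Tt, w_true) + matrix(rnorm(16 * 30, 0, 0.1), 16, 30)
    y <- Tt + rnorm(16, 0, 0.1)
    fit <- fit_pls(X, y, n_components = 1)
    abs(cor(fit$weights[, 1], w_true))
  })
  expect_true(all(cors >= 0.95))
  # permutation null: true fit explains more response SS than permuted y
  set.seed(10)
  w_true <- rnorm(30); Tt <- rnorm(16)
  X <- outer(Tt, w_true) + matrix(rnorm(16 * 30, 0, 0.1), 16, 30)
  y <- Tt + rnorm(16, 0, 0.1)
  ss_true <- sum(fit_pls(X, y, 1)$ss_response)
  ss_perm <- replicate(100, sum(fit_pls(X, sample(y), 1)$ss_response))
  expect_gt(ss_true, max(ss_perm))
})

test_that("NIPALS agrees with an independent PLS implementation", {
  skip_if_no("mixOmics")
  set.seed(12)
  X <- scale(matrix(rnorm(14 * 6), 14, 6))
  y <- as.vector(scale(X %*% rnorm(6) + rnorm(14, 0, 0.2)))
  fit <- fit_pls(X, y, n_components = 2)
  ref <- mixOmics::pls(X, y, ncomp = 2, scale = FALSE, mode = "regression")
  for (a in 1:2) {
    expect_equal(abs(cor(fit$scores[, a], ref$variates$X[, a])), 1,
                 tolerance = 1e-6)
    expect_equal(abs(sum(fit$weights[, a] * ref$loadings$X[, a] /
                           sqrt(sum(ref$loadings$X[, a]^2)))), 1,
                 tolerance = 1e-6)
  }
})

test_that("leave-one-out Q2 picks a sensible component count", {
  set.seed(13)
  Tt <- rnorm(20); w <- rnorm(10)
  X <- outer(Tt, w) + matrix(rnorm(200, 0, 0.2), 20, 10)
  y <- Tt + rnorm(20, 0, 0.2)
  pick <- choose_ncomp_q2(X, y, max_components = 4)
  expect_true(pick$n_components %in% 1:2)      # one real latent axis
  expect_gt(max(pick$q2), 0.8)
})

test_that("PLS-DA with dummy-coded groups separates planted classes", {
  set.seed(14)
  cls <- rep(c("a", "b", "c"), each = 5)
  X <- matrix(rnorm(15 * 8, 0, 0.3), 15, 8)
  X[cls == "b", 1] <- X[cls == "b", 1] + 3
  X[cls == "c", 2] <- X[cls == "c", 2] + 3
  fit <- fit_plsda(scale(X), cls, n_components = 2)
  vip <- compute_vip(fit)
  expect_true(all(vip$vip[1:2] > 1))
  expect_setequal(order(vip$vip, decreasing = TRUE)[1:2], 1:2)
})
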