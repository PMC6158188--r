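# Expression filtering, profile standardization, fuzzy c-means,
# differential statistics, directional gene-set analysis, ORA and BH.

four_tp_matrix <- function(vals) {
  expression_matrix(vals, time_h = rep(c(16, 24, 42, 66), each = 2),
                    replicate = rep(1:2, 4),
                    phase = rep(c("aerobic", "limited", "limited", "limited"),
                                each = 2))
}

test_that("low-expression filter removes genes low at >= 2 time points", {
  vals <- rbind(
    ok1 = rep(50, 8),
    low2 = c(0, 0, 0.5, 0.5, 50, 50, 50, 50),     # low at 2 of 4 -> removed
    low1 = c(0.5, 0.5, rep(50, 6)),               # low at 1 of 4 -> kept
    ok2 = rep(2, 8))
  mat <- four_tp_matrix(vals)
  filt <- filter_low_expression(mat)
  expect_setequal(rownames(filt$values), c("ok1", "low1", "ok2"))
  expect_equal(attr(filt, "removed"), "low2")
  # all-above-threshold input passes unchanged
  mat2 <- four_tp_matrix(matrix(10, 4, 8, dimnames = list(paste0("g", 1:4), NULL)))
  expect_equal(filter_low_expression(mat2)$values, mat2$values)
  expect_error(filter_low_expression(mat, fpkm_threshold = -1), ">= 0")
})

test_that("a planted low block is exactly the removed set", {
  vals <- matrix(100, 10, 8, dimnames = list(sprintf("g%02d", 1:10), NULL))
  vals[c(2, 5, 9), c(1:2, 5:6)] <- 0.2           # low at 2 time points
  filt <- filter_low_expression(four_tp_matrix(vals))
  expect_equal(nrow(filt$values), 7L)
  expect_setequal(attr(filt, "removed"), sprintf("g%02d", c(2, 5, 9)))
})

test_that("standardized profiles are per-gene z-scores of time-point means", {
  vals <- rbind(g1 = c(1, 1, 2, 2, 4, 4, 8, 8), flat = rep(3, 8))
  mat <- four_tp_matrix(vals)
  expect_message(Z <- standardize_profiles(mat), "zero-variance")
  expect_equal(attr(Z, "dropped"), "flat")
  tp_means <- c(1, 2, 4, 8)
  expect_equal(unname(Z["g1", ]), (tp_means - mean(tp_means)) / sd(tp_means))
  expect_equal(unname(apply(Z, 1, sd)), rep(1, nrow(Z)))
})

test_that("fuzzy c-means invariants: memberships, monotone objective, limits", {
  set.seed(21)
  X <- rbind(matrix(rnorm(80, 3, 0.4), 20), matrix(rnorm(80, -3, 0.4), 20))
  f <- fuzzy_cmeans(X, k = 2, m = 2, seed = 4, n_init = 1)
  expect_equal(unname(rowSums(f$memberships)), rep(1, 40), tolerance = 1e-9)
  expect_true(all(diff(f$objective_trace) <= 1e-8))
  expect_true(f$converged)
  # two well-separated shapes: own-cluster membership > 0.95
  hard <- max.col(f$memberships)
  own <- f$memberships[cbind(seq_len(40), hard)]
  expect_true(all(own > 0.95))
  expect_equal(length(unique(hard[1:20])), 1L)    # blocks stay together
  expect_equal(length(unique(hard[21:40])), 1L)
  # a profile coinciding with a center gets membership ~1 there
  f3 <- fuzzy_cmeans(rbind(f$centers, X), k = 2, m = 2, seed = 4, n_init = 1)
  expect_true(all(apply(f3$memberships[1:2, ], 1, max) > 0.999))
  expect_error(fuzzy_cmeans(X, k = 100, m = 2), "exceeds")
  expect_error(fuzzy_cmeans(X, k = 2, m = 1), "m must be > 1")
})

test_that("four planted temporal patterns are recovered (seeds 1-5)", {
  skip_if_no("mclust")
  for (s in 1:5) {
    syn <- make_synthetic_expression(seed = s, n_low = 0)
    prof <- standardize_profiles(syn$matrix)
    fcm <- fuzzy_cmeans(prof, k = 4, m = estimate_fuzzifier(prof), seed = s)
    keep <- !is.na(fcm$assignment)
    ari <- mclust::adjustedRandIndex(fcm$assignment[keep],
                                     syn$truth$pattern[rownames(prof)][keep])
    expect_gte(ari, 0.9)
  }
})

test_that("fuzzy c-means matches an independent implementation", {
  skip_if_no("e1071")
  set.seed(22)
  X <- rbind(matrix(rnorm(60, 1.5), 15), matrix(rnorm(60, -1.5), 15))
  mine <- fuzzy_cmeans(X, k = 2, m = 2, seed = 5, n_init = 1, tol = 1e-10)
  ref <- e1071::cmeans(X, centers = mine$centers, m = 2, iter.max = 300)
  o1 <- order(mine$centers[, 1]); o2 <- order(ref$centers[, 1])
  expect_equal(unname(mine$centers[o1, ]), unname(ref$centers[o2, ]),
               tolerance = 1e-6)
  expect_equal(unname(mine$memberships[, o1]), unname(ref$membership[, o2]),
               tolerance = 1e-6)
})

test_that("fuzzifier heuristic evaluates its formula and behaves sanely", {
  N <- 5000; D <- 4
  direct <- 1 + (1418 / N + 22.05) / 16 +
    (12.33 / N + 0.243) * 4^(-0.0406 * log(N) - 0.1134)
  expect_equal(estimate_fuzzifier(matrix(0, N, D)), direct, tolerance = 1e-12)
  # m > 1 everywhere; decreasing in D at fixed N
  for (N in c(10, 200, 6662)) {
    ms <- sapply(3:12, function(D) estimate_fuzzifier(matrix(0, N, D)))
    expect_true(all(ms > 1))
    expect_true(all(diff(ms) < 0))
  }
  expect_error(estimate_fuzzifier(matrix(0, 1, 4)), "at least 2")
})

test_that("differential statistics: identity, exact fold change, Welch match", {
  vals <- matrix(c(3, 3, 3, 3, 15, 15, 15, 15), 1, 8,
                 dimnames = list("g1", NULL))
  mat <- four_tp_matrix(rbind(vals, same = rep(7, 8)))
  mat$samples$phase <- rep(c("A", "B"), each = 4)
  st <- differential_stats(mat, "A", "B")
  expect_equal(st$log2fc[st$gene == "g1"], 2)          # (15+1)/(3+1) = 4
  expect_equal(st$log2fc[st$gene == "same"], 0)
  expect_equal(st$p_value[st$gene == "same"], 1)
  # against stats::t.test on noisy data
  set.seed(23)
  noisy <- matrix(rlnorm(3 * 8, 3, 0.4), 3, 8,
                  dimnames = list(paste0("n", 1:3), NULL))
  mat2 <- four_tp_matrix(noisy)
  mat2$samples$phase <- rep(c("A", "B"), each = 4)
  st2 <- differential_stats(mat2, "A", "B")
  for (i in 1:3) {
    ref <- t.test(log2(noisy[i, 5:8] + 1), log2(noisy[i, 1:4] + 1))
    expect_equal(st2$t[i], unname(ref$statistic), tolerance = 1e-9)
    expect_equal(st2$p_value[i], ref$p.value, tolerance = 1e-9)
  }
  # single replicate: fold change only
  mat3 <- four_tp_matrix(noisy)
  mat3$samples$phase <- c("A", rep(NA, 6), "B")
  expect_warning(st3 <- differential_stats(mat3, "A", "B"), "single replicate")
  expect_true(all(is.na(st3$p_value)))
})

test_that("Welch p-values are near-uniform and not anti-conservative under the null", {
  # mildly conservative by the Satterthwaite approximation at this depth,
  # so the check is approximate uniformity plus type-I control
  ks <- fp <- numeric(10)
  for (s in 1:10) {
    set.seed(s)
    mu <- exp(rnorm(2000, 5, 0.5))
    X <- matrix(rep(mu, 8), ncol = 8) *
      exp(matrix(rnorm(2000 * 8, 0, 0.2), ncol = 8))
    mat <- expression_matrix(X, time_h = rep(c(16, 42), each = 4),
                             replicate = rep(1:4, 2),
                             phase = rep(c("A", "B"), each = 4))
    st <- differential_stats(mat, "A", "B")
    ks[s] <- suppressWarnings(ks.test(st$p_value, "punif")$statistic)
    fp[s] <- mean(st$p_value < 0.05)
  }
  expect_lt(max(ks), 0.05)
  expect_lt(max(fp), 0.05 + 2 * sqrt(0.05 * 0.95 / 2000))
})

## ---- gene-set analysis ---------------------------------------------------

test_that("an extreme all-up set reaches the smallest possible empirical p", {
  set.seed(31)
  t_all <- setNames(rnorm(500), paste0("g", 1:500))
  top <- names(sort(t_all, decreasing = TRUE))[1:20]
  res <- gene_set_analysis(t_all, list(top = top), n_perm = 999, seed = 2)
  expect_equal(res$p_dist_up, 1 / 1000)
  expect_equal(res$p_mix_up, 1 / 1000)
  expect_gt(res$p_dist_dn, 0.99)
})

test_that("all-zero statistics give p = 1 in every class", {
  t_all <- setNames(rep(0, 100), paste0("g", 1:100))
  res <- gene_set_analysis(t_all, list(s = paste0("g", 1:10)),
                           n_perm = 199, seed = 3)
  expect_equal(unlist(res[, c("p_dist_up", "p_dist_dn", "p_mix_up",
                              "p_mix_dn", "p_nondir")]),
               rep(1, 5), ignore_attr = TRUE)
})

test_that("half-up/half-down sets are mixed-significant, not distinct (10 seeds)", {
  for (s in 1:10) {
    set.seed(s)
    t_all <- setNames(rnorm(2000), paste0("g", 1:2000))
    idx <- sample(2000, 30)
    t_all[idx[1:15]] <- rnorm(15, 4, 0.5)
    t_all[idx[16:30]] <- rnorm(15, -4, 0.5)
    res <- gene_set_analysis(t_all, list(mix = names(t_all)[idx]),
                             n_perm = 999, seed = s + 100)
    expect_lt(res$p_mix_up, 0.01)
    expect_lt(res$p_mix_dn, 0.01)
    expect_gt(min(res$p_dist_up, res$p_dist_dn), 0.1)
  }
})

test_that("GSA handles empty and poorly covered sets with notices", {
  t_all <- setNames(rnorm(50), paste0("g", 1:50))
  expect_message(res <- gene_set_analysis(
    t_all, list(gone = c("x1", "x2"), ok = paste0("g", 1:10)),
    n_perm = 99, seed = 1), "skipping")
  expect_equal(res$set, "ok")
  expect_warning(gene_set_analysis(
    t_all, list(half = c(paste0("g", 1:5), paste0("y", 1:5))),
    n_perm = 99, seed = 1), "coverage")
})

test_that("GSA p-values are uniform under a null generator", {
  set.seed(41)
  t_all <- setNames(rnorm(2000), paste0("g", 1:2000))
  sets <- lapply(1:50, function(i) sample(names(t_all), 20))
  names(sets) <- paste0("s", 1:50)
  res <- gene_set_analysis(t_all, sets, n_perm = 499, seed = 6)
  crit_01 <- 1.628 / sqrt(50)
  for (cl in c("p_nondir", "p_dist_up", "p_mix_up"))
    expect_lt(suppressWarnings(ks.test(res[[cl]], "punif")$statistic), crit_01)
})

test_that("ORA equals exact hypergeometric tail sums", {
  universe <- paste0("g", 1:20)
  sets <- list(s5 = paste0("g", 1:5))
  selected <- paste0("g", c(1:4, 10))
  res <- ora_hypergeometric(selected, universe, sets)
  manual <- sum(dhyper(4:5, 5, 15, 5))
  expect_equal(res$p_value, manual, tolerance = 1e-12)
  # full-overlap closed form: p = 1 / C(N, n)
  res2 <- ora_hypergeometric(paste0("g", 1:5), universe, sets)
  expect_equal(res2$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  # zero overlap has tail probability 1 when achievable
  res3 <- ora_hypergeometric(paste0("g", 16:18), universe, sets)
  expect_equal(res3$overlap, 0)
  expect_equal(res3$p_value, 1)
  expect_error(ora_hypergeometric(c("g1", "zz"), universe, sets), "zz")
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.2, 4)), rep(0.2, 4))
  p <- c(0.01, 0.04, 0.03, 0.005)
  # ordered: .005, .01, .03, .04 -> step-up: .02, .02, .04, .04
  expect_equal(bh_adjust(p), c(0.02, 0.04, 0.04, 0.02))
  expect_true(all(bh_adjust(p) >= p))
})

test_that("cluster annotation cross-tabulates an external gene list", {
  syn <- make_synthetic_expression(seed = 2, n_low = 0)
  prof <- standardize_profiles(syn$matrix)
  fcm <- fuzzy_cmeans(prof, k = 4, m = 2, seed = 1)
  tf_list <- rownames(prof)[1:10]
  ann <- annotate_clusters(fcm, tf_list)
  expect_equal(sum(ann$n_in_list), sum(tf_list %in%
    names(fcm$assignment)[!is.na(fcm$assignment)]))
  expect_true(all(ann$n_in_list <= ann$n_genes))
})
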