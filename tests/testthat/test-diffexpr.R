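norm_from_matrix <- function(x) {
  # wrap an arbitrary positive matrix as a uq_norm object for screen tests
  structure(list(log2_values = log2(x + 1),
                 norm_factors = rep(1, ncol(x)),
                 conditional_uq = rep(1, ncol(x)),
                 filter_report = list()),
            class = "uq_norm")
}

test_that("Spearman correlation matches the midrank-Pearson oracle including ties", {
  x <- c(1.2, 3.4, 3.4, 0.5, 2.2, 9.1)
  y <- c(2.0, 1.0, 4.0, 4.0, 3.0, 5.0)
  expect_equal(spearman_cor(x, y)$rho, oracle_spearman(x, y), tolerance = 1e-12)
  set.seed(6)
  for (i in 1:20) {
    a <- sample(1:8, 10, replace = TRUE)   # many ties
    b <- rnorm(10)
    expect_equal(spearman_cor(a, b)$rho, oracle_spearman(a, b), tolerance = 1e-12)
    expect_equal(spearman_cor(a, b)$rho,
                 suppressWarnings(cor(a, b, method = "spearman")),
                 tolerance = 1e-12)
  }
})

test_that("monotone expression gives rho of exactly +/- 1", {
  expect_equal(spearman_cor(exp(1:6), 1:6)$rho, 1)
  expect_equal(spearman_cor(1:5, 5:1)$rho, -1)
  expect_equal(spearman_cor(1:5, 5:1)$p_value, 0)
})

test_that("oxygen correlation screen orients, ranks and thresholds correctly", {
  set.seed(8)
  auc <- runif(20, 0, 4)
  x <- rbind(
    up = 2^(auc + rnorm(20, 0, 1e-6)),     # strictly increasing in AUC
    down = 2^(4 - auc + rnorm(20, 0, 1e-6)),
    noise = 2^rnorm(20, 3, 1)
  )
  res <- correlate_oxygen(norm_from_matrix(x), auc)
  expect_equal(res$statistic[res$gene_id == "up"], 1)
  expect_equal(res$statistic[res$gene_id == "down"], -1)
  expect_equal(res$direction[res$gene_id == "up"], "up")
  expect_equal(res$direction[res$gene_id == "down"], "down")
  expect_true(all(res$significant[res$gene_id %in% c("up", "down")]))
  expect_error(correlate_oxygen(norm_from_matrix(x), rep(1, 20)), "constant")
})

test_that("BH q-values match the brute-force step-up oracle", {
  p <- c(0.01, 0.02, 0.03, 0.04, 0.2)
  expect_equal(bh_fdr(p), c(0.05, 0.05, 0.05, 0.05, 0.2))
  expect_equal(bh_fdr(p), oracle_bh(p))
  set.seed(9)
  for (i in 1:10) {
    pr <- runif(25)^2
    expect_equal(bh_fdr(pr), oracle_bh(pr), tolerance = 1e-12)
  }
  expect_equal(bh_fdr(rep(1, 4)), rep(1, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(numeric(0)), numeric(0))
})

test_that("adjusted LRT is zero for degenerate genes", {
  set.seed(11)
  n <- 40
  gab <- runif(n, 23, 32)
  y <- runif(n) < stats::plogis(0.5 * (27 - gab))
  if (length(unique(y)) < 2) y[1:2] <- c(TRUE, FALSE)
  # lin_gab is built so its log2 normalized value is exactly linear in GAB
  x <- rbind(const = rep(5, n), lin_gab = 2^(0.5 * gab) - 1,
             real = 2^rnorm(n, 4, 1))
  res <- lrt_adjusted(norm_from_matrix(x), y, gab)
  expect_equal(res$statistic[res$gene_id == "const"], 0, tolerance = 1e-8)
  expect_equal(res$p_value[res$gene_id == "const"], 1, tolerance = 1e-6)
  # a gene that is an exact linear function of GAB adds no information
  expect_lt(res$statistic[res$gene_id == "lin_gab"], 1e-4)
})

test_that("adjusted LRT matches an independent maximum-likelihood fit", {
  set.seed(12)
  n <- 40
  gab <- runif(n, 23, 32)
  g <- rnorm(n, 8, 2)
  y <- runif(n) < stats::plogis(-0.3 * (gab - 27) + 0.4 * (g - 8))
  if (length(unique(y)) < 2) y[1:2] <- c(TRUE, FALSE)
  x <- matrix(2^g - 1, 1, dimnames = list("g1", NULL))
  res <- lrt_adjusted(norm_from_matrix(x), y, gab)
  null_glm <- stats::glm(y ~ gab, family = binomial())
  full_glm <- stats::glm(y ~ gab + g, family = binomial())
  oracle_stat <- 2 * as.numeric(logLik(full_glm) - logLik(null_glm))
  expect_equal(res$statistic, oracle_stat, tolerance = 1e-6)
  expect_equal(res$p_value, pchisq(oracle_stat, 1, lower.tail = FALSE),
               tolerance = 1e-6)
})

test_that("LRT reduces to the unadjusted test when GAB is constant", {
  set.seed(13)
  n <- 30
  g <- rnorm(n)
  y <- rep(c(TRUE, FALSE), each = 15)
  x <- matrix(2^(g + 5), 1, dimnames = list("g1", NULL))
  res <- lrt_adjusted(norm_from_matrix(x), y, rep(28, n))
  null_glm <- stats::glm(y ~ 1, family = binomial())
  full_glm <- stats::glm(y ~ log2(2^(g + 5) + 1), family = binomial())
  oracle_stat <- 2 * as.numeric(logLik(full_glm) - logLik(null_glm))
  expect_equal(res$statistic, oracle_stat, tolerance = 1e-6)
})

test_that("separated genes are flagged and produce finite results", {
  n <- 20
  y <- rep(c(TRUE, FALSE), each = 10)
  x <- matrix(2^c(rep(10, 10), rep(2, 10)), 1, dimnames = list("sep", NULL))
  res <- lrt_adjusted(norm_from_matrix(x), y, runif(n, 23, 30))
  expect_true(res$separation)
  expect_true(is.finite(res$statistic))
  expect_lt(res$p_value, 0.01)
})

test_that("resampling count test calls nothing on a label-shuffled null", {
  set.seed(14)
  counts <- make_counts(matrix(rnbinom(300 * 24, mu = 50, size = 3), 300, 24))
  y <- sample(rep(c(TRUE, FALSE), each = 12))
  res <- samseq_test(counts, y, n_resamples = 5, n_perms = 200, seed = 1)
  expect_lte(sum(res$significant), 3)   # at most ~1% of 300 genes
})

test_that("depth resampling neutralizes a 5x depth difference between groups", {
  set.seed(15)
  base <- matrix(rnbinom(300 * 24, mu = 40, size = 3), 300, 24)
  y <- rep(c(TRUE, FALSE), each = 12)
  base[, y] <- matrix(rpois(300 * 12, base[, y] * 5), 300, 12)  # 5x deeper cases
  res <- samseq_test(make_counts(base), y, n_resamples = 10, n_perms = 200, seed = 2)
  expect_lte(sum(res$significant), 3)
})

test_that("a strongly induced gene is detected across seeds", {
  for (s in 1:3) {
    set.seed(100 + s)
    counts <- matrix(rnbinom(200 * 60, mu = 60, size = 3), 200, 60)
    y <- rep(c(TRUE, FALSE), each = 30)
    counts[1, y] <- rnbinom(30, mu = 60 * 4, size = 3)   # log2FC = 2
    res <- samseq_test(make_counts(counts), y, n_resamples = 10,
                       n_perms = 300, seed = s)
    expect_true(res$significant[res$gene_id == "g1"])
    expect_gt(res$log2_fold_change[res$gene_id == "g1"], 1)
    expect_equal(res$direction[res$gene_id == "g1"], "up")
  }
})

test_that("an all-equal gene has statistic zero and is never significant", {
  set.seed(16)
  counts <- matrix(rnbinom(50 * 20, mu = 30, size = 2), 50, 20)
  counts[7, ] <- 0
  y <- rep(c(TRUE, FALSE), each = 10)
  res <- samseq_test(make_counts(counts), y, n_resamples = 5, n_perms = 100, seed = 3)
  expect_equal(res$statistic[res$gene_id == "g7"], 0)
  expect_false(res$significant[res$gene_id == "g7"])
})

test_that("the resampling test is stable under global count scaling", {
  # scaling every count by a constant rescales the depths identically, so
  # after down-sampling to the common depth the statistic distribution is
  # unchanged up to Poisson resampling noise
  set.seed(17)
  counts <- matrix(rnbinom(100 * 20, mu = 30, size = 2), 100, 20)
  y <- rep(c(TRUE, FALSE), each = 10)
  r1 <- samseq_test(make_counts(counts), y, n_resamples = 5, n_perms = 100, seed = 4)
  r2 <- samseq_test(make_counts(counts * 3), y, n_resamples = 5, n_perms = 100, seed = 4)
  r2 <- r2[match(r1$gene_id, r2$gene_id), ]
  expect_gt(cor(r1$statistic, r2$statistic), 0.9)
  expect_equal(sum(r1$significant), sum(r2$significant))
})

test_that("the resampling test is invariant to subject relabeling", {
  set.seed(19)
  counts <- matrix(rnbinom(80 * 20, mu = 30, size = 2), 80, 20,
                   dimnames = list(sprintf("g%d", 1:80), sprintf("s%d", 1:20)))
  y <- rep(c(TRUE, FALSE), each = 10)
  perm <- sample(20)
  r1 <- samseq_test(count_matrix(counts), y, n_resamples = 5, n_perms = 100, seed = 6)
  r2 <- samseq_test(count_matrix(counts[, perm]), y[perm],
                    n_resamples = 5, n_perms = 100, seed = 6)
  r2 <- r2[match(r1$gene_id, r2$gene_id), ]
  # same subjects, same labels, different column order: statistics agree up
  # to resampling noise and the called set is identical in size
  expect_gt(cor(r1$statistic, r2$statistic), 0.9)
  expect_equal(sum(r1$significant), sum(r2$significant))
})

test_that("q-values are monotone consistent with the significance ordering", {
  set.seed(18)
  counts <- matrix(rnbinom(150 * 30, mu = 40, size = 3), 150, 30)
  y <- rep(c(TRUE, FALSE), each = 15)
  counts[1:10, y] <- matrix(rnbinom(10 * 15, mu = 120, size = 3), 10, 15)
  res <- samseq_test(make_counts(counts), y, n_resamples = 5, n_perms = 200, seed = 5)
  # res is sorted by q; |statistic| ordering and q ordering must agree in the
  # sense that q never decreases as |statistic| decreases
  ord <- order(abs(res$statistic), decreasing = TRUE)
  expect_true(all(diff(res$q_value[ord]) >= -1e-12))
})
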