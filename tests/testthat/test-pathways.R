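test_that("GMT parsing deduplicates members and validates structure", {
  f <- withr::local_tempfile()
  writeLines(c("P1\tdesc\tA\tB\tA", "P2\tother\tC"), f)
  sets <- read_gmt(f)
  expect_identical(sets[["P1"]], c("A", "B"))
  expect_identical(sets[["P2"]], "C")
  expect_identical(unname(attr(sets, "descriptions")), c("desc", "other"))
})

test_that("malformed GMT lines raise an error with the line number", {
  f <- withr::local_tempfile()
  writeLines(c("P1\tdesc\tA", "broken_line_without_tabs"), f)
  expect_error(read_gmt(f), "line 2")
})

test_that("an empty GMT file warns and yields an empty collection", {
  f <- withr::local_tempfile()
  writeLines(character(0), f)
  expect_warning(sets <- read_gmt(f), "empty")
  expect_equal(length(sets), 0)
})

test_that("write/read round trip is the identity on canonical form", {
  sets <- gene_sets(list(Alpha = c("g1", "g2", "g3"), Beta = c("g2", "g9")),
                    descriptions = c("first", "second"), source = "test")
  f <- withr::local_tempfile()
  write_gmt(sets, f)
  back <- read_gmt(f)
  expect_identical(unclass(back)[seq_along(back)], unclass(sets)[seq_along(sets)])
  expect_identical(unname(attr(back, "descriptions")),
                   unname(attr(sets, "descriptions")))
})

test_that("the shipped four-pathway PRD gene sets contain 28 distinct genes", {
  gmt <- system.file("extdata", "prd_pathways.gmt", package = "preemiexpr")
  sets <- read_gmt(gmt)
  expect_equal(length(sets), 4)
  expect_equal(sum(lengths(sets)), 29)       # one gene appears in two sets
  expect_equal(n_distinct_genes(sets), 28)
  shared <- intersect(sets[[1]], sets[[2]])
  expect_identical(shared, "SLCO1A2")
})

test_that("pathway scores: a singleton pathway is the standardized gene", {
  set.seed(50)
  x <- matrix(rnorm(60, 5), 3, 20,
              dimnames = list(c("a", "b", "c"), sprintf("s%d", 1:20)))
  sets <- gene_sets(list(solo = "a", pair = c("b", "c"), ghost = c("zz")))
  ps <- pathway_scores(x, sets)
  expect_equal(rownames(ps$scores), c("solo", "pair"))   # ghost dropped
  expect_equal(unname(ps$scores["solo", ]), as.numeric(scale(x["a", ])),
               tolerance = 1e-10)
  expect_equal(ps$dropped_genes, 1)
})

test_that("disjoint pathways are scored independently of each other and order", {
  set.seed(51)
  x <- matrix(rnorm(200), 10, 20,
              dimnames = list(sprintf("g%d", 1:10), sprintf("s%d", 1:20)))
  s1 <- gene_sets(list(A = c("g1", "g2"), B = c("g5", "g6", "g7")))
  s2 <- gene_sets(list(B = c("g5", "g6", "g7"), A = c("g1", "g2")))
  p1 <- pathway_scores(x, s1)
  p2 <- pathway_scores(x, s2)
  expect_equal(p1$scores["A", ], p2$scores["A", ])
  expect_equal(p1$scores["B", ], p2$scores["B", ])
})

test_that("pathway PC1 recovers the generating latent factor", {
  cf <- simulation_config(n_subjects = 500, n_genes = 60, n_pathways = 1,
                          genes_per_pathway = c(20, 20),
                          within_pathway_correlation = 0.8,
                          frac_signal_genes = 0, signal_log2fc = 0, seed = 52)
  co <- simulate_cohort(cf)
  norm <- uq_normalize(co$counts)
  ps <- pathway_scores(norm, co$gene_sets)
  # oracle: the mean standardized log2 expression of the block approximates
  # the latent factor; PC1 must align with it
  block <- norm$log2_values[co$gene_sets[[1]], ]
  latent_proxy <- colMeans(t(scale(t(block))))
  rho <- abs(cor(ps$scores[1, ], latent_proxy, method = "spearman"))
  expect_gte(rho, 0.9)
})

test_that("pathway screening handles constant and separating scores", {
  set.seed(53)
  n <- 30
  y <- rep(c(TRUE, FALSE), each = 15)
  scores <- rbind(const = rep(1, n),
                  sep = as.numeric(y),           # perfect separation
                  noise = rnorm(n))
  colnames(scores) <- sprintf("s%d", 1:n)
  scr <- screen_pathways(scores, y, alpha = 1.0001)
  allp <- attr(scr, "all_p")
  expect_equal(unname(allp["const"]), 1)
  expect_equal(scr$pathway[1], "sep")            # smallest p, ranked first
  expect_lt(allp["sep"], allp["noise"])
})

test_that("pathway LRT p-values match the glm oracle", {
  set.seed(54)
  n <- 50
  s <- rnorm(n)
  gab <- runif(n, 23, 35)
  y <- runif(n) < stats::plogis(0.8 * s - 0.2 * (gab - 29))
  if (length(unique(y)) < 2) y[1:2] <- c(TRUE, FALSE)
  scores <- matrix(s, 1, dimnames = list("pw", NULL))
  allp <- attr(screen_pathways(scores, y, gab_weeks = gab, alpha = 1.1), "all_p")
  null_glm <- stats::glm(y ~ gab, family = binomial())
  full_glm <- stats::glm(y ~ gab + s, family = binomial())
  oracle_p <- pchisq(2 * as.numeric(logLik(full_glm) - logLik(null_glm)), 1,
                     lower.tail = FALSE)
  expect_equal(unname(allp["pw"]), oracle_p, tolerance = 1e-6)
})

test_that("degenerate grids reduce to the top-screened pathway", {
  set.seed(55)
  n <- 60
  lat <- rnorm(n)
  y <- runif(n) < stats::plogis(1.5 * lat)
  x <- rbind(
    t(vapply(1:4, function(i) 5 + lat + rnorm(n, 0, 0.4), numeric(n))),
    matrix(rnorm(6 * n, 5), 6, n)
  )
  dimnames(x) <- list(sprintf("g%d", 1:10), sprintf("s%d", 1:n))
  sets <- gene_sets(list(signal = sprintf("g%d", 1:4),
                         null1 = sprintf("g%d", 5:7),
                         null2 = sprintf("g%d", 8:10)))
  m <- fit_pathway_classifier(x, sets, y, alpha_grid = 1.0001, k_grid = 1,
                              cv_folds = 3, seed = 1)
  scr <- screen_pathways(pathway_scores(x, sets)$scores, y, alpha = 1.0001)
  expect_equal(m$pathways, scr$pathway[1])
  expect_equal(m$k, 1)
})

test_that("a duplicated pathway is never selected after its twin", {
  set.seed(56)
  n <- 80
  lat <- rnorm(n)
  y <- runif(n) < stats::plogis(2 * lat)
  x <- rbind(
    t(vapply(1:3, function(i) lat + rnorm(n, 0, 0.2), numeric(n))),
    matrix(rnorm(3 * n), 3, n)
  )
  dimnames(x) <- list(sprintf("g%d", 1:6), sprintf("s%d", 1:n))
  sets <- gene_sets(list(sig = c("g1", "g2", "g3"),
                         twin = c("g1", "g2", "g3"),    # identical membership
                         null = c("g4", "g5", "g6")))
  ps <- pathway_scores(x, sets)
  fs <- preemiexpr:::forward_select(ps$scores, as.numeric(y), k_max = 3)
  first_two <- fs$order[1:2]
  expect_true(first_two[1] %in% c("sig", "twin"))
  expect_false(all(c("sig", "twin") %in% first_two))
  # the twin's incremental likelihood gain is essentially zero
  ll_gain <- diff(c(fs$loglik[1], fs$loglik[2]))
  expect_gt(fs$loglik[1], stats::logLik(stats::glm(y ~ 1, family = binomial()))[1])
})

test_that("in-sample log-likelihood is non-decreasing along the forward path", {
  set.seed(57)
  n <- 60
  scores <- matrix(rnorm(6 * n), 6, n,
                   dimnames = list(sprintf("pw%d", 1:6), sprintf("s%d", 1:n)))
  y <- rep(c(TRUE, FALSE), each = n / 2)
  fs <- preemiexpr:::forward_select(scores, as.numeric(y), k_max = 6)
  expect_true(all(diff(fs$loglik) >= -1e-8))
})

test_that("distinct-gene counting deduplicates across selected pathways", {
  set.seed(58)
  n <- 40
  x <- matrix(rnorm(8 * n, 5), 8, n,
              dimnames = list(sprintf("g%d", 1:8), sprintf("s%d", 1:n)))
  y <- rep(c(TRUE, FALSE), each = n / 2)
  x[1:5, y] <- x[1:5, y] + 2
  sets <- gene_sets(list(A = sprintf("g%d", 1:3), B = sprintf("g%d", 3:5)))
  m <- fit_pathway_classifier(x, sets, y, alpha_grid = 1.0001, k_grid = 2,
                              cv_folds = 3, seed = 2)
  expect_equal(length(m$pathways), 2)
  expect_equal(count_model_genes(m), 5)   # g3 shared, counted once
  # identical membership counts once per distinct gene
  sets2 <- gene_sets(list(A = sprintf("g%d", 1:5), B = sprintf("g%d", 1:5)))
  m2 <- fit_pathway_classifier(x, sets2, y, alpha_grid = 1.0001, k_grid = 2,
                               cv_folds = 3, seed = 3)
  expect_equal(count_model_genes(m2), 5)
})

test_that("LASSO pathway coefficients shrink to zero at strong penalties", {
  set.seed(59)
  n <- 80
  lat <- rnorm(n)
  y <- runif(n) < stats::plogis(1.5 * lat)
  x <- rbind(
    t(vapply(1:3, function(i) lat + rnorm(n, 0, 0.3), numeric(n))),
    matrix(rnorm(6 * n), 6, n)
  )
  dimnames(x) <- list(sprintf("g%d", 1:9), sprintf("s%d", 1:n))
  sets <- gene_sets(list(sig = sprintf("g%d", 1:3),
                         n1 = sprintf("g%d", 4:6), n2 = sprintf("g%d", 7:9)))
  ps <- pathway_scores(x, sets)
  lam <- c(10, 10^seq(-0.5, -3, length.out = 7))
  g <- glmnet::glmnet(t(ps$scores), factor(y), family = "binomial", lambda = lam)
  b <- as.matrix(g$beta)
  expect_true(all(b[, 1] == 0))            # infinite-penalty limit: intercept only
  expect_true(any(b[, ncol(b)] != 0))
  # coefficient magnitude of the signal pathway is monotone in the penalty
  sig_path <- abs(b["sig", ])
  expect_true(all(diff(sig_path) >= -1e-8))
})

test_that("the LASSO route of the classifier fits and predicts", {
  set.seed(60)
  n <- 100
  lat <- rnorm(n)
  y <- runif(n) < stats::plogis(2 * lat)
  x <- rbind(
    t(vapply(1:4, function(i) lat + rnorm(n, 0, 0.3), numeric(n))),
    matrix(rnorm(8 * n), 8, n)
  )
  dimnames(x) <- list(sprintf("g%d", 1:12), sprintf("s%d", 1:n))
  sets <- gene_sets(list(sig = sprintf("g%d", 1:4),
                         n1 = sprintf("g%d", 5:8), n2 = sprintf("g%d", 9:12)))
  m <- fit_pathway_classifier(x, sets, y, alpha_grid = c(0.1, 1.0001),
                              k_grid = 1:6, method = "lasso", cv_folds = 4,
                              seed = 4)
  expect_true("sig" %in% m$pathways)
  pr <- predict(m, x)
  expect_gt(auc_mw(pr, y), 0.8)
})

test_that("nested pathway evaluation beats the GAB baseline only with real signal", {
  # outcome depends only on GAB: the pathway model cannot beat the baseline
  set.seed(61)
  n <- 80
  gab <- runif(n, 23, 38)
  y <- runif(n) < stats::plogis(0.5 * (29 - gab))
  if (length(unique(y)) < 2) y[1:2] <- c(TRUE, FALSE)
  x <- matrix(rnorm(30 * n, 6), 30, n,
              dimnames = list(sprintf("g%d", 1:30), sprintf("s%d", 1:n)))
  sets <- gene_sets(split(sprintf("g%d", 1:30), rep(1:6, each = 5)))
  ev <- evaluate_nested_pathways(x, sets, y, gab_weeks = gab,
                                 alpha_grid = c(0.05, 0.1), k_grid = 1:2,
                                 outer_folds = 4, inner_folds = 4, seed = 5)
  expect_gt(ev$baseline_auc, 0.65)
  expect_lt(ev$cv_auc, ev$baseline_auc + 0.1)
  expect_equal(ev$cv_auc, oracle_auc(ev$cv_probs, ev$labels), tolerance = 1e-12)
})
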