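# Screened principal components (sPCA) BPD classifier: univariate Wilcoxon
# screen -> PC1 of the survivors (with near-zero loadings pruned) ->
# logistic model, with the screen threshold chosen by inner CV and honest
# performance from an outer nested-CV loop. All screening and PC fitting
# happen inside training folds; there is no API path that fits on full data
# before the outer split (a deliberately leaky variant exists only in the
# test suite to demonstrate AUC inflation).

#' Univariate Wilcoxon rank-sum screen
#'
#' Two-sided rank-sum p-value per gene. The exact distribution is used when
#' both groups are small and the gene has no ties; otherwise a normal
#' approximation with tie correction and continuity correction.
#'
#' @param x genes-x-subjects numeric matrix (or a `uq_norm` object).
#' @param outcome logical case labels (both classes non-empty).
#' @param alpha retain genes with p < alpha (default 0.10).
#' @param gab_weeks optional gestational age; when supplied, the screen is
#'   computed on rank-residualized expression (gene ranks with the linear
#'   effect of GAB ranks removed), a rank-based partial association.
#' @return data.frame (`gene_id`, `p_value`) of survivors in ascending-p
#'   order; attribute `"all_p"` holds every gene's p-value.
#' @export
wilcoxon_screen <- function(x, outcome, alpha = 0.10, gab_weeks = NULL) {
  if (inherits(x, "uq_norm")) x <- x$log2_values
  outcome <- as.logical(outcome)
  stopifnot(ncol(x) == length(outcome), any(outcome), any(!outcome))
  p <- wilcoxon_row_p(x, outcome, gab_weeks)
  keep <- which(p < alpha)
  keep <- keep[order(p[keep])]
  out <- data.frame(gene_id = rownames(x)[keep], p_value = p[keep],
                    stringsAsFactors = FALSE)
  attr(out, "all_p") <- stats::setNames(p, rownames(x))
  out
}

wilcoxon_row_p <- function(x, outcome, gab_weeks = NULL) {
  n <- ncol(x); n1 <- sum(outcome); n0 <- n - n1
  ranks <- row_ranks(x)
  if (!is.null(gab_weeks)) {
    # rank-based partial association: residualize gene ranks on GAB ranks,
    # then re-rank the residuals
    rg <- rank(gab_weeks)
    X <- cbind(1, rg)
    H <- X %*% solve(crossprod(X), t(X))
    ranks <- row_ranks(ranks - ranks %*% t(H))
  }
  W <- as.vector(ranks %*% outcome)
  ss <- rowSums(ranks^2) - n * ((n + 1) / 2)^2
  no_ties <- abs(ss - (n * (n + 1) * (2 * n + 1) / 6 - n * ((n + 1) / 2)^2)) < 1e-8
  U <- W - n1 * (n1 + 1) / 2
  p <- numeric(nrow(x))
  exact <- no_ties & (max(n1, n0) < 50)
  if (any(exact)) {
    u <- U[exact]
    lo <- pwilcox(u, n1, n0)
    hi <- pwilcox(u - 1, n1, n0, lower.tail = FALSE)
    p[exact] <- pmin(1, 2 * pmin(lo, hi))
  }
  if (any(!exact)) {
    v <- ss[!exact] * n1 * n0 / (n * (n - 1))
    mu <- n1 * (n + 1) / 2
    z <- (abs(W[!exact] - mu) - 0.5) / sqrt(pmax(v, 1e-300))
    z[v <= 0] <- 0
    pn <- 2 * pnorm(-pmax(z, 0))
    pn[v <= 0] <- 1
    p[!exact] <- pmin(1, pn)
  }
  p
}

#' First principal component of a gene submatrix, with loading pruning
#'
#' Genes are centered and (by default) scaled to unit variance; PC1 comes
#' from the SVD. Genes whose absolute loading falls below
#' `prune_frac * max(|loading|)` are dropped and PC1 is recomputed on the
#' survivors (one prune-and-refit pass). The sign convention fixes
#' `sum(loadings) > 0` (first nonzero loading positive on an exact tie).
#'
#' @param x genes-x-subjects numeric matrix (>= 1 non-constant gene).
#' @param prune_frac pruning threshold as a fraction of the maximum
#'   absolute loading (0 disables pruning; default 0.1).
#' @param scale. scale genes to unit variance before the SVD (default TRUE,
#'   i.e. a correlation-matrix PC1); FALSE gives the covariance-mode PC1.
#' @return object of class `pc1_fit`: `loadings` (named unit vector),
#'   `center`, `scale`, `genes`, `scores` (per training subject), and
#'   `var_explained`.
#' @export
pc1_fit <- function(x, prune_frac = 0.1, scale. = TRUE) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list("g1", names(x)))
  sds <- apply(x, 1L, sd)
  keep <- sds > 0
  if (!any(keep)) stop("all genes constant; PC1 undefined")
  x <- x[keep, , drop = FALSE]
  fit1 <- pc1_core(x, scale.)
  if (prune_frac > 0 && nrow(x) > 1) {
    thr <- prune_frac * max(abs(fit1$loadings))
    survivors <- abs(fit1$loadings) >= thr
    if (!all(survivors)) {
      x <- x[survivors, , drop = FALSE]
      fit1 <- pc1_core(x, scale.)
    }
  }
  fit1
}

pc1_core <- function(x, scale.) {
  ctr <- rowMeans(x)
  scl <- if (scale.) apply(x, 1L, sd) else rep(1, nrow(x))
  xs <- (x - ctr) / scl
  sv <- svd(t(xs), nu = 1, nv = 1)
  v <- sv$v[, 1]
  s <- sum(v)
  flip <- if (abs(s) > 1e-12) s < 0 else v[which(v != 0)[1]] < 0
  if (isTRUE(flip)) v <- -v
  scores <- drop(t(xs) %*% v)
  structure(list(
    loadings = stats::setNames(v, rownames(x)),
    center = stats::setNames(ctr, rownames(x)),
    scale = stats::setNames(scl, rownames(x)),
    genes = rownames(x),
    scores = stats::setNames(scores, colnames(x)),
    var_explained = sv$d[1]^2 / sum(apply(xs, 1, function(r) sum((r - mean(r))^2)))
  ), class = "pc1_fit")
}

#' Project new subjects onto a fitted PC1
#' @param fit a [pc1_fit()] object.
#' @param newx genes-x-subjects matrix containing the fitted genes.
#' @return numeric score per subject.
#' @export
project_pc1 <- function(fit, newx) {
  stopifnot(inherits(fit, "pc1_fit"))
  xs <- (newx[fit$genes, , drop = FALSE] - fit$center) / fit$scale
  drop(t(xs) %*% fit$loadings)
}

# One screen -> PC1 -> logistic pipeline fit on a training matrix, with
# prediction on a test matrix. Empty survivor sets fall back to an
# intercept-only model (predicting the training prevalence).
spca_pipeline <- function(x_tr, y_tr, x_te, gab_tr, gab_te, alpha, all_p,
                          include_gab, prune_frac) {
  genes <- names(all_p)[all_p < alpha]
  if (length(genes) == 0) {
    prev <- mean(y_tr)
    return(list(prob = rep(prev, ncol(x_te)), n_genes = 0, fit = NULL))
  }
  pc <- pc1_fit(x_tr[genes, , drop = FALSE], prune_frac = prune_frac)
  Xtr <- cbind(1, pc$scores, if (include_gab) gab_tr)
  lf <- logistic_fit(Xtr, as.numeric(y_tr))
  sc_te <- project_pc1(pc, x_te)
  Xte <- cbind(1, sc_te, if (include_gab) gab_te)
  list(prob = drop(1 / (1 + exp(-(Xte %*% lf$coef)))),
       n_genes = length(pc$genes), fit = list(pc = pc, coef = lf$coef))
}

#' Fit the screened-PC classifier with CV-chosen screening threshold
#'
#' For each candidate screening threshold, the screen -> PC1 -> logistic
#' pipeline is refit inside each inner training fold and evaluated on the
#' held-out fold; the threshold with the best inner-CV AUC (pooled
#' predictions per repeat, averaged over repeats) is selected, preferring
#' the smaller threshold on ties. The final model is refit on all supplied
#' data at the chosen threshold.
#'
#' @param norm a `uq_norm` object (or genes-x-subjects matrix).
#' @param outcome logical case labels.
#' @param gab_weeks gestational age vector (required when
#'   `include_gab = TRUE`).
#' @param alpha_grid candidate screening p-value cutoffs.
#' @param cv_folds,cv_repeats inner stratified CV shape (default 10 x 3).
#' @param include_gab adjust both the screen (rank-residualized) and the
#'   logistic model for gestational age.
#' @param prune_frac PC1 loading pruning fraction (default 0.1).
#' @param seed RNG seed controlling fold assignment.
#' @return object of class `spca_model`: chosen `alpha`, screened `genes`,
#'   `pc1` fit (loadings/center/scale), logistic `coef`, `inner_auc` table,
#'   and the fit context.
#' @export
fit_spca_classifier <- function(norm, outcome, gab_weeks = NULL,
                                alpha_grid = c(0.001, 0.005, 0.01, 0.05, 0.10),
                                cv_folds = 10, cv_repeats = 3,
                                include_gab = FALSE, prune_frac = 0.1,
                                seed = 1) {
  x <- if (inherits(norm, "uq_norm")) norm$log2_values else norm
  y <- as.logical(outcome)
  stopifnot(ncol(x) == length(y), length(alpha_grid) >= 1)
  if (include_gab) stopifnot(!is.null(gab_weeks))
  screen_gab <- if (include_gab) gab_weeks else NULL

  inner_auc <- with_seed(seed, {
    auc_rep <- matrix(NA_real_, cv_repeats, length(alpha_grid))
    for (r in seq_len(cv_repeats)) {
      folds <- stratified_folds(y, cv_folds)
      k <- attr(folds, "k")
      probs <- matrix(NA_real_, length(y), length(alpha_grid))
      for (f in seq_len(k)) {
        te <- folds == f
        p_tr <- wilcoxon_row_p(x[, !te, drop = FALSE], y[!te],
                               gab_weeks = if (include_gab) gab_weeks[!te])
        names(p_tr) <- rownames(x)
        for (a in seq_along(alpha_grid)) {
          pl <- spca_pipeline(x[, !te, drop = FALSE], y[!te],
                              x[, te, drop = FALSE],
                              gab_weeks[!te], gab_weeks[te],
                              alpha_grid[a], p_tr, include_gab, prune_frac)
          probs[te, a] <- pl$prob
        }
      }
      auc_rep[r, ] <- apply(probs, 2L, function(pr) auc_mw(pr, y))
    }
    colMeans(auc_rep)
  })

  best <- which(inner_auc >= max(inner_auc) - 1e-12)
  alpha <- alpha_grid[min(best)]   # tie -> smaller (more stringent) threshold

  scr <- wilcoxon_screen(x, y, alpha = alpha, gab_weeks = screen_gab)
  if (nrow(scr) == 0) stop("no genes survive the chosen screening threshold")
  pc <- pc1_fit(x[scr$gene_id, , drop = FALSE], prune_frac = prune_frac)
  Xf <- cbind(1, pc$scores, if (include_gab) gab_weeks)
  lf <- logistic_fit(Xf, as.numeric(y))
  structure(list(
    alpha = alpha, inner_auc = stats::setNames(inner_auc, alpha_grid),
    screen = scr, genes = pc$genes, pc1 = pc, coef = lf$coef,
    include_gab = include_gab, prune_frac = prune_frac, seed = seed
  ), class = "spca_model")
}

#' @export
print.spca_model <- function(x, ...) {
  cat(sprintf("spca_model: alpha=%g, %d genes in PC1, include_gab=%s\n",
              x$alpha, length(x$genes), x$include_gab))
  invisible(x)
}

#' Predicted case probabilities from an sPCA model
#' @param object an `spca_model`.
#' @param newx genes-x-subjects matrix (or `uq_norm`).
#' @param gab_weeks gestational age for the new subjects (if the model uses it).
#' @param ... unused.
#' @return numeric probabilities.
#' @export
predict.spca_model <- function(object, newx, gab_weeks = NULL, ...) {
  if (inherits(newx, "uq_norm")) newx <- newx$log2_values
  sc <- project_pc1(object$pc1, newx)
  X <- cbind(1, sc, if (object$include_gab) gab_weeks)
  drop(1 / (1 + exp(-(X %*% object$coef))))
}

#' Nested cross-validated evaluation of the sPCA classifier
#'
#' Outer stratified CV; within each outer training set the entire procedure
#' — screening-threshold selection by inner CV included — is rerun, and
#' held-out predicted probabilities are pooled into a single ROC curve. The
#' naive AUC comes from the in-sample predictions of the full-data refit.
#'
#' @inheritParams fit_spca_classifier
#' @param outer_folds outer CV folds (default 10).
#' @param inner_folds,inner_repeats inner CV shape passed to the fit.
#' @return object of class `roc_result`: `roc` (held-out ROC points),
#'   `naive_roc`, `cv_auc`, `naive_auc`, `cv_probs`, fold assignments, seed,
#'   and the full-data `model`.
#' @export
evaluate_nested <- function(norm, outcome, gab_weeks = NULL,
                            alpha_grid = c(0.001, 0.005, 0.01, 0.05, 0.10),
                            outer_folds = 10, inner_folds = 10,
                            inner_repeats = 3, include_gab = FALSE,
                            prune_frac = 0.1, seed = 1) {
  x <- if (inherits(norm, "uq_norm")) norm$log2_values else norm
  y <- as.logical(outcome)
  folds <- with_seed(seed, stratified_folds(y, outer_folds))
  k <- attr(folds, "k")
  probs <- rep(NA_real_, length(y))
  for (f in seq_len(k)) {
    te <- folds == f
    m <- fit_spca_classifier(x[, !te, drop = FALSE], y[!te],
                             gab_weeks = gab_weeks[!te],
                             alpha_grid = alpha_grid, cv_folds = inner_folds,
                             cv_repeats = inner_repeats,
                             include_gab = include_gab,
                             prune_frac = prune_frac,
                             seed = derive_seed(seed, f))
    probs[te] <- predict(m, x[, te, drop = FALSE], gab_weeks = gab_weeks[te])
  }
  model <- fit_spca_classifier(x, y, gab_weeks = gab_weeks,
                               alpha_grid = alpha_grid, cv_folds = inner_folds,
                               cv_repeats = inner_repeats,
                               include_gab = include_gab,
                               prune_frac = prune_frac, seed = seed)
  naive_probs <- predict(model, x, gab_weeks = gab_weeks)
  roc_result(cv_probs = probs, naive_probs = naive_probs, labels = y,
             folds = folds, seed = seed, model = model)
}

# Shared ROC result constructor for both classifiers.
roc_result <- function(cv_probs, naive_probs, labels, folds, seed, model,
                       baseline_probs = NULL) {
  out <- list(
    roc = roc_curve(cv_probs, labels),
    naive_roc = roc_curve(naive_probs, labels),
    cv_auc = auc_mw(cv_probs, labels),
    naive_auc = auc_mw(naive_probs, labels),
    cv_probs = cv_probs, naive_probs = naive_probs, labels = labels,
    folds = folds, seed = seed, model = model
  )
  if (!is.null(baseline_probs)) {
    out$baseline_roc <- roc_curve(baseline_probs, labels)
    out$baseline_auc <- auc_mw(baseline_probs, labels)
  }
  structure(out, class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: naive AUC = %.3f, CV-AUC = %.3f%s\n",
              x$naive_auc, x$cv_auc,
              if (!is.null(x$baseline_auc))
                sprintf(", baseline AUC = %.3f", x$baseline_auc) else ""))
  invisible(x)
}
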