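# Canonical-pathway PRD classifier: each curated gene set is reduced to the
# PC1 of its member genes (a pathway eigengene); a univariate logistic LRT
# screens pathways; bivariate CV jointly selects the screening threshold
# and the number of forward-selection steps (or the LASSO penalty); an
# outer nested-CV loop gives honest ROC/AUC, with a gestational-age-only
# baseline for comparison. Pathway PC1s are computed inside training folds
# by default (leakage-safe); a global-PC mode exists for sensitivity
# analysis.

#' Pathway eigengene scores (PC1 per gene set)
#'
#' For each pathway, the PC1 of its matrix-resident member genes (no
#' loading pruning). Pathways with no resident genes are dropped, and the
#' count of non-resident genes is recorded; genes belonging to no pathway
#' simply never contribute.
#'
#' @param norm a `uq_norm` object or genes-x-subjects matrix.
#' @param sets a [gene_sets()] collection.
#' @param scale. passed to [pc1_fit()].
#' @return object of class `pathway_scores`: `scores`
#'   (pathways x subjects), `fits` (per-pathway [pc1_fit()]), and
#'   `dropped_genes` (count of member genes absent from the matrix).
#' @export
pathway_scores <- function(norm, sets, scale. = TRUE) {
  x <- if (inherits(norm, "uq_norm")) norm$log2_values else norm
  stopifnot(inherits(sets, "gene_sets"))
  resident <- lapply(sets, function(g) intersect(g, rownames(x)))
  dropped <- sum(lengths(sets)) - sum(lengths(resident))
  keep <- lengths(resident) > 0
  resident <- resident[keep]
  fits <- lapply(resident, function(g) {
    tryCatch(pc1_fit(x[g, , drop = FALSE], prune_frac = 0, scale. = scale.),
             error = function(e) NULL)   # all-constant sets are dropped
  })
  ok <- !vapply(fits, is.null, logical(1))
  fits <- fits[ok]
  if (length(fits) == 0) stop("no pathway has usable resident genes")
  scores <- do.call(rbind, lapply(fits, function(f) f$scores[colnames(x)]))
  dimnames(scores) <- list(names(fits), colnames(x))
  structure(list(scores = scores, fits = fits, dropped_genes = dropped),
            class = "pathway_scores")
}

# Project new subjects through fitted pathway PC1s.
project_pathway_scores <- function(ps, newx) {
  stopifnot(inherits(ps, "pathway_scores"))
  out <- do.call(rbind, lapply(ps$fits, function(f) project_pc1(f, newx)))
  dimnames(out) <- list(names(ps$fits), colnames(newx))
  out
}

#' Univariate logistic LRT screen of pathway scores
#'
#' Per pathway, a likelihood-ratio test of the logistic model with the
#' pathway score against the null (optionally gestational-age-adjusted)
#' model. Survivors at p < alpha are returned in ascending-p order.
#'
#' @param scores pathways-x-subjects score matrix (or `pathway_scores`).
#' @param outcome logical case labels.
#' @param gab_weeks optional adjustment covariate.
#' @param alpha screening threshold.
#' @return data.frame (`pathway`, `p_value`) of survivors, ascending p;
#'   attribute `"all_p"` holds every pathway's p-value.
#' @export
screen_pathways <- function(scores, outcome, gab_weeks = NULL, alpha = 0.10) {
  if (inherits(scores, "pathway_scores")) scores <- scores$scores
  y <- as.numeric(as.logical(outcome))
  stopifnot(ncol(scores) == length(y), length(unique(y)) == 2)
  covar <- gab_weeks
  null_fit <- logistic_fit(cbind(rep(1, length(y)), covar), y)
  p <- vapply(seq_len(nrow(scores)), function(i) {
    s <- scores[i, ]
    if (sd(s) == 0) return(1)
    lrt_logistic(y, s, covar = covar, null_fit = null_fit)$p_value
  }, numeric(1))
  names(p) <- rownames(scores)
  keep <- which(p < alpha)
  keep <- keep[order(p[keep])]
  out <- data.frame(pathway = rownames(scores)[keep], p_value = p[keep],
                    stringsAsFactors = FALSE)
  attr(out, "all_p") <- p
  out
}

# Greedy logistic forward selection over pathway scores. Returns the
# selection order (up to k_max) with per-step log-likelihoods.
forward_select <- function(scores, y, covar = NULL, k_max) {
  cand <- rownames(scores)
  sel <- character(0)
  lls <- numeric(0)
  base <- cbind(rep(1, length(y)), covar)
  while (length(sel) < min(k_max, nrow(scores))) {
    rest <- setdiff(cand, sel)
    if (length(rest) == 0) break
    ll <- vapply(rest, function(pw) {
      X <- cbind(base, t(scores[c(sel, pw), , drop = FALSE]))
      logistic_fit(X, y)$loglik
    }, numeric(1))
    best <- rest[which.max(ll)]
    sel <- c(sel, best)
    lls <- c(lls, max(ll))
  }
  list(order = sel, loglik = lls)
}

fit_logistic_on <- function(scores, sel, y, covar = NULL) {
  X <- cbind(1, covar, t(scores[sel, , drop = FALSE]))
  logistic_fit(X, y)
}

predict_logistic_on <- function(coef, scores_te, sel, covar_te = NULL) {
  X <- cbind(1, covar_te, t(scores_te[sel, , drop = FALSE]))
  drop(1 / (1 + exp(-(X %*% coef))))
}

#' Fit the pathway classifier with bivariate CV
#'
#' Inner CV over the grid of (screening threshold alpha) x (model size k —
#' forward-selection step count, or index into the LASSO penalty sequence).
#' Within each inner training fold, pathway PC1s are recomputed (unless
#' `pc_mode = "global"`), pathways are screened, and the selection path is
#' fit; held-out predictions pooled per grid cell give the inner-CV AUC.
#' The best cell is chosen by AUC, preferring fewer pathways and then the
#' larger (more stringent grid position) alpha on ties. The final model is
#' refit on all data at the chosen cell.
#'
#' @param norm a `uq_norm` object or genes-x-subjects matrix.
#' @param sets a [gene_sets()] collection.
#' @param outcome logical case labels.
#' @param gab_weeks optional adjustment covariate (the PRD recipe default
#'   is unadjusted).
#' @param alpha_grid candidate screening thresholds.
#' @param k_grid candidate model sizes (forward steps or LASSO penalty
#'   indices).
#' @param method `"forward"` or `"lasso"`.
#' @param cv_folds,cv_repeats inner CV shape.
#' @param include_gab adjust screen and model for gestational age.
#' @param pc_mode `"fold"` (PC1s computed within training folds;
#'   leakage-safe default) or `"global"`.
#' @param lasso_lambda LASSO penalty sequence (log-scale grid), indexed by
#'   `k_grid`.
#' @param seed RNG seed.
#' @return object of class `pathway_model`: selected `pathways` in order,
#'   per-pathway `loadings`, logistic `coef` (pathway log odds ratios),
#'   `gene_or` (per-gene univariate odds ratios on standardized
#'   expression), chosen `alpha`/`k`, inner-AUC grid, and fit context.
#' @export
fit_pathway_classifier <- function(norm, sets, outcome, gab_weeks = NULL,
                                   alpha_grid = c(0.01, 0.05, 0.10),
                                   k_grid = 1:5, method = c("forward", "lasso"),
                                   cv_folds = 10, cv_repeats = 1,
                                   include_gab = FALSE, pc_mode = c("fold", "global"),
                                   lasso_lambda = 10^seq(-0.5, -3, length.out = 8),
                                   seed = 1) {
  method <- match.arg(method)
  pc_mode <- match.arg(pc_mode)
  x <- if (inherits(norm, "uq_norm")) norm$log2_values else norm
  y <- as.logical(outcome)
  stopifnot(ncol(x) == length(y), length(alpha_grid) >= 1, length(k_grid) >= 1)
  covar_all <- if (include_gab) gab_weeks else NULL
  if (include_gab) stopifnot(!is.null(gab_weeks))

  global_ps <- pathway_scores(x, sets)

  grid_auc <- with_seed(seed, {
    acc <- array(0, c(cv_repeats, length(alpha_grid), length(k_grid)))
    for (r in seq_len(cv_repeats)) {
      folds <- stratified_folds(y, cv_folds)
      k_eff <- attr(folds, "k")
      probs <- array(NA_real_, c(length(y), length(alpha_grid), length(k_grid)))
      for (f in seq_len(k_eff)) {
        te <- folds == f
        ps_tr <- if (pc_mode == "fold") pathway_scores(x[, !te, drop = FALSE], sets) else global_ps
        s_tr <- if (pc_mode == "fold") ps_tr$scores else global_ps$scores[, !te, drop = FALSE]
        s_te <- if (pc_mode == "fold") project_pathway_scores(ps_tr, x[, te, drop = FALSE])
                else global_ps$scores[, te, drop = FALSE]
        cv_tr <- covar_all[!te]; cv_te <- covar_all[te]
        scr <- screen_pathways(s_tr, y[!te], gab_weeks = cv_tr, alpha = max(alpha_grid))
        all_p <- attr(scr, "all_p")
        for (a in seq_along(alpha_grid)) {
          surv <- names(all_p)[all_p < alpha_grid[a]]
          if (length(surv) == 0) {
            probs[te, a, ] <- mean(y[!te]); next
          }
          if (method == "forward") {
            fs <- forward_select(s_tr[surv, , drop = FALSE], as.numeric(y[!te]),
                                 covar = cv_tr, k_max = max(k_grid))
            for (ki in seq_along(k_grid)) {
              sel <- head(fs$order, k_grid[ki])
              if (length(sel) == 0) { probs[te, a, ki] <- mean(y[!te]); next }
              lf <- fit_logistic_on(s_tr, sel, as.numeric(y[!te]), cv_tr)
              probs[te, a, ki] <- predict_logistic_on(lf$coef, s_te, sel, cv_te)
            }
          } else if (length(surv) < 2) {
            # glmnet needs >= 2 predictors; a single survivor is just the
            # unpenalized single-pathway logistic model
            lf <- fit_logistic_on(s_tr, surv, as.numeric(y[!te]), cv_tr)
            probs[te, a, ] <- predict_logistic_on(lf$coef, s_te, surv, cv_te)
          } else {
            gfit <- glmnet::glmnet(t(s_tr[surv, , drop = FALSE]),
                                   factor(y[!te]), family = "binomial",
                                   lambda = lasso_lambda)
            pr <- stats::predict(gfit, t(s_te[surv, , drop = FALSE]),
                                 s = lasso_lambda[k_grid], type = "response")
            probs[te, a, ] <- pr
          }
        }
      }
      for (a in seq_along(alpha_grid)) for (ki in seq_along(k_grid)) {
        acc[r, a, ki] <- auc_mw(probs[, a, ki], y)
      }
    }
    apply(acc, c(2, 3), mean)
  })

  # tie-break: best AUC, then fewer pathways (smaller k), then larger alpha
  best_val <- max(grid_auc)
  cells <- which(grid_auc >= best_val - 1e-12, arr.ind = TRUE)
  cells <- cells[order(cells[, 2], -cells[, 1]), , drop = FALSE]
  a_star <- alpha_grid[cells[1, 1]]
  k_star <- k_grid[cells[1, 2]]

  scr <- screen_pathways(global_ps$scores, y, gab_weeks = covar_all, alpha = a_star)
  if (nrow(scr) == 0) stop("no pathway survives the chosen screening threshold")
  yv <- as.numeric(y)
  if (method == "forward" || nrow(scr) < 2) {
    fs <- forward_select(global_ps$scores[scr$pathway, , drop = FALSE], yv,
                         covar = covar_all, k_max = k_star)
    sel <- fs$order
    lf <- fit_logistic_on(global_ps$scores, sel, yv, covar_all)
    coefs <- lf$coef
  } else {
    gfit <- glmnet::glmnet(t(global_ps$scores[scr$pathway, , drop = FALSE]),
                           factor(y), family = "binomial", lambda = lasso_lambda)
    bm <- stats::coef(gfit, s = lasso_lambda[k_star])
    b <- stats::setNames(as.numeric(bm), rownames(bm))
    nz <- names(b)[-1][b[-1] != 0]
    sel <- nz
    coefs <- c(b[1], b[nz])
  }

  member_genes <- lapply(global_ps$fits[sel], function(f) f$genes)
  gene_ids <- unique(unlist(member_genes, use.names = FALSE))
  gene_or <- vapply(gene_ids, function(g) {
    gx <- scale(x[g, ])[, 1]
    exp(logistic_fit(cbind(1, gx), yv)$coef[2])
  }, numeric(1))

  structure(list(
    pathways = sel,
    coef = coefs,
    loadings = lapply(global_ps$fits[sel], function(f) f$loadings),
    member_genes = member_genes,
    gene_or = gene_or,
    alpha = a_star, k = k_star, method = method,
    include_gab = include_gab, pc_mode = pc_mode,
    inner_auc = grid_auc, alpha_grid = alpha_grid, k_grid = k_grid,
    lasso_lambda = if (method == "lasso") lasso_lambda else NULL,
    fits = global_ps$fits[sel], seed = seed
  ), class = "pathway_model")
}

#' @export
print.pathway_model <- function(x, ...) {
  cat(sprintf("pathway_model (%s): %d pathways, %d distinct genes, alpha=%g, k=%s\n",
              x$method, length(x$pathways), count_model_genes(x), x$alpha,
              as.character(x$k)))
  invisible(x)
}

#' Count distinct genes across a model's selected pathways
#'
#' A gene belonging to several selected pathways is counted once.
#'
#' @param model a `pathway_model`.
#' @return integer count of distinct member genes (0 for an empty model).
#' @export
count_model_genes <- function(model) {
  stopifnot(inherits(model, "pathway_model"))
  length(unique(unlist(model$member_genes, use.names = FALSE)))
}

#' Predicted case probabilities from a pathway model
#' @param object a `pathway_model`.
#' @param newx genes-x-subjects matrix (or `uq_norm`).
#' @param gab_weeks gestational age if the model adjusts for it.
#' @param ... unused.
#' @return numeric probabilities.
#' @export
predict.pathway_model <- function(object, newx, gab_weeks = NULL, ...) {
  if (inherits(newx, "uq_norm")) newx <- newx$log2_values
  s <- do.call(rbind, lapply(object$fits, function(f) project_pc1(f, newx)))
  rownames(s) <- object$pathways
  covar <- if (object$include_gab) gab_weeks else NULL
  predict_logistic_on(object$coef, s, object$pathways, covar)
}

#' Nested cross-validated evaluation of the pathway classifier
#'
#' As [evaluate_nested()] but with the whole bivariate (alpha, k) selection
#' — and, in `"fold"` PC mode, the pathway PC1s — recomputed inside every
#' outer training fold. Also returns a gestational-age-only logistic
#' baseline ROC fit per outer fold.
#'
#' @inheritParams fit_pathway_classifier
#' @param outer_folds outer CV folds.
#' @param inner_folds,inner_repeats inner CV shape passed to the fit.
#' @return a `roc_result` with `baseline_auc`/`baseline_roc` (GAB-only).
#' @export
evaluate_nested_pathways <- function(norm, sets, outcome, gab_weeks = NULL,
                                     alpha_grid = c(0.01, 0.05, 0.10),
                                     k_grid = 1:5, method = "forward",
                                     outer_folds = 10, inner_folds = 10,
                                     inner_repeats = 1, include_gab = FALSE,
                                     pc_mode = "fold", seed = 1) {
  x <- if (inherits(norm, "uq_norm")) norm$log2_values else norm
  y <- as.logical(outcome)
  folds <- with_seed(seed, stratified_folds(y, outer_folds))
  k_eff <- attr(folds, "k")
  probs <- rep(NA_real_, length(y))
  base_probs <- rep(NA_real_, length(y))
  for (f in seq_len(k_eff)) {
    te <- folds == f
    m <- tryCatch(
      fit_pathway_classifier(x[, !te, drop = FALSE], sets, y[!te],
                             gab_weeks = gab_weeks[!te],
                             alpha_grid = alpha_grid, k_grid = k_grid,
                             method = method, cv_folds = inner_folds,
                             cv_repeats = inner_repeats,
                             include_gab = include_gab, pc_mode = pc_mode,
                             seed = derive_seed(seed, f)),
      error = function(e) {
        if (grepl("no pathway survives", conditionMessage(e))) NULL else stop(e)
      })
    # a training fold with no surviving pathway has no model: the honest
    # held-out prediction is the training prevalence
    probs[te] <- if (is.null(m)) mean(y[!te]) else
      predict(m, x[, te, drop = FALSE], gab_weeks = gab_weeks[te])
    if (!is.null(gab_weeks)) {
      bl <- logistic_fit(cbind(1, gab_weeks[!te]), as.numeric(y[!te]))
      base_probs[te] <- drop(1 / (1 + exp(-(cbind(1, gab_weeks[te]) %*% bl$coef))))
    }
  }
  model <- fit_pathway_classifier(x, sets, y, gab_weeks = gab_weeks,
                                  alpha_grid = alpha_grid, k_grid = k_grid,
                                  method = method, cv_folds = inner_folds,
                                  cv_repeats = inner_repeats,
                                  include_gab = include_gab, pc_mode = pc_mode,
                                  seed = seed)
  naive_probs <- predict(model, x, gab_weeks = gab_weeks)
  roc_result(cv_probs = probs, naive_probs = naive_probs, labels = y,
             folds = folds, seed = seed, model = model,
             baseline_probs = if (!is.null(gab_weeks)) base_probs)
}

#' Write a pathway model as a coefficient/gene table (TSV)
#'
#' One row per (pathway, member gene): pathway log odds ratio from the
#' joint logistic fit, and the per-gene univariate odds ratio on
#' standardized log2 expression. The per-gene odds ratio is a descriptive
#' annotation, not a coefficient of the fitted model.
#'
#' @param model a `pathway_model`.
#' @param path output TSV.
#' @export
write_pathway_table <- function(model, path) {
  stopifnot(inherits(model, "pathway_model"))
  n_cov <- length(model$coef) - length(model$pathways)
  logor <- model$coef[seq_along(model$pathways) + n_cov]
  rows <- do.call(rbind, lapply(seq_along(model$pathways), function(i) {
    genes <- model$member_genes[[i]]
    data.frame(pathway = model$pathways[i],
               pathway_logOR = unname(round(logor[i], 4)),
               gene = genes,
               gene_OR = unname(round(model$gene_or[genes], 4)),
               stringsAsFactors = FALSE)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
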