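#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif rbinom rpois rnbinom rlnorm quantile median
#'   pchisq pnorm pwilcox p.adjust binomial glm.fit uniroot sd var complete.cases
#' @importFrom utils read.delim write.table head tail packageVersion
NULL

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so package functions never perturb the user's stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic child seed derivation; stays below .Machine$integer.max.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 7919) %% 2147483629)
}

#' Stratified cross-validation fold assignment
#'
#' Assigns fold labels 1..k such that both outcome classes are spread as
#' evenly as possible across folds. If a class has fewer members than `k`,
#' the number of folds is reduced (with a warning) so every fold contains
#' both classes.
#'
#' @param y logical or 0/1 outcome vector.
#' @param k requested number of folds.
#' @return integer vector of fold assignments (attribute `"k"` gives the
#'   number of folds actually used). Uses the current RNG stream.
#' @export
stratified_folds <- function(y, k = 10) {
  y <- as.logical(y)
  stopifnot(!anyNA(y))
  n1 <- sum(y); n0 <- sum(!y)
  if (min(n1, n0) < 1) stop("both outcome classes must be non-empty")
  k_eff <- min(k, n1, n0)
  if (k_eff < k) {
    warning(sprintf("reducing folds from %d to %d so each fold has both classes", k, k_eff))
  }
  folds <- integer(length(y))
  folds[y]  <- sample(rep_len(seq_len(k_eff), n1))
  folds[!y] <- sample(rep_len(seq_len(k_eff), n0))
  attr(folds, "k") <- k_eff
  folds
}

# Midranks of each row of a matrix.
row_ranks <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  t(apply(x, 1L, rank))
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Midrank-based Spearman correlation (rank, then Pearson). The p-value uses
#' the usual t approximation with n - 2 degrees of freedom, two-sided.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return list with elements `rho` and `p_value`.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) stop("Spearman correlation undefined for constant input")
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) / sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  n <- length(x)
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p_value = p)
}

# Row-wise Spearman correlation of a matrix against a vector.
row_spearman <- function(x, y) {
  ry <- rank(y)
  if (sd(ry) == 0) stop("Spearman correlation undefined: reference vector is constant")
  rx <- row_ranks(x)
  ryc <- ry - mean(ry)
  rxc <- rx - rowMeans(rx)
  num <- as.vector(rxc %*% ryc)
  den <- sqrt(rowSums(rxc^2) * sum(ryc^2))
  rho <- ifelse(den > 0, num / den, NA_real_)
  n <- length(y)
  tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-300))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[abs(rho) >= 1] <- 0
  list(rho = rho, p_value = pmin(p, 1))
}

#' Area under the ROC curve as the tie-corrected Mann-Whitney statistic
#'
#' AUC is computed as the proportion of (case, control) pairs where the case
#' score exceeds the control score, with ties given half credit — i.e.
#' U / (n1 * n0) with the midrank form of U.
#'
#' @param scores numeric predictions (higher = more case-like).
#' @param labels logical or 0/1 outcome.
#' @return AUC in \[0, 1\].
#' @export
auc_mw <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("AUC requires both classes")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC points (sensitivity/specificity over all score thresholds)
#'
#' @inheritParams auc_mw
#' @return data.frame with columns `threshold`, `sensitivity`, `specificity`;
#'   attribute `"auc"` holds the trapezoidal area, which equals [auc_mw()].
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  uniq <- !duplicated(s)
  tp <- cumsum(l); fp <- cumsum(!l)
  idx <- c(which(uniq)[-1] - 1L, length(s))
  sens <- c(0, tp[idx] / n1)
  fpr <- c(0, fp[idx] / n0)
  df <- data.frame(
    threshold = c(Inf, s[idx]),
    sensitivity = sens,
    specificity = 1 - fpr
  )
  auc <- sum(diff(fpr) * (head(sens, -1) + tail(sens, -1)) / 2)
  attr(df, "auc") <- auc
  df
}

# ---- logistic regression helpers -------------------------------------------

# IRLS logistic fit with optional ridge penalty on non-intercept terms.
# X: model matrix including intercept column. Returns coefficients,
# log-likelihood (unpenalized, at the fitted coefficients) and a separation
# flag.
logistic_irls <- function(X, y, lambda = 0, max_iter = 50, tol = 1e-10) {
  p <- ncol(X)
  beta <- numeric(p)
  pen <- diag(c(0, rep(lambda, p - 1L)), p, p)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta_new <- tryCatch(
      solve(XtW %*% X + pen, XtW %*% z),
      error = function(e) NULL
    )
    if (is.null(beta_new)) break
    beta_new <- drop(beta_new)
    if (max(abs(beta_new - beta)) < tol * (1 + max(abs(beta)))) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  eta <- drop(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  sep <- any(mu > 1 - 1e-8) || any(mu < 1e-8)
  mu_c <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  ll <- sum(y * log(mu_c) + (1 - y) * log(1 - mu_c))
  list(coef = beta, loglik = ll, fitted = mu, separation = sep)
}

# Logistic fit with automatic ridge fallback under (quasi-)separation.
logistic_fit <- function(X, y, ridge_lambda = 1e-3) {
  fit <- logistic_irls(X, y, lambda = 0)
  if (fit$separation || any(!is.finite(fit$coef))) {
    fit <- logistic_irls(X, y, lambda = ridge_lambda)
    fit$separation <- TRUE
  }
  fit
}

# Likelihood-ratio test of a single added covariate `x` against a null model
# with covariates `covar` (NULL for intercept-only). Returns the LRT
# statistic, chi-square(1) p-value, slope of x, and separation flag.
lrt_logistic <- function(y, x, covar = NULL, null_fit = NULL) {
  n <- length(y)
  X0 <- cbind(rep(1, n), covar)
  if (is.null(null_fit)) null_fit <- logistic_fit(X0, y)
  X1 <- cbind(X0, x)
  full <- logistic_fit(X1, y)
  stat <- max(0, 2 * (full$loglik - null_fit$loglik))
  list(
    statistic = stat,
    p_value = pchisq(stat, df = 1, lower.tail = FALSE),
    slope = full$coef[length(full$coef)],
    separation = full$separation,
    full = full,
    null = null_fit
  )
}

# yes/no/NA character column to logical.
yn_to_logical <- function(x) {
  out <- rep(NA, length(x))
  out[x %in% c("yes", "TRUE", "1")] <- TRUE
  out[x %in% c("no", "FALSE", "0")] <- FALSE
  if (is.logical(x)) out <- x
  out
}
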