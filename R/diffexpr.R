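# Three univariate differential-expression screens: Spearman correlation of
# expression with 14-day oxygen utilization, a resampling Wilcoxon two-group
# test on raw counts with permutation-based median FDR, and a gestational-
# age-adjusted logistic likelihood-ratio test. All screens annotate BH FDR
# (or permutation mFDR) and a median-ratio fold change.

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up adjustment with monotonicity enforced; thin wrapper over
#' [stats::p.adjust()].
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return q-values of the same length (empty in, empty out).
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  p.adjust(p_values, method = "BH")
}

# Median-ratio log2 fold change between groups on pre-log normalized values.
median_ratio_log2fc <- function(pre_log, group) {
  m1 <- apply(pre_log[, group, drop = FALSE], 1L, median)
  m0 <- apply(pre_log[, !group, drop = FALSE], 1L, median)
  log2((m1 + 0.5) / (m0 + 0.5))   # small offset guards all-zero medians
}

de_result <- function(gene_id, statistic, p_value, q_value, log2fc, significant,
                      extra = NULL) {
  df <- data.frame(
    gene_id = gene_id, statistic = statistic, p_value = p_value,
    q_value = q_value, log2_fold_change = log2fc,
    direction = ifelse(is.na(log2fc), NA_character_,
                       ifelse(log2fc >= 0, "up", "down")),
    significant = significant,
    stringsAsFactors = FALSE
  )
  if (!is.null(extra)) df <- cbind(df, extra)
  df <- df[order(df$q_value, df$p_value), ]
  rownames(df) <- NULL
  class(df) <- c("de_result", class(df))
  df
}

#' Per-gene Spearman correlation with oxygen utilization
#'
#' For each gene, the Spearman rank correlation between log2 UQ-normalized
#' expression and the per-subject 14-day oxygen AUC, with a two-sided
#' t-approximation p-value and BH q-values. The caller is expected to have
#' restricted the matrix to the at-risk (<29 weeks GAB) subgroup.
#'
#' @param norm a `uq_norm` object (subjects aligned with `auc`).
#' @param auc per-subject oxygen AUC vector (named or positionally aligned).
#' @param fdr significance threshold on the q-value (default 0.1).
#' @param group optional logical case labels used only to annotate the
#'   median-ratio fold change; when absent, `log2_fold_change` is `NA` and
#'   direction follows the sign of the correlation.
#' @return a `de_result` data.frame sorted by q-value.
#' @export
correlate_oxygen <- function(norm, auc, fdr = 0.1, group = NULL) {
  stopifnot(inherits(norm, "uq_norm"))
  x <- norm$log2_values
  stopifnot(length(auc) == ncol(x))
  if (!is.null(names(auc)) && !is.null(colnames(x))) {
    stopifnot(all(colnames(x) %in% names(auc)))
    auc <- auc[colnames(x)]
  }
  if (sd(auc) == 0) stop("oxygen AUC vector is constant; correlation undefined")
  rs <- row_spearman(x, auc)
  fc <- if (is.null(group)) rep(NA_real_, nrow(x)) else
    median_ratio_log2fc(norm_values(norm), as.logical(group))
  q <- bh_fdr(rs$p_value)
  res <- de_result(rownames(x), rs$rho, rs$p_value, q, fc, q < fdr)
  if (is.null(group)) {
    res$direction <- ifelse(res$statistic >= 0, "up", "down")
  }
  res
}

# Finite-population mean and variance of the group-1 rank sum (handles ties
# through the observed rank dispersion).
ranksum_z <- function(ranks, ind) {
  n <- ncol(ranks)
  n1 <- colSums(ind)
  W <- ranks %*% ind
  mu <- outer(rep(1, nrow(ranks)), n1 * (n + 1) / 2)
  ss <- rowSums(ranks^2) - n * ((n + 1) / 2)^2   # sum (r - rbar)^2 per gene
  v <- outer(ss, n1 * (n - n1) / (n * (n - 1)))
  z <- (W - mu) / sqrt(pmax(v, 1e-300))
  z[v <= 0] <- 0
  z
}

#' Resampling Wilcoxon two-group test on counts with permutation mFDR
#'
#' A reimplementation of the two-class resampling rank test for sequencing
#' counts: subject counts are Poisson down-sampled to the minimum subject
#' depth `n_resamples` times, a tie-aware standardized Wilcoxon rank-sum
#' statistic is computed per resample and averaged, and label permutations
#' provide the null. The median FDR (mFDR) at a cutoff is the median, over
#' permutations, of the number of null statistics exceeding the cutoff,
#' divided by the observed count; genes are called at `mfdr <`
#' `mfdr_threshold` after monotonicity enforcement.
#'
#' @param counts raw [count_matrix()] restricted to retained genes/subjects.
#' @param group logical case labels (>= 3 per group).
#' @param n_resamples Poisson down-sampling replicates (default 20).
#' @param n_perms label permutations (default 1000).
#' @param mfdr_threshold call threshold on mFDR (default 0.1).
#' @param seed RNG seed.
#' @return a `de_result` data.frame; `q_value` holds the per-gene mFDR and
#'   `p_value` is `NA` (significance is permutation-based).
#' @export
samseq_test <- function(counts, group, n_resamples = 20, n_perms = 1000,
                        mfdr_threshold = 0.1, seed = 1) {
  counts <- as_counts(counts)
  group <- as.logical(group)
  stopifnot(length(group) == ncol(counts), sum(group) >= 3, sum(!group) >= 3)
  n <- ncol(counts); g <- nrow(counts)
  depth <- colSums(counts)
  dmin <- min(depth)

  with_seed(seed, {
    ind <- matrix(0, n, n_perms + 1L)
    ind[, 1] <- as.numeric(group)
    for (p in seq_len(n_perms)) ind[sample.int(n, sum(group)), p + 1L] <- 1

    zbar <- matrix(0, g, n_perms + 1L)
    scale_fac <- dmin / depth
    for (r in seq_len(n_resamples)) {
      lam <- sweep(unclass(counts), 2L, scale_fac, `*`)
      xr <- matrix(rpois(g * n, lam), g, n)
      ranks <- row_ranks(xr)
      zbar <- zbar + ranksum_z(ranks, ind)
    }
    zbar <- zbar / n_resamples

    z_obs <- zbar[, 1]
    z_null <- abs(zbar[, -1, drop = FALSE])
    ord <- order(abs(z_obs), decreasing = TRUE)
    cutoffs <- abs(z_obs)[ord]
    # per permutation, count null exceedances at each observed cutoff
    exceed <- matrix(0L, g, n_perms)
    for (p in seq_len(n_perms)) {
      s <- sort(z_null[, p], decreasing = TRUE)
      exceed[, p] <- length(s) - findInterval(cutoffs, rev(s), left.open = TRUE)
    }
    med_exceed <- apply(exceed, 1L, median)
    mfdr_sorted <- pmin(1, med_exceed / seq_len(g))
    # enforce monotone non-increasing estimate toward stricter cutoffs
    mfdr_sorted <- rev(cummin(rev(mfdr_sorted)))
    mfdr <- numeric(g); mfdr[ord] <- mfdr_sorted

    pre <- sweep(unclass(counts), 2L, mean(depth) / depth, `*`)
    fc <- median_ratio_log2fc(pre, group)
    de_result(rownames(counts), z_obs, NA_real_, mfdr, fc,
              mfdr < mfdr_threshold)
  })
}

#' Gestational-age-adjusted logistic likelihood-ratio screen
#'
#' Per gene, a logistic regression of the binary outcome on gestational age
#' at birth (null) versus gestational age plus the gene's log2 normalized
#' expression (full); the LRT statistic 2*(ll_full - ll_null) is referred to
#' chi-square(1). Genes with (quasi-)separated fits are refit with a small
#' ridge penalty and flagged.
#'
#' @param norm a `uq_norm` object.
#' @param outcome logical case labels.
#' @param gab_weeks per-subject gestational age at birth (weeks).
#' @param fdr BH q-value threshold (default 0.1).
#' @return a `de_result` data.frame with an extra `separation` column.
#' @export
lrt_adjusted <- function(norm, outcome, gab_weeks, fdr = 0.1) {
  stopifnot(inherits(norm, "uq_norm"))
  x <- norm$log2_values
  outcome <- as.logical(outcome)
  stopifnot(length(outcome) == ncol(x), length(gab_weeks) == ncol(x),
            !anyNA(gab_weeks))
  if (length(unique(outcome)) < 2) stop("outcome does not vary")
  y <- as.numeric(outcome)
  covar <- if (sd(gab_weeks) == 0) NULL else gab_weeks
  null_fit <- logistic_fit(cbind(rep(1, length(y)), covar), y)
  res <- vapply(seq_len(nrow(x)), function(i) {
    fit <- lrt_logistic(y, x[i, ], covar = covar, null_fit = null_fit)
    c(fit$statistic, fit$p_value, as.numeric(fit$separation))
  }, numeric(3))
  stat <- res[1, ]; p <- res[2, ]; sepf <- res[3, ] > 0
  q <- bh_fdr(p)
  fc <- median_ratio_log2fc(norm_values(norm), outcome)
  de_result(rownames(x), stat, p, q, fc, q < fdr,
            extra = data.frame(separation = sepf))
}

#' Write a DE result table as TSV (sorted by q-value)
#' @param result a `de_result` data.frame.
#' @param path output file.
#' @export
write_de_result <- function(result, path) {
  write.table(result, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
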