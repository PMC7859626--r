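# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration, explicit formulas, or
# base-R model fits.

# Benjamini-Hochberg step-up by direct enumeration.
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in rev(seq_len(n))) {
    val <- min(prev, p[ord[i]] * n / i)
    q[ord[i]] <- val
    prev <- val
  }
  q
}

# Spearman rho via explicit midranks + the Pearson product-moment formula.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}

# AUC by brute-force pairwise comparison with half credit for ties.
oracle_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  s1 <- scores[labels]; s0 <- scores[!labels]
  tot <- 0
  for (a in s1) for (b in s0) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(s1) * length(s0))
}

# Conditional upper quartile by sort-and-interpolate (quantile type 7).
oracle_uq <- function(v) {
  nz <- sort(v[v > 0])
  n <- length(nz)
  h <- (n - 1) * 0.75 + 1
  lo <- floor(h); hi <- ceiling(h)
  unname(nz[lo] + (h - lo) * (nz[hi] - nz[lo]))
}

# PRD label by enumeration over completions of missing surveys: "yes" iff
# already >= 2 positive; "no" iff even with every missing survey positive
# fewer than 2 positives are reachable; otherwise "missing".
oracle_prd <- function(status) {  # status in {"positive","negative","missing"}
  n_pos <- sum(status == "positive")
  n_mis <- sum(status == "missing")
  if (n_pos >= 2) "yes" else if (n_pos + n_mis < 2) "no" else "missing"
}

# Small deterministic two-group expression fixture.
make_two_group <- function(n1 = 10, n0 = 10, n_genes = 50, shift_genes = 0,
                           shift = 0, seed = 42) {
  set.seed(seed)
  x <- matrix(rnorm(n_genes * (n1 + n0)), n_genes,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n1 + n0))))
  y <- rep(c(TRUE, FALSE), c(n1, n0))
  if (shift_genes > 0) x[seq_len(shift_genes), y] <- x[seq_len(shift_genes), y] + shift
  list(x = x, y = y)
}

# Tiny count matrix for preprocessing tests.
make_counts <- function(values, genes = NULL, subjects = NULL) {
  m <- as.matrix(values)
  rownames(m) <- genes %||% sprintf("g%d", seq_len(nrow(m)))
  colnames(m) <- subjects %||% sprintf("s%d", seq_len(ncol(m)))
  count_matrix(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Flat oxygen trace at a constant effective FiO2.
make_flat_trace <- function(fio2, n_days = 28, mode = "vent", bw = 900) {
  oxygen_trace("T1",
               data.frame(day = seq_len(n_days), fio2 = fio2,
                          support_mode = mode, flow_lpm = 0, pressure_cmH2O = 0),
               birth_weight_g = bw)
}
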