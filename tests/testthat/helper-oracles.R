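# Independent brute-force oracles used to cross-check the implementation.

# centred time-window moving average, one naive mean per sample
oracle_moving_average <- function(time_s, intensity_au, window_s) {
  vapply(seq_along(time_s), function(i) {
    mean(intensity_au[abs(time_s - time_s[i]) <= window_s / 2])
  }, numeric(1))
}

# exhaustive scan over all candidate onset start indices
oracle_onset_scan <- function(time_s, intensity_au, threshold, min_run) {
  n <- length(intensity_au)
  for (i in seq_len(n - min_run + 1)) {
    if (all(intensity_au[i:(i + min_run - 1)] > threshold)) return(time_s[i])
  }
  NA_real_
}

# dense-grid first upward half-maximum crossing of the closed-form rise
oracle_halfmax_dense <- function(alpha, n_grid = 1e5) {
  x <- seq(1e-9, 1, length.out = n_grid)
  g <- exp(alpha * (log(x) + 1 - x))
  j <- which(g >= 0.5)[1]
  # linear interpolation between bracketing grid points
  x[j - 1] + (0.5 - g[j - 1]) / (g[j] - g[j - 1]) * (x[j] - x[j - 1])
}

# normal-equations least squares (design matrix X, response y)
oracle_ols <- function(X, y) {
  solve(crossprod(X), crossprod(X, y))[, 1]
}

# CI of the mean response at x0 via the explicit hat-matrix formula
oracle_mean_ci <- function(X, y, x0, level = 0.95) {
  beta <- oracle_ols(X, y)
  n <- nrow(X); p <- ncol(X)
  s2 <- sum((y - X %*% beta)^2) / (n - p)
  se <- sqrt(s2 * drop(t(x0) %*% solve(crossprod(X)) %*% x0))
  fit <- drop(x0 %*% beta)
  tq <- qt(1 - (1 - level) / 2, n - p)
  c(fit = fit, lwr = fit - tq * se, upr = fit + tq * se)
}

# sort-based type-7 percentile
oracle_percentile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  if (lo == length(x)) return(x[lo])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

# Clopper-Pearson interval via direct beta quantiles
oracle_clopper <- function(x, n, level = 0.95) {
  a <- 1 - level
  c(if (x == 0) 0 else qbeta(a / 2, x, n - x + 1),
    if (x == n) 1 else qbeta(1 - a / 2, x + 1, n - x))
}

# two-sided Fisher exact p by full hypergeometric enumeration
oracle_fisher_enum <- function(tp, fp, fn, tn) {
  m <- tp + fn          # condition-positive margin
  n2 <- fp + tn
  k <- tp + fp          # test-positive margin
  xs <- max(0, k - n2):min(k, m)
  probs <- dhyper(xs, m, n2, k)
  p_obs <- dhyper(tp, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# AUC as the Mann-Whitney pair count
oracle_auc_pairs <- function(score, label) {
  pos <- score[label == 1]; neg <- score[label == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Spearman rho as Pearson on average ranks
oracle_spearman <- function(x, y) {
  cor(rank(x), rank(y))
}

# ROI disc mean by explicit pixel loop (x = column, y = row)
oracle_roi_mean <- function(frame, x, y, radius) {
  tot <- 0; cnt <- 0
  for (r in seq_len(nrow(frame))) for (c in seq_len(ncol(frame))) {
    if ((c - x)^2 + (r - y)^2 <= radius^2) {
      tot <- tot + frame[r, c]; cnt <- cnt + 1
    }
  }
  tot / cnt
}

# thresholded edge list by explicit double loop (strict inequality)
oracle_edges <- function(rho, threshold) {
  out <- NULL
  for (i in seq_len(nrow(rho) - 1)) for (j in (i + 1):ncol(rho)) {
    if (!is.na(rho[i, j]) && abs(rho[i, j]) > threshold)
      out <- rbind(out, data.frame(i = i, j = j, rho = rho[i, j]))
  }
  out
}

# point-by-point brute-force stepwise rule
oracle_stepwise <- function(th, tm, sl, c_th = 10, c_tm = 30, c_sl = 5) {
  vapply(seq_along(th), function(i) {
    nin <- (th[i] <= c_th) + (tm[i] <= c_tm)
    if (nin == 2) ">=60"
    else if (nin == 0) "<60"
    else if (sl[i] >= c_sl) ">=60" else "<60"
  }, character(1))
}
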