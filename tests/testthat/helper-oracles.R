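# Independent brute-force oracles used to cross-check the implementation.

# Exact two-sided rank-sum p-value by full enumeration of all
# choose(n1 + n2, n1) rank assignments (tie-free samples only).
exact_rank_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(n1 + n2, n1)
  u_all <- apply(idx, 2, function(i) sum(r[i])) - n1 * (n1 + 1) / 2
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# OLS through the normal equations.
ols_normal_equations <- function(x, y) {
  X <- cbind(1, x)
  as.numeric(solve(t(X) %*% X, t(X) %*% y))  # (intercept, slope)
}

# Linear-interpolation percentile by explicit sort-and-index.
quantile_oracle <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Small planted dataset used by several metric tests.
small_planted_ds <- function(genes = c("katG", "fhuF", "hcp"),
                             n_trenches = 30, noise = noise_off(1)) {
  tmpl <- default_regulon_templates()[genes]
  generate_tracks("planted",
                  channel_layout(n_trenches = n_trenches,
                                 cells_per_trench = 1),
                  templates = tmpl, noise = noise)
}
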