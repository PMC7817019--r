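# Independent brute-force oracles, deliberately written as literal dense
# computations so they share no code path with the implementation.

# random right-stochastic matrix with strictly positive entries
rand_stochastic <- function(n, seed) {
  set.seed(seed)
  m <- matrix(runif(n * n, min = 0.01, max = 1), n, n)
  m / rowSums(m)
}

# literal leave-self-out mapping: s(M) = L^-1 (M - V), V = diag(M),
# L = diagonal matrix of off-diagonal row sums
deself_oracle <- function(m) {
  m <- as.matrix(m)
  V <- diag(diag(m), nrow(m))
  L <- diag(rowSums(m - V), nrow(m))
  solve(L) %*% (m - V)
}

# literal diffusion recursion: Mbar_1 = M, Mbar_n = s(Mbar_{n-1}) s(M),
# objective trace mse_n = mean((s(Mbar_n) X - X)^2), everything recomputed
# from scratch with dense algebra
diffusion_trace_oracle <- function(m, x, n_max) {
  m <- as.matrix(m); x <- as.matrix(x)
  sM <- deself_oracle(m)
  mbar <- m
  out <- numeric(n_max)
  for (n in seq_len(n_max)) {
    if (n > 1) mbar <- deself_oracle(mbar) %*% sM
    out[n] <- mean((deself_oracle(mbar) %*% x - x)^2)
  }
  out
}

# explicit double-loop leave-self-out prediction
predict_oracle <- function(p, x) {
  p <- as.matrix(p); x <- as.matrix(x)
  out <- matrix(0, nrow(x), ncol(x))
  for (k in seq_len(nrow(x)))
    for (j in seq_len(ncol(x)))
      for (kh in seq_len(nrow(x)))
        if (kh != k) out[k, j] <- out[k, j] + p[k, kh] * x[kh, j]
  out
}

# all-pairs within-group Pearson correlation
wgc_oracle <- function(x, groups) {
  x <- as.matrix(x)
  vals <- c()
  for (g in unique(groups)) {
    idx <- which(groups == g)
    for (a in seq_along(idx)) for (b in seq_along(idx)) if (a < b)
      vals <- c(vals, cor(x[idx[a], ], x[idx[b], ]))
  }
  mean(vals)
}

# small preprocessed cluster fixture shared across files
cluster_fixture <- function(n_cells = 120, n_genes = 200, n_groups = 3,
                            seed = 5) {
  sim <- make_cluster_counts(n_cells, n_genes, n_groups, seed = seed)
  list(sim = sim,
       x = freeman_tukey(median_normalize(sim$counts)))
}
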