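# shared fixtures and independent oracles

# six-level chain: cytoarchitectonic area up to whole brain
chain_tree <- function() {
  region_tree(data.frame(
    name = c("brain", "telencephalon", "cerebral-cortex", "frontal-lobe",
             "dorsal-precentral-gyrus", "area-6d1"),
    parent = c(NA, "brain", "telencephalon", "cerebral-cortex",
               "frontal-lobe", "dorsal-precentral-gyrus")))
}

# OLS oracle: explicit normal equations + t-distribution, independent of lm
ols_oracle <- function(X, y) {
  xtx_inv <- solve(t(X) %*% X)
  beta <- drop(xtx_inv %*% t(X) %*% y)
  res <- y - drop(X %*% beta)
  df <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(diag(xtx_inv) * s2)
  t <- beta / se
  list(beta = beta, t = t, p = 2 * pt(-abs(t), df), df = df)
}

# brute-force voxel loop for region_volume
triple_loop_volume <- function(lvr, pmap) {
  d <- dim(lvr$grid)
  acc <- 0
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    acc <- acc + pmap$grid[i, j, k] * lvr$grid[i, j, k]
  }
  acc * lvr$voxel_volume
}

# direct step-up enumeration of the BH definition
bh_oracle <- function(pvals, q) {
  n <- length(pvals)
  ps <- sort(pvals)
  k <- 0
  for (j in n:1) {
    if (ps[j] <= j * q / n) { k <- j; break }
  }
  if (k == 0) integer(0) else which(pvals <= ps[k])
}

# a numeric vector with exactly the requested mean and sd
vector_with_moments <- function(n, mean, sd) {
  x <- seq_len(n)
  x <- (x - base::mean(x)) / stats::sd(x)
  mean + sd * x
}

# minimal deterministic cohort for exact-effect examples
exact_cohort <- function() {
  simulate_cohort(simulation_config(seed = 101))
}
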