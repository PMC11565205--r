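# Shared fixtures: built in code, never stored.

# A small, fast trial for structural tests.
small_trial <- function(seed = 11, n_genotypes = 12, ...) {
  simulate_trial(sim_config(seed = seed, n_genotypes = n_genotypes, ...))
}

# Replicate-level records with log g_s appended (the additive modelling
# scale for variance-component work).
with_log_gs <- function(records) {
  records$log_gs <- log(records$g_s)
  records
}

# Brute-force two-way ANOVA sums of squares by direct deviation sums,
# independent of the package implementation.
brute_force_ss <- function(y, A, B) {
  A <- factor(A); B <- factor(B)
  gm <- mean(y)
  mA <- tapply(y, A, mean); mB <- tapply(y, B, mean)
  mAB <- tapply(y, interaction(A, B), mean)
  r <- length(y) / (nlevels(A) * nlevels(B))
  ss_a <- sum(r * nlevels(B) * (mA - gm)^2)
  ss_b <- sum(r * nlevels(A) * (mB - gm)^2)
  ss_e <- 0; ss_ab <- 0
  for (i in levels(A)) for (j in levels(B)) {
    idx <- A == i & B == j
    cm <- mean(y[idx])
    ss_e <- ss_e + sum((y[idx] - cm)^2)
    ss_ab <- ss_ab + r * (cm - mA[[i]] - mB[[j]] + gm)^2
  }
  c(a = ss_a, b = ss_b, ab = ss_ab, e = ss_e)
}
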