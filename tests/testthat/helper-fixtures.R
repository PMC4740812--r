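# Shared fixtures: random-but-valid parameter draws and small synthetic
# configurations, all built in code at test time.

# A random promoter parameterisation whose chain is irreducible and
# aperiodic (all structural transition probabilities strictly positive).
rand_params <- function() {
  a <- runif(1, 0.05, 0.45)
  promoter_params(
    affinity = a,
    tfiid_recruit = runif(1, 0.05, min(0.45, 0.95 - a)),
    engage = runif(1, 0.2, 0.7),
    competition = runif(1, 0.1, 0.9),
    t_off = runif(1, 0.05, 0.25),
    r_M = runif(1, 1.5, 10),
    r_S = runif(1, 2, 20),
    r_D = runif(1, 2, 30),
    label = "random"
  )
}

# Moderate-residence parameters for equilibration-sensitive checks
# (relaxation time well under the default 150-step recording).
mixing_params <- function() {
  promoter_params(affinity = 0.3, tfiid_recruit = 0.1, engage = 0.6,
                  competition = 0.5, t_off = 0.1, r_M = 2, r_S = 8,
                  r_D = 20, label = "mixing")
}

# A row-stochastic matrix with every transition allowed (dirichlet-ish
# rows), for oracle comparisons.
rand_stochastic <- function(k = 5) {
  M <- matrix(stats::rgamma(k * k, shape = 1), k, k)
  M <- M / rowSums(M)
  dimnames(M) <- list(microstates()[1:k], microstates()[1:k])
  M
}

small_config <- function(n_genes = 200, ...) {
  synth_config(n_genes = n_genes,
               cytometry = list(n_events = 2000), ...)
}

# Independent eigen-based stationary distribution (oracle for the power
# iteration).
eigen_stationary <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

# Exhaustive permutation oracle for the two-sided rank-sum p-value
# (no ties): enumerate all assignments of ranks to the first sample.
perm_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  m <- length(x)
  w_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(length(pooled), m)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  mu <- m * length(y) / 2
  # two-sided: as or more extreme in distance from the null mean
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}
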