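# Independent oracles used across the suite. These deliberately use brute
# force / closed forms, never the package's own computational path.

# Exact distribution of S = sum g_i (Y_i - mu_i) over all 2^n Bernoulli
# phenotype configurations; returns P(S >= s) (observed value included).
enum_score_upper_tail <- function(g, mu, s, tol = 1e-9) {
  n <- length(g)
  stopifnot(n <= 16)
  configs <- as.matrix(expand.grid(rep(list(0:1), n)))
  pr <- apply(configs, 1, function(y) prod(ifelse(y == 1, mu, 1 - mu)))
  svals <- as.numeric(configs %*% g) - sum(g * mu)
  sum(pr[svals >= s - tol])
}

# Exact ER oracle: full enumeration over carrier phenotypes of
# P(|Q| >= |Q_obs|) with Q = sum g_c (y_c - mu_c).
enum_er_pvalue <- function(g_carriers, y_carriers, mu_carriers, tol = 1e-9) {
  m <- length(g_carriers)
  stopifnot(m <= 16)
  center <- sum(g_carriers * mu_carriers)
  q_obs <- sum(g_carriers * y_carriers) - center
  configs <- as.matrix(expand.grid(rep(list(0:1), m)))
  pr <- apply(configs, 1, function(y) {
    prod(ifelse(y == 1, mu_carriers, 1 - mu_carriers))
  })
  qs <- as.numeric(configs %*% g_carriers) - center
  sum(pr[abs(qs) >= abs(q_obs) - tol])
}

# Normal-equations OLS oracle: solve (X'X) b = X'y directly.
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  unname(drop(solve(t(X) %*% X, t(X) %*% y)))
}

# Small case-control fixture with covariates; common-MAF so tests stay on
# the asymptotic route unless they ask otherwise.
make_cohorts <- function(n_int = 400, n_ext = 300, V = 10, maf_int = 0.3,
                         maf_ext = maf_int, seed = 42) {
  withr::with_seed(seed, {
    internal <- cohort_data(
      matrix(rbinom(n_int * V, 2, maf_int), n_int,
             dimnames = list(NULL, paste0("v", seq_len(V)))),
      phenotype = rep(0:1, length.out = n_int),
      covariates = data.frame(z1 = rnorm(n_int), z2 = rbinom(n_int, 1, 0.5))
    )
    external <- cohort_data(
      matrix(rbinom(n_ext * V, 2, maf_ext), n_ext,
             dimnames = list(NULL, paste0("v", seq_len(V)))),
      covariates = data.frame(z1 = rnorm(n_ext), z2 = rbinom(n_ext, 1, 0.5))
    )
    list(internal = internal, external = external)
  })
}
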