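# Efficient-resampling p-values for low minor-allele-count variants.
#
# With m minor-allele carriers, the score is driven entirely by the carrier
# phenotypes. Conditional on the null fit, the carrier phenotypes are
# independent Bernoulli(mu_i); the p-value decomposes over D, the number of
# cases among the carriers:
#   Pr(|Q| >= |Q_obs|) = sum_d Pr(|Q| >= |Q_obs| | D = d) Pr(D = d),
# with Pr(D = d) the Poisson-binomial of the carrier case-probabilities and
# the inner term enumerated exactly over the C(m, d) case assignments
# (weighted by their conditional probabilities) whenever that is feasible.
# Q is the raw carrier score sum g_i (y_i - mu_i); genotype-2 carriers enter
# with weight 2. The observed outcome is counted in its own tail, so p > 0.

# Poisson-binomial pmf of sum of independent Bernoulli(prob) by convolution.
dpoisbinom <- function(prob) {
  pmf <- 1
  for (p in prob) pmf <- c(pmf * (1 - p), 0) + c(0, pmf * p)
  pmf
}

#' Efficient-resampling (exact conditional) p-value for a rare variant
#'
#' @param G Genotype dosage vector, minor-allele coded (carriers are
#'   subjects with `G >= 1`). The scan dispatch flips major-coded variants
#'   before calling.
#' @param null_model An [fit_null_model()] fit on the same subjects.
#' @param enum_limit Enumerate all case assignments for a given `D = d`
#'   when `choose(m, d)` is at most this (default 1e5); otherwise estimate
#'   that term by self-normalized importance sampling over uniform
#'   d-subsets.
#' @param n_samples Number of sampled subsets per non-enumerable `d`.
#' @param seed Optional seed for the sampling branch.
#' @return One-row tibble: `m` (carrier count), `q_obs` (observed carrier
#'   score), `p_value`, `method` (`"exact_enumeration"` or
#'   `"conditional_sampling"`).
#' @examples
#' y <- c(1, 1, 0, 0, 0, 0, 0, 0)
#' nm <- fit_null_model(y)
#' er_pvalue(c(1, 1, 0, 0, 0, 0, 0, 0), nm)
#' @export
er_pvalue <- function(G, null_model, enum_limit = 1e5, n_samples = 1e4,
                      seed = NULL) {
  G <- as.numeric(G)
  carriers <- which(G >= 1)
  m <- length(carriers)
  if (m == 0) {
    return(tibble(m = 0L, q_obs = 0, p_value = 1, method = "exact_enumeration"))
  }
  g <- G[carriers]
  mu <- null_model$mu[carriers]
  y <- null_model$y[carriers]
  center <- sum(g * mu)
  q_obs <- sum(g * y) - center
  # distribution of D = number of cases among carriers
  pd <- dpoisbinom(mu)
  tol <- 1e-9 * max(1, abs(q_obs))
  p <- 0
  sampled <- FALSE
  for (d in 0:m) {
    if (pd[d + 1] <= 0) next
    if (d == 0 || d == m) {
      q <- sum(g) * (d == m) - center
      p_cond <- as.numeric(abs(q) >= abs(q_obs) - tol)
    } else if (choose(m, d) <= enum_limit) {
      subsets <- combn(m, d)
      qs <- colSums(matrix(g[subsets], nrow = d)) - center
      # conditional probability of each assignment given D = d:
      # product of mu over cases times (1-mu) over non-cases
      lw <- colSums(matrix(log(mu[subsets]) - log(1 - mu[subsets]), nrow = d)) +
        sum(log(1 - mu))
      w <- exp(lw - max(lw))
      p_cond <- sum(w * (abs(qs) >= abs(q_obs) - tol)) / sum(w)
    } else {
      sampled <- TRUE
      p_cond <- with_seed(seed, {
        hits <- w_tot <- 0
        for (r in seq_len(n_samples)) {
          a <- sample.int(m, d)
          w <- exp(sum(log(mu[a])) + sum(log(1 - mu[-a])))
          w_tot <- w_tot + w
          hits <- hits + w * (abs(sum(g[a]) - center) >= abs(q_obs) - tol)
        }
        hits / w_tot
      })
    }
    p <- p + p_cond * pd[d + 1]
  }
  tibble(m = m, q_obs = q_obs, p_value = min(max(p, .Machine$double.xmin), 1),
         method = if (sampled) "conditional_sampling" else "exact_enumeration")
}
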