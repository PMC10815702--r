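# Covariate-adjusted logistic score test for one variant.
#
# With null fit mu-hat and V = diag(mu(1-mu)), the covariate-adjusted
# genotype is Gt = G - Z (Z'VZ)^-1 Z'V G, the score is S = Gt'(y - mu),
# Var(S) = sum Gt_i^2 v_i, and T = S^2/Var(S) is asymptotically chi-square
# with 1 df under no association.

#' Covariate-adjusted genotype residual
#'
#' Returns the V-weighted projection residual of the genotype on the column
#' space of the covariates: `G - Z (Z'VZ)^{-1} Z'V G`. Accepts a matrix to
#' adjust many variants in one call.
#'
#' @param G Genotype vector (length n) or n x V matrix.
#' @param null_model An [fit_null_model()] fit.
#' @return Adjusted genotype(s), same shape as `G`.
#' @export
adjust_genotype <- function(G, null_model) {
  stopifnot(inherits(null_model, "iecat_null"))
  Z <- null_model$Z
  v <- null_model$v
  if (is.matrix(G)) {
    if (nrow(G) != null_model$n) abort("genotype rows must match the null fit.")
    G - Z %*% (null_model$zvz_inv %*% crossprod(Z, v * G))
  } else {
    if (length(G) != null_model$n) abort("genotype length must match the null fit.")
    drop(G - Z %*% (null_model$zvz_inv %*% crossprod(Z, v * G)))
  }
}

#' Single-variant logistic score test (asymptotic route)
#'
#' @param G Genotype dosage vector for one variant.
#' @param null_model An [fit_null_model()] fit on the same subjects.
#' @return A one-row tibble: `score`, `var_score`, `g_tilde` (list column
#'   with the adjusted genotype), `t_stat`, `p_value`, `route`. A variant
#'   that is monomorphic after adjustment (`var_score = 0`) gets `p = 1`
#'   with route `"monomorphic"` rather than an error.
#' @examples
#' y <- rbinom(500, 1, 0.3)
#' nm <- fit_null_model(y)
#' score_test(rbinom(500, 2, 0.2), nm)
#' @export
score_test <- function(G, null_model) {
  if (!null_model$converged) {
    abort("null model did not converge; refusing to test against it.")
  }
  gt <- adjust_genotype(G, null_model)
  S <- sum(gt * (null_model$y - null_model$mu))
  varS <- sum(gt^2 * null_model$v)
  if (varS <= 0) {
    return(tibble(score = S, var_score = varS, g_tilde = list(gt),
                  t_stat = 0, p_value = 1, route = "monomorphic"))
  }
  t_stat <- S^2 / varS
  tibble(score = S, var_score = varS, g_tilde = list(gt), t_stat = t_stat,
         p_value = pchisq(t_stat, df = 1, lower.tail = FALSE),
         route = "asymptotic")
}

# Vectorized score machinery for a genotype matrix (used by the scan and the
# simulation harness): returns per-variant score, variance, z and the
# adjusted matrix.
score_components_matrix <- function(Gmat, null_model) {
  gt <- adjust_genotype(Gmat, null_model)
  S <- unname(drop(crossprod(gt, null_model$y - null_model$mu)))
  varS <- unname(drop(crossprod(gt^2, null_model$v)))
  z <- ifelse(varS > 0, S / sqrt(pmax(varS, 1e-300)), 0)
  list(g_tilde = gt, score = S, var_score = varS, z = z)
}
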