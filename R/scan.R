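# Per-variant orchestration of the three analysis strategies:
#   internal  - internal cases and controls only
#   naive     - internal subjects plus raw external controls (Y = 0)
#   rc        - internal subjects plus regression-calibrated external controls
# and the p-value dispatch rule: efficient resampling when the minor-allele
# count is low, saddlepoint calibration when external controls are
# integrated or the internal case fraction is small, asymptotic chi-square
# otherwise.

#' Dispatch configuration for p-value calibration
#'
#' @param mac_threshold Use the efficient-resampling route when the sample
#'   minor-allele count is below this (default 10).
#' @param spa_policy `"auto"` applies the saddlepoint route to combined
#'   samples and whenever the case fraction is below 1/3 (the normal and
#'   saddlepoint approximations agree for balanced designs); `"always"` and
#'   `"never"` override.
#' @param spa_cutoff Normal-scale |z| below which the saddlepoint route
#'   returns the normal approximation directly (see [spa_pvalue()]).
#' @param er_enum_limit,er_samples Enumeration/sampling switch for
#'   [er_pvalue()].
#' @param seed Seed for the (rarely reached) ER sampling branch.
#' @return A list of class `iecat_dispatch`.
#' @export
dispatch_config <- function(mac_threshold = 10, spa_policy = c("auto", "always", "never"),
                            spa_cutoff = 1.2, er_enum_limit = 1e5,
                            er_samples = 1e4, seed = NULL) {
  structure(
    list(mac_threshold = mac_threshold, spa_policy = match.arg(spa_policy),
         spa_cutoff = spa_cutoff, er_enum_limit = er_enum_limit,
         er_samples = er_samples, seed = seed),
    class = "iecat_dispatch"
  )
}

# p-values for every column of a genotype matrix under one null fit.
# `combined` marks integrated (internal + external) samples for the SPA
# policy. Returns a tibble, one row per variant.
pvalues_for_matrix <- function(Gmat, null_model, dispatch = dispatch_config(),
                               combined = FALSE) {
  Gmat <- as_dosage_matrix(Gmat)
  comp <- score_components_matrix(Gmat, null_model)
  n <- null_model$n
  V <- ncol(Gmat)
  ac <- colSums(Gmat)
  mac <- pmin(ac, 2 * n - ac)
  p <- pchisq(comp$z^2, df = 1, lower.tail = FALSE)
  route <- rep("asymptotic", V)
  mono <- comp$var_score <= 0
  p[mono] <- 1
  route[mono] <- "monomorphic"

  er_idx <- which(!mono & mac > 0 & mac < dispatch$mac_threshold)
  for (j in er_idx) {
    g <- Gmat[, j]
    if (ac[j] > n) g <- 2 - g  # flip to minor-allele coding
    p[j] <- er_pvalue(g, null_model, dispatch$er_enum_limit,
                      dispatch$er_samples, dispatch$seed)$p_value
    route[j] <- "ER"
  }

  spa_on <- switch(dispatch$spa_policy,
    always = TRUE, never = FALSE,
    auto = combined || null_model$n_case / n < 1 / 3
  )
  if (spa_on) {
    cand <- which(!mono & !(seq_len(V) %in% er_idx))
    hot <- cand[abs(comp$z[cand]) >= dispatch$spa_cutoff]
    route[cand] <- "SPA_fallback_normal"
    for (j in hot) {
      sp <- spa_pvalue(comp$g_tilde[, j], null_model$mu, comp$score[j],
                       cutoff = 0)
      p[j] <- sp$p_value
      route[j] <- if (sp$fallback_used) "SPA_fallback_normal" else "SPA"
    }
  }

  tibble(
    variant_id = variant_ids(Gmat),
    n = n, n_case = null_model$n_case, mac = as.numeric(mac),
    score = comp$score, var_score = comp$var_score,
    t_stat = ifelse(comp$var_score > 0, comp$z^2, 0),
    p_value = p, route = route
  )
}

#' Test a single variant under a fitted null model
#'
#' Applies the full dispatch rule (ER at low minor-allele count, saddlepoint
#' calibration per policy, asymptotic otherwise) to one genotype vector.
#'
#' @param G Genotype dosage vector.
#' @param null_model An [fit_null_model()] fit on the same subjects.
#' @param dispatch A [dispatch_config()].
#' @param combined Whether the sample integrates external controls (drives
#'   the `"auto"` saddlepoint policy).
#' @param variant_id Label for the result row.
#' @return One-row results tibble (see [iecat_scan()]).
#' @export
test_variant <- function(G, null_model, dispatch = dispatch_config(),
                         combined = FALSE, variant_id = "v1") {
  m <- matrix(as.numeric(G), ncol = 1, dimnames = list(NULL, variant_id))
  pvalues_for_matrix(m, null_model, dispatch, combined)
}

# Assemble phenotype / covariates / genotypes for one analysis strategy.
assemble_analysis_sample <- function(method, internal, external = NULL,
                                     external_genotypes = NULL) {
  y_int <- check_binary_phenotype(internal$phenotype)
  cov_int <- cohort_covariates(internal)
  if (method == "internal") {
    return(list(y = y_int, covariates = cov_int, G = internal$genotypes))
  }
  if (is.null(external)) abort("integration methods need an external cohort.")
  Ge <- external_genotypes %||% external$genotypes
  cov_ext <- cohort_covariates(external)
  if (xor(is.null(cov_int), is.null(cov_ext)) ||
      (!is.null(cov_int) && ncol(cov_int) != ncol(cov_ext))) {
    abort("internal and external cohorts must carry matching covariate columns.")
  }
  list(
    y = c(y_int, rep(0, external$n)),
    covariates = if (is.null(cov_int)) NULL else rbind(cov_int, cov_ext),
    G = rbind(internal$genotypes, Ge)
  )
}

# covariates + PCs, no intercept (fit_null_model adds it)
cohort_covariates <- function(cohort) {
  parts <- list()
  if (!is.null(cohort$covariates)) {
    cv <- as.matrix(as.data.frame(cohort$covariates))
    storage.mode(cv) <- "double"
    parts <- c(parts, list(cv))
  }
  if (!is.null(cohort$pcs)) parts <- c(parts, list(cohort$pcs))
  if (length(parts) == 0) NULL else do.call(cbind, parts)
}

#' Scan all variants with one analysis strategy
#'
#' Fits the covariate-only null model once, then tests every variant of the
#' assembled analysis sample: internal subjects only (`"internal"`),
#' internal plus raw external controls (`"naive"`), or internal plus
#' regression-calibrated external controls (`"rc"`, the full method).
#'
#' @param internal An [cohort_data()] cohort with 0/1 phenotype.
#' @param external A control-only [cohort_data()] cohort over the same
#'   variants (required unless `method = "internal"`).
#' @param method `"rc"`, `"naive"` or `"internal"`.
#' @param K,p Calibration repeats and PC count passed to
#'   [calibrate_external()] (method `"rc"` only).
#' @param dispatch A [dispatch_config()].
#' @param seed Seed for the calibration draws.
#' @return A tibble of class `iecat_scan`, one row per variant: variant_id,
#'   method, n, n_case, mac, score, var_score, t_stat, p_value, route, and a
#'   reserved `p_iecat_score` column (NA) for merging externally computed
#'   shrinkage-score p-values.
#' @examples
#' set.seed(2)
#' internal <- cohort_data(matrix(rbinom(1000, 2, 0.3), 500),
#'                         phenotype = rep(0:1, 250),
#'                         covariates = data.frame(z1 = rnorm(500)))
#' external <- cohort_data(matrix(rbinom(400, 2, 0.3), 200),
#'                         covariates = data.frame(z1 = rnorm(200)))
#' iecat_scan(internal, external, method = "rc", seed = 1)
#' @export
iecat_scan <- function(internal, external = NULL,
                       method = c("rc", "naive", "internal"),
                       K = 10, p = 0, dispatch = dispatch_config(),
                       seed = NULL) {
  method <- match.arg(method)
  cal_genotypes <- NULL
  if (method == "rc") {
    cal <- calibrate_external(internal, external, K = K, p = p, seed = seed)
    cal_genotypes <- cal$calibrated
  }
  smp <- assemble_analysis_sample(method, internal, external, cal_genotypes)
  null_model <- fit_null_model(smp$y, smp$covariates)
  res <- pvalues_for_matrix(smp$G, null_model, dispatch,
                            combined = method != "internal")
  res <- mutate(res, method = method, p_iecat_score = NA_real_,
                .after = "variant_id")
  class(res) <- c("iecat_scan", class(res))
  res
}

#' @method autoplot iecat_scan
#' @export
autoplot.iecat_scan <- function(object, ...) {
  d <- arrange(as_tibble(object), .data$p_value)
  d$expected <- (seq_len(nrow(d)) - 0.5) / nrow(d)
  ggplot(d, aes(x = -log10(.data$expected), y = -log10(.data$p_value))) +
    geom_point(alpha = 0.7) +
    geom_hline(yintercept = 0, linewidth = 0) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    labs(x = "expected -log10(p)", y = "observed -log10(p)",
         title = "Score-test p-value diagnostics") +
    theme_minimal()
}
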