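#' Bundle one cohort's genotypes, phenotypes, covariates and PCs
#'
#' A cohort is the unit the association machinery works on: a subjects x
#' variants dosage matrix (0/1/2 copies of the coded allele), an optional
#' binary phenotype (absent for control-only external cohorts, where every
#' subject is a control), an optional covariate table and optional genotype
#' principal components.
#'
#' @param genotypes Numeric subjects x variants matrix with entries in
#'   \{0, 1, 2\} (or imputed dosages in \[0, 2\]). A data frame is accepted and
#'   converted. Column names are used as variant IDs.
#' @param phenotype Optional numeric/integer vector of 0/1 disease status,
#'   one per subject. `NULL` declares a control-only cohort (all subjects
#'   treated as controls, phenotype 0).
#' @param covariates Optional data frame or matrix of per-subject covariates
#'   (no intercept column; it is added by the model code).
#' @param pcs Optional subjects x p matrix of genotype principal components,
#'   ordered by decreasing explained variance (see [compute_pcs()]).
#' @return An object of class `iecat_cohort`: a list with elements
#'   `genotypes`, `phenotype`, `covariates`, `pcs`, `n`, `n_case`, `n_control`.
#' @examples
#' g <- matrix(rbinom(20, 2, 0.3), nrow = 10)
#' coh <- cohort_data(g, phenotype = rep(c(0, 1), 5))
#' coh$n_case
#' @export
cohort_data <- function(genotypes, phenotype = NULL, covariates = NULL,
                        pcs = NULL) {
  g <- as_dosage_matrix(genotypes)
  n <- nrow(g)
  if (!is.null(phenotype)) {
    phenotype <- check_binary_phenotype(phenotype)
    if (length(phenotype) != n) {
      abort("phenotype length must equal the number of genotype rows.")
    }
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n) {
      abort("covariates must have one row per subject.")
    }
  }
  if (!is.null(pcs)) {
    pcs <- as_dosage_matrix(pcs, "pcs")
    if (nrow(pcs) != n) abort("pcs must have one row per subject.")
  }
  structure(
    list(
      genotypes = g,
      phenotype = phenotype,
      covariates = covariates,
      pcs = pcs,
      n = n,
      n_case = if (is.null(phenotype)) 0L else as.integer(sum(phenotype)),
      n_control = if (is.null(phenotype)) n else as.integer(sum(1 - phenotype))
    ),
    class = "iecat_cohort"
  )
}

#' @export
print.iecat_cohort <- function(x, ...) {
  cat(sprintf(
    "<iecat_cohort> %d subjects (%d cases, %d controls), %d variants%s%s\n",
    x$n, x$n_case, x$n_control, ncol(x$genotypes),
    if (is.null(x$covariates)) "" else
      sprintf(", %d covariates", ncol(x$covariates)),
    if (is.null(x$pcs)) "" else sprintf(", %d PCs", ncol(x$pcs))
  ))
  invisible(x)
}

# covariate design for a cohort: intercept + covariates + pcs
cohort_design <- function(cohort, use_pcs = TRUE) {
  parts <- list(`(Intercept)` = rep(1, cohort$n))
  if (!is.null(cohort$covariates)) {
    cv <- as.matrix(cohort$covariates)
    storage.mode(cv) <- "double"
    parts <- c(parts, list(cv))
  }
  if (use_pcs && !is.null(cohort$pcs)) parts <- c(parts, list(cohort$pcs))
  do.call(cbind, parts)
}
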