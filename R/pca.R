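#' Genotype principal components
#'
#' Column-mean-centers a subjects x variants dosage matrix and returns the
#' top-p principal component scores (left singular vectors scaled by their
#' singular values). The sign of each component is fixed by forcing its
#' largest-magnitude variant loading to be positive, so results are
#' deterministic.
#'
#' @param genotypes Subjects x variants numeric matrix, no missing entries
#'   (impute upstream, e.g. with [apply_basic_qc()]).
#' @param p Number of components to keep. `p = 0` returns an empty score
#'   matrix (useful for pure simulations with no PC structure).
#' @return An object of class `iecat_pca`: list with `scores` (subjects x p),
#'   `loadings` (variants x p), `d` (singular values), `center` (column
#'   means), `p`.
#' @seealso [project_pcs()] to place new subjects on existing loadings.
#' @examples
#' g <- matrix(rbinom(200, 2, 0.3), nrow = 20)
#' pca <- compute_pcs(g, p = 2)
#' dim(pca$scores)
#' @export
compute_pcs <- function(genotypes, p = 10) {
  g <- as_dosage_matrix(genotypes)
  if (anyNA(g)) abort("genotype matrix has missing entries; impute first.")
  p <- as.integer(p)
  if (p < 0) abort("p must be >= 0.")
  center <- colMeans(g)
  if (p == 0) {
    return(structure(
      list(scores = matrix(0, nrow(g), 0), loadings = matrix(0, ncol(g), 0),
           d = numeric(0), center = center, p = 0L),
      class = "iecat_pca"
    ))
  }
  if (p > min(dim(g))) {
    abort(sprintf("p = %d exceeds min(subjects, variants) = %d.",
                  p, min(dim(g))))
  }
  gc <- sweep(g, 2, center)
  sv <- svd(gc, nu = p, nv = p)
  rank <- sum(sv$d > sv$d[1] * 1e-10)
  if (p > rank) {
    abort(sprintf("p = %d exceeds the matrix rank (%d).", p, rank))
  }
  u <- sv$u
  v <- sv$v
  # deterministic sign: largest-|loading| entry of each component positive
  for (j in seq_len(p)) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) {
      v[, j] <- -v[, j]
      u[, j] <- -u[, j]
    }
  }
  structure(
    list(scores = u %*% diag(sv$d[seq_len(p)], p, p), loadings = v,
         d = sv$d[seq_len(p)], center = center, p = p),
    class = "iecat_pca"
  )
}

#' Project new subjects onto fitted principal-component loadings
#'
#' Used to give external subjects coordinates in the internal cohort's PC
#' space: the new genotypes are centered with the fitted column means and
#' multiplied by the stored loadings.
#'
#' @param pca An `iecat_pca` from [compute_pcs()].
#' @param genotypes New subjects x variants matrix over the same variants.
#' @return Subjects x p score matrix.
#' @export
project_pcs <- function(pca, genotypes) {
  g <- as_dosage_matrix(genotypes)
  if (ncol(g) != length(pca$center)) {
    abort("new genotypes must cover the same variants as the fitted PCA.")
  }
  sweep(g, 2, pca$center) %*% pca$loadings
}
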