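# Small shared helpers. Nothing here is user-facing.

expit <- stats::plogis

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so calls are reproducible without
#' disturbing the caller's RNG stream.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG stream alone.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive n child seeds (< 2^31) from one parent seed, reproducibly.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# subjects x variants dosage matrix coercion with basic checks
as_dosage_matrix <- function(x, what = "genotypes") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, ncol = 1)
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric subjects x variants matrix.", what))
  }
  storage.mode(x) <- "double"
  x
}

check_binary_phenotype <- function(y) {
  y <- as.numeric(y)
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    abort("phenotype must be coded 0/1 with no missing values.")
  }
  y
}

variant_ids <- function(g) {
  colnames(g) %||% paste0("v", seq_len(ncol(g)))
}
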