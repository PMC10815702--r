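# Regression calibration of external-control genotypes.
#
# External controls come from a different study; platform and calling
# differences (batch effects) shift their genotype distribution relative to
# the internal controls. Calibration maps each external genotype through a
# paired least-squares model averaged over K random pairings, then
# discretizes the continuous predictions so that the calibrated genotype
# frequencies match the internal-control frequencies.

#' One paired least-squares calibration repeat
#'
#' Pairs a random subsample of external controls with the internal controls
#' and regresses the internal-control genotype on the paired external
#' genotype (plus optional PC terms for both cohorts). Uses the current RNG
#' stream unless `pairing` is supplied.
#'
#' @param internal_control_genotypes Numeric vector (length n0I) of internal
#'   control dosages in \{0,1,2\}.
#' @param external_genotypes Numeric vector (length n0E >= n0I unless a
#'   partial-block pairing is supplied) of external control dosages.
#' @param internal_pcs Optional n0I x p matrix of internal-subject PCs.
#' @param external_pcs Optional n0E x p matrix of external-subject PCs.
#' @param pairing Optional list with integer vectors `int` and `ext` of equal
#'   length giving the paired row indices; drawn via [draw_pairing()] when
#'   `NULL`.
#' @param on_singular `"error"` to fail on a rank-deficient design (the
#'   message names `variant_id`), `"zero"` to drop the offending columns and
#'   set their coefficients to zero (used by the scan paths so monomorphic
#'   blocks degrade to an intercept-only fit rather than aborting).
#' @param variant_id Label used in error messages.
#' @return Named numeric vector `c(beta0, beta1, alphaI..., alphaE...)`.
#' @export
fit_calibration_repeat <- function(internal_control_genotypes,
                                   external_genotypes,
                                   internal_pcs = NULL, external_pcs = NULL,
                                   pairing = NULL,
                                   on_singular = c("error", "zero"),
                                   variant_id = "?") {
  on_singular <- match.arg(on_singular)
  G <- as.numeric(internal_control_genotypes)
  g <- as.numeric(external_genotypes)
  n0I <- length(G)
  if (n0I < 2) abort("need at least 2 internal controls to calibrate.")
  if (is.null(pairing)) {
    if (length(g) < n0I) {
      abort(sprintf(
        "variant %s: external block (%d) smaller than internal controls (%d); supply a partial-block pairing.",
        variant_id, length(g), n0I))
    }
    pairing <- draw_pairing(n0I, length(g))
  }
  p <- if (is.null(internal_pcs)) 0L else ncol(internal_pcs)
  X <- cbind(1, g[pairing$ext])
  if (p > 0) {
    X <- cbind(X, internal_pcs[pairing$int, , drop = FALSE],
               external_pcs[pairing$ext, , drop = FALSE])
  }
  y <- G[pairing$int]
  qx <- qr(X)
  coefs <- rep(0, ncol(X))
  if (qx$rank < ncol(X)) {
    if (on_singular == "error") {
      abort(sprintf("variant %s: singular calibration design (rank %d < %d).",
                    variant_id, qx$rank, ncol(X)))
    }
    keep <- qx$pivot[seq_len(qx$rank)]
    coefs[keep] <- qr.coef(qr(X[, keep, drop = FALSE]), y)
  } else {
    coefs <- qr.coef(qx, y)
  }
  names(coefs) <- c("beta0", "beta1",
                    if (p > 0) c(paste0("alphaI", seq_len(p)),
                                 paste0("alphaE", seq_len(p))))
  coefs
}

#' Draw one internal/external pairing for a calibration repeat
#'
#' Full blocks (`m >= n0I`): all internal controls, in order, paired with
#' `n0I` external subjects sampled without replacement. Partial blocks
#' (`m < n0I`): the whole block, in random order, paired with an equal-sized
#' simple random subsample of internal controls.
#'
#' @param n0I Number of internal controls.
#' @param m External block size.
#' @return List with integer index vectors `int` and `ext`.
#' @export
draw_pairing <- function(n0I, m) {
  if (m >= n0I) {
    list(int = seq_len(n0I), ext = sample.int(m, n0I))
  } else {
    list(int = sort(sample.int(n0I, m)), ext = sample.int(m, m))
  }
}

#' Discretize continuous calibrated genotypes by internal-control frequencies
#'
#' Thresholds a0 <= a1 are chosen so that the frequencies of genotype 0 and
#' of genotypes \{0,1\} among the discretized values match the
#' internal-control frequencies (to within rounding, 1/m). Implemented by
#' rank: the lowest `round(f0*m)` predictions become 0, the next
#' `round(f1*m)` become 1, the rest 2. Ties between equal predictions are
#' broken uniformly at random (current RNG stream), so the frequency match
#' holds even when the predictions are discrete — which is the rule rather
#' than the exception when no PCs enter the model and predictions take at
#' most three distinct values.
#'
#' @param continuous_predictions Numeric vector (length m) of continuous
#'   calibrated genotypes.
#' @param internal_control_genotypes Internal control dosages whose 0/1/2
#'   frequencies are to be matched.
#' @return List with `a0`, `a1` (the realized thresholds; `-Inf` when a
#'   category is empty), and `discrete` (integer vector in \{0,1,2\}).
#' @examples
#' discretize_by_internal_frequency(c(.1, .2, .3, .4), c(0, 0, 1, 2))
#' @export
discretize_by_internal_frequency <- function(continuous_predictions,
                                             internal_control_genotypes) {
  x <- as.numeric(continuous_predictions)
  m <- length(x)
  if (m < 1) abort("no predictions to discretize.")
  G <- as.numeric(internal_control_genotypes)
  f0 <- mean(G == 0)
  f01 <- mean(G <= 1)
  n0 <- round(f0 * m)
  n01 <- max(round(f01 * m), n0)
  ord <- order(x, runif(m))
  disc <- integer(m)
  if (n0 < m) disc[ord[(n0 + 1):m]] <- 1L
  if (n01 < m) disc[ord[(n01 + 1):m]] <- 2L
  list(
    a0 = if (n0 >= 1) x[ord[n0]] else -Inf,
    a1 = if (n01 >= 1) x[ord[n01]] else -Inf,
    discrete = disc
  )
}

#' Calibrate one external block against the internal controls
#'
#' Runs K paired least-squares repeats (fresh pairing each repeat), averages
#' the coefficient estimates element-wise, predicts a continuous calibrated
#' genotype for every block member, and discretizes by internal-control
#' frequency matching.
#'
#' @inheritParams fit_calibration_repeat
#' @param external_block_genotypes External dosages for this block (length m).
#' @param external_block_pcs Optional m x p external-PC rows for the block.
#' @param internal_pcs_of_block Optional m x p internal-PC coordinates of the
#'   block members (external subjects projected onto the internal loadings);
#'   required when PCs are used, because the prediction model has both an
#'   internal-PC and an external-PC term for each external subject.
#' @param K Number of pairing repeats to average.
#' @param pairings Optional list of K pairings (see [draw_pairing()]).
#' @return List with `coefficients` (averaged), `a0`, `a1`, `K`,
#'   `continuous` and `discrete` calibrated genotypes for the block.
#' @export
calibrate_block <- function(internal_control_genotypes,
                            external_block_genotypes,
                            internal_pcs = NULL,
                            external_block_pcs = NULL,
                            internal_pcs_of_block = NULL,
                            K = 10, pairings = NULL,
                            on_singular = "zero", variant_id = "?") {
  K <- as.integer(K)
  if (K < 1) abort("K must be >= 1.")
  G <- as.numeric(internal_control_genotypes)
  g <- as.numeric(external_block_genotypes)
  m <- length(g)
  if (is.null(pairings)) {
    pairings <- replicate(K, draw_pairing(length(G), m), simplify = FALSE)
  }
  coefs <- vapply(pairings, function(pr) {
    fit_calibration_repeat(G, g, internal_pcs, external_block_pcs,
                           pairing = pr, on_singular = on_singular,
                           variant_id = variant_id)
  }, numeric(2 + 2 * (if (is.null(internal_pcs)) 0 else ncol(internal_pcs))))
  avg <- rowMeans(matrix(coefs, ncol = K))
  names(avg) <- rownames(coefs)
  cont <- avg[1] + avg[2] * g
  p <- if (is.null(internal_pcs)) 0L else ncol(internal_pcs)
  if (p > 0) {
    cont <- cont + internal_pcs_of_block %*% avg[3:(2 + p)] +
      external_block_pcs %*% avg[(3 + p):(2 + 2 * p)]
    cont <- drop(cont)
  }
  dz <- discretize_by_internal_frequency(cont, G)
  list(coefficients = avg, a0 = dz$a0, a1 = dz$a1, K = K,
       continuous = cont, discrete = dz$discrete)
}

# consecutive blocks of size <= n0I covering 1..n0E
block_partition <- function(n0E, n0I) {
  split(seq_len(n0E), ceiling(seq_len(n0E) / n0I))
}

# Shared engine: calibrate every column of an external genotype matrix.
# Pairings are drawn once per (block, repeat) and shared across variants;
# per-variant RNG is only the discretization tie-break, consumed in variant-
# major order so the vectorized p = 0 path and the general path are
# bit-identical under the same seed.
calibrate_genotype_matrix <- function(internal_control_genotypes,
                                      external_genotypes, K = 10,
                                      internal_pcs = NULL,
                                      external_pcs = NULL,
                                      internal_pcs_of_external = NULL) {
  Gint <- as_dosage_matrix(internal_control_genotypes)
  Gext <- as_dosage_matrix(external_genotypes)
  if (ncol(Gint) != ncol(Gext)) abort("variant sets differ between cohorts.")
  n0I <- nrow(Gint)
  n0E <- nrow(Gext)
  V <- ncol(Gint)
  p <- if (is.null(internal_pcs)) 0L else ncol(internal_pcs)
  blocks <- block_partition(n0E, n0I)
  pairings <- lapply(blocks, function(b) {
    replicate(K, draw_pairing(n0I, length(b)), simplify = FALSE)
  })
  out <- matrix(0L, n0E, V, dimnames = list(rownames(Gext), colnames(Gext)))
  report <- vector("list", V * length(blocks))
  vid <- variant_ids(Gext)

  if (p == 0) {
    # closed-form OLS (slope, intercept) per block/repeat, all variants at once
    block_coefs <- lapply(seq_along(blocks), function(bi) {
      b <- blocks[[bi]]
      acc0 <- numeric(V); acc1 <- numeric(V)
      for (k in seq_len(K)) {
        pr <- pairings[[bi]][[k]]
        y <- Gint[pr$int, , drop = FALSE]
        x <- Gext[b, , drop = FALSE][pr$ext, , drop = FALSE]
        nm <- length(pr$int)
        mx <- colMeans(x); my <- colMeans(y)
        vx <- colMeans(x * x) - mx^2
        cxy <- colMeans(x * y) - mx * my
        b1 <- ifelse(vx > 0, cxy / vx, 0)
        acc1 <- acc1 + b1
        acc0 <- acc0 + (my - b1 * mx)
      }
      list(beta0 = acc0 / K, beta1 = acc1 / K)
    })
    ri <- 1L
    for (v in seq_len(V)) {
      for (bi in seq_along(blocks)) {
        b <- blocks[[bi]]
        cf <- block_coefs[[bi]]
        cont <- cf$beta0[v] + cf$beta1[v] * Gext[b, v]
        dz <- discretize_by_internal_frequency(cont, Gint[, v])
        out[b, v] <- dz$discrete
        report[[ri]] <- tibble(
          variant_id = vid[v], block = bi,
          beta0 = cf$beta0[v], beta1 = cf$beta1[v],
          a0 = dz$a0, a1 = dz$a1, K = K
        )
        ri <- ri + 1L
      }
    }
  } else {
    ri <- 1L
    for (v in seq_len(V)) {
      for (bi in seq_along(blocks)) {
        b <- blocks[[bi]]
        cb <- calibrate_block(
          Gint[, v], Gext[b, v],
          internal_pcs = internal_pcs,
          external_block_pcs = external_pcs[b, , drop = FALSE],
          internal_pcs_of_block = internal_pcs_of_external[b, , drop = FALSE],
          K = K, pairings = pairings[[bi]], variant_id = vid[v]
        )
        out[b, v] <- cb$discrete
        report[[ri]] <- tibble(
          variant_id = vid[v], block = bi,
          beta0 = unname(cb$coefficients[1]), beta1 = unname(cb$coefficients[2]),
          a0 = cb$a0, a1 = cb$a1, K = K
        )
        ri <- ri + 1L
      }
    }
  }
  list(calibrated = out, report = bind_rows(report))
}

#' Calibrate all external-control genotypes against an internal cohort
#'
#' Partitions the external controls into consecutive blocks of at most n0I
#' subjects, calibrates each block against the internal controls
#' ([calibrate_block()]), and concatenates the results in the original
#' external-subject order. With `p > 0`, one PCA is fitted on the internal
#' genotype matrix and one on the external matrix; external subjects get
#' internal-PC coordinates by projection onto the internal loadings.
#'
#' @param internal An [cohort_data()] cohort with a 0/1 phenotype; its
#'   controls are the calibration reference.
#' @param external A control-only [cohort_data()] cohort over the same
#'   variants.
#' @param K Number of pairing repeats per block (default 10).
#' @param p Number of genotype PCs to include in the calibration model
#'   (default 0; the PC terms need many variants to be meaningful).
#' @param seed Integer seed for the pairing and tie-break draws.
#' @return An `iecat_calibration` object: list with `calibrated` (n0E x V
#'   integer dosage matrix), `report` (tibble: variant_id, block, beta0,
#'   beta1, a0, a1, K), `K`, `p`, `seed`.
#' @examples
#' set.seed(1)
#' internal <- cohort_data(matrix(rbinom(400, 2, 0.3), 200),
#'                         phenotype = rep(0:1, each = 100))
#' external <- cohort_data(matrix(rbinom(600, 2, 0.45), 300))
#' cal <- calibrate_external(internal, external, K = 5, seed = 7)
#' colMeans(cal$calibrated) / 2  # pulled toward the internal-control MAF
#' @export
calibrate_external <- function(internal, external, K = 10, p = 0,
                               seed = NULL) {
  stopifnot(inherits(internal, "iecat_cohort"), inherits(external, "iecat_cohort"))
  if (is.null(internal$phenotype)) {
    abort("internal cohort needs a 0/1 phenotype to identify its controls.")
  }
  ctrl <- internal$phenotype == 0
  if (sum(ctrl) < 2) abort("need at least 2 internal controls.")
  Gint <- internal$genotypes[ctrl, , drop = FALSE]
  XI_int <- XE_ext <- XI_ext <- NULL
  if (p > 0) {
    pca_int <- compute_pcs(internal$genotypes, p)
    pca_ext <- compute_pcs(external$genotypes, p)
    XI_int <- pca_int$scores[ctrl, , drop = FALSE]
    XE_ext <- pca_ext$scores
    XI_ext <- project_pcs(pca_int, external$genotypes)
  }
  res <- with_seed(seed, calibrate_genotype_matrix(
    Gint, external$genotypes, K = K,
    internal_pcs = XI_int, external_pcs = XE_ext,
    internal_pcs_of_external = XI_ext
  ))
  structure(
    list(calibrated = res$calibrated, report = res$report,
         K = K, p = p, seed = seed),
    class = "iecat_calibration"
  )
}

#' @export
print.iecat_calibration <- function(x, ...) {
  cat(sprintf("<iecat_calibration> %d external subjects x %d variants (K = %d, p = %d)\n",
              nrow(x$calibrated), ncol(x$calibrated), x$K, x$p))
  invisible(x)
}

#' @rdname calibrate_external
#' @param x An `iecat_calibration` object.
#' @param ... Unused.
#' @method tidy iecat_calibration
#' @export
tidy.iecat_calibration <- function(x, ...) x$report
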