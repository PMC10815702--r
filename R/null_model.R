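#' Fit the covariate-only logistic null model
#'
#' Maximum-likelihood fit of `logit P(Y=1|Z) = Z alpha` by Newton iteration
#' (iteratively reweighted least squares), with the genotype excluded — the
#' score test evaluates every variant against this single fit, so it is
#' computed once per phenotype/covariate configuration and reused across a
#' scan. Fitted probabilities are clipped to `[1e-12, 1 - 1e-12]` to keep
#' the saddlepoint machinery finite.
#'
#' @param y Binary 0/1 phenotype vector.
#' @param covariates Covariate matrix or data frame (no intercept column;
#'   one is prepended), or `NULL` for an intercept-only model.
#' @param tol Convergence tolerance on the maximum absolute coefficient
#'   change (default 1e-8).
#' @param max_iter Maximum Newton iterations (default 50).
#' @param start Optional starting coefficient vector (warm starts across
#'   phenotype resamples).
#' @return An `iecat_null` object: list with `alpha` (coefficients), `mu`
#'   (fitted probabilities), `v` (weights mu(1-mu)), `Z` (design matrix),
#'   `y`, `zvz_inv` (the (Z'VZ)^-1 projection cache), `converged`,
#'   `iterations`, `n`, `n_case`.
#' @examples
#' y <- rbinom(200, 1, 0.3)
#' z <- rnorm(200)
#' nm <- fit_null_model(y, data.frame(z = z))
#' glance(nm)
#' @export
fit_null_model <- function(y, covariates = NULL, tol = 1e-8, max_iter = 50L,
                           start = NULL) {
  y <- check_binary_phenotype(y)
  n <- length(y)
  if (all(y == 0) || all(y == 1)) {
    abort("both phenotype classes must be present to fit the null model.")
  }
  Z <- if (is.null(covariates)) {
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    cv <- as.matrix(as.data.frame(covariates))
    storage.mode(cv) <- "double"
    if (nrow(cv) != n) abort("covariates must have one row per subject.")
    cbind(`(Intercept)` = 1, cv)
  }
  q <- ncol(Z)
  if (qr(Z)$rank < q) {
    abort("covariate design is rank deficient; drop collinear columns.")
  }
  alpha <- if (is.null(start)) c(qlogis(mean(y)), rep(0, q - 1)) else start
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(Z %*% alpha)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-300)
    delta <- tryCatch(
      solve(crossprod(Z, Z * w), crossprod(Z, y - mu)),
      error = function(e) abort("null-model Newton step failed (separation?).")
    )
    alpha <- alpha + drop(delta)
    if (max(abs(delta)) < tol) {
      converged <- TRUE
      break
    }
  }
  eta <- drop(Z %*% alpha)
  mu <- pmin(pmax(plogis(eta), 1e-12), 1 - 1e-12)
  v <- mu * (1 - mu)
  structure(
    list(
      alpha = setNames(drop(alpha), colnames(Z)),
      mu = mu, v = v, Z = Z, y = y,
      zvz_inv = solve(crossprod(Z, Z * v)),
      converged = converged, iterations = iter,
      n = n, n_case = as.integer(sum(y))
    ),
    class = "iecat_null"
  )
}

#' @export
print.iecat_null <- function(x, ...) {
  cat(sprintf(
    "<iecat_null> n = %d (%d cases), %d coefficients, %sconverged in %d iterations\n",
    x$n, x$n_case, length(x$alpha), if (x$converged) "" else "NOT ", x$iterations))
  invisible(x)
}

#' @rdname fit_null_model
#' @param x An `iecat_null` object.
#' @param ... Unused.
#' @method tidy iecat_null
#' @export
tidy.iecat_null <- function(x, ...) {
  se <- sqrt(diag(x$zvz_inv))
  tibble(
    term = names(x$alpha),
    estimate = unname(x$alpha),
    std.error = se,
    statistic = unname(x$alpha) / se,
    p.value = 2 * pnorm(-abs(unname(x$alpha) / se))
  )
}

#' @rdname fit_null_model
#' @method glance iecat_null
#' @export
glance.iecat_null <- function(x, ...) {
  ll <- sum(x$y * log(x$mu) + (1 - x$y) * log(1 - x$mu))
  tibble(
    n = x$n, n_case = x$n_case, logLik = ll,
    converged = x$converged, iterations = x$iterations
  )
}
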