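# Simulation engine for type-I-error and power evaluation.
#
# Phenotypes follow logit P(Y=1) = a0 + 0.5 Z1 + 0.5 Z2 + beta G + eps with
# Z1 ~ N(0,1), Z2 ~ Bernoulli(0.5), eps ~ N(0,1), G ~ Binomial(2, MAF), and
# a0 solved so the population prevalence hits its target (0.05 by default).
# Batch effects are induced by giving a fraction (the differential variant
# size, DVS) of variants a perturbed external-control MAF: doubled (2q) or
# drawn from Uniform(0.1q, 4q).

#' Simulation configuration
#'
#' The six study models index the internal case:control:external ratio and
#' the batch mechanism: models 1-3 double the external MAF (2q) with ratios
#' 5000:5000:10000, 6667:3333:10000, 500:5000:10000; models 4-6 use the same
#' ratios with external MAF ~ Uniform(0.1q, 4q).
#'
#' @param model Optional preset 1-6 filling `n1I`, `n0I`, `n0E`,
#'   `batch_mechanism`.
#' @param n1I,n0I,n0E Internal cases, internal controls, external controls.
#' @param dvs Differential variant size: proportion of variants whose
#'   external-control MAF is perturbed.
#' @param batch_mechanism `"double"` (external MAF = min(2q, 0.5)) or
#'   `"uniform"` (external MAF ~ Uniform(0.1q, 4q), capped at 0.5).
#' @param beta Log odds ratio of the causal variant (0 for null data).
#' @param prevalence Population disease prevalence anchoring the intercept.
#' @param maf_source Optional numeric vector of empirical MAFs (or a path to
#'   a one-column text file of MAFs) sampled with replacement; `NULL` uses
#'   the built-in exome-like site-frequency-spectrum sampler
#'   (see [sample_maf()]).
#' @param n_variants Number of variants (independent genotype sets).
#' @param n_pheno_resamples Phenotype resamples per genotype set in the
#'   type-I-error harness.
#' @param alpha_levels Significance levels evaluated by the harnesses.
#' @param calibration_K Pairing repeats for the calibrated method.
#' @param intercept_draws Monte-Carlo draws for the prevalence intercept.
#' @param seed Master seed; all randomness derives from it.
#' @return A list of class `iecat_sim_config`.
#' @export
sim_config <- function(model = NULL, n1I = 5000, n0I = 5000, n0E = 10000,
                       dvs = 0.03, batch_mechanism = c("double", "uniform"),
                       beta = 0, prevalence = 0.05, maf_source = NULL,
                       n_variants = 200, n_pheno_resamples = 100,
                       alpha_levels = c(0.05, 0.01, 1e-3, 1e-4),
                       calibration_K = 10, intercept_draws = 1e6, seed = 1) {
  bm_supplied <- !missing(batch_mechanism)
  batch_mechanism <- match.arg(batch_mechanism)
  if (!is.null(model)) {
    stopifnot(model %in% 1:6)
    ratios <- list(c(5000, 5000, 10000), c(6667, 3333, 10000),
                   c(500, 5000, 10000))
    r <- ratios[[(model - 1) %% 3 + 1]]
    # preset fills whatever the caller did not set explicitly
    if (missing(n1I)) n1I <- r[1]
    if (missing(n0I)) n0I <- r[2]
    if (missing(n0E)) n0E <- r[3]
    if (!bm_supplied) {
      batch_mechanism <- if (model <= 3) "double" else "uniform"
    }
  }
  if (dvs < 0 || dvs > 1) abort("dvs must lie in [0, 1].")
  if (prevalence <= 0 || prevalence >= 1) abort("prevalence must lie in (0, 1).")
  structure(
    list(model_id = model, n1I = n1I, n0I = n0I, n0E = n0E, dvs = dvs,
         batch_mechanism = batch_mechanism, beta = beta,
         prevalence = prevalence, maf_source = maf_source,
         n_variants = n_variants, n_pheno_resamples = n_pheno_resamples,
         alpha_levels = alpha_levels, calibration_K = calibration_K,
         intercept_draws = intercept_draws, seed = seed),
    class = "iecat_sim_config"
  )
}

#' Sample per-variant minor allele frequencies
#'
#' The default sampler emulates the site-frequency spectrum of an exome
#' discovery panel of `panel_size` diploids: the folded minor-allele count k
#' is drawn with probability proportional to `k^-sfs_exponent` over
#' 1..panel_size and the MAF is k/(2 panel_size). The default exponent 1.5
#' reproduces the rare-variant excess of exome sequence panels of this size
#' (about 38% singletons). An empirical MAF list can be supplied instead and
#' is sampled with replacement.
#'
#' @param n_variants Number of MAFs to draw.
#' @param maf_source Optional numeric vector of empirical MAFs or path to a
#'   one-column text file.
#' @param sfs_exponent Power-law exponent of the folded spectrum.
#' @param panel_size Emulated discovery-panel size (diploids).
#' @return Numeric vector of MAFs in (0, 0.5]. Uses the current RNG stream.
#' @export
sample_maf <- function(n_variants, maf_source = NULL, sfs_exponent = 1.5,
                       panel_size = 697) {
  if (!is.null(maf_source)) {
    if (is.character(maf_source)) {
      maf_source <- as.numeric(readLines(maf_source))
    }
    maf_source <- maf_source[is.finite(maf_source)]
    if (length(maf_source) == 0) abort("empty MAF list.")
    if (any(maf_source <= 0 | maf_source > 0.5)) {
      abort("empirical MAFs must lie in (0, 0.5].")
    }
    return(sample(maf_source, n_variants, replace = TRUE))
  }
  k <- sample.int(panel_size, n_variants, replace = TRUE,
                  prob = seq_len(panel_size)^(-sfs_exponent))
  k / (2 * panel_size)
}

#' Perturb external-control MAFs to induce a batch effect
#'
#' Selects `round(dvs * length(q))` variants uniformly at random and gives
#' them a perturbed external MAF; all others keep the internal MAF.
#'
#' @param q Internal MAF vector.
#' @param dvs Differential variant size in \[0, 1\].
#' @param mechanism `"double"` or `"uniform"` (see [sim_config()]).
#' @return List with `q_ext` (external MAF vector) and `differential`
#'   (logical flags). Uses the current RNG stream.
#' @export
apply_batch_effect <- function(q, dvs, mechanism = c("double", "uniform")) {
  mechanism <- match.arg(mechanism)
  V <- length(q)
  n_diff <- round(dvs * V)
  flag <- rep(FALSE, V)
  flag[sample.int(V, n_diff)] <- TRUE
  q_ext <- q
  if (n_diff > 0) {
    q_ext[flag] <- if (mechanism == "double") {
      pmin(2 * q[flag], 0.5)
    } else {
      pmin(runif(n_diff, 0.1 * q[flag], 4 * q[flag]), 0.5)
    }
  }
  list(q_ext = q_ext, differential = flag)
}

#' Solve the phenotype-model intercept for a target prevalence
#'
#' Finds a0 such that the population mean of
#' `expit(a0 + 0.5 Z1 + 0.5 Z2 + beta G + eps)` equals the target, by
#' root-finding over a fixed Monte-Carlo sample of the covariate law
#' (common random numbers, so the solve is smooth and deterministic given
#' the seed).
#'
#' @param prevalence Target disease prevalence in (0, 1).
#' @param beta Genotype log odds ratio.
#' @param q Causal-variant MAF (only used when `beta != 0`).
#' @param n_draws Monte-Carlo sample size.
#' @param z1_sd,z2_prob,eps_sd Covariate-law parameters; setting all of
#'   them to 0 recovers the closed form `qlogis(prevalence)`.
#' @param seed Optional seed.
#' @return The intercept a0 (scalar).
#' @export
solve_intercept <- function(prevalence, beta = 0, q = 0.1, n_draws = 1e6,
                            z1_sd = 1, z2_prob = 0.5, eps_sd = 1,
                            seed = NULL) {
  if (prevalence <= 0 || prevalence >= 1) abort("prevalence must lie in (0, 1).")
  with_seed(seed, {
    lp <- 0.5 * rnorm(n_draws, sd = z1_sd) +
      0.5 * rbinom(n_draws, 1, z2_prob) +
      rnorm(n_draws, sd = eps_sd)
    if (beta != 0) lp <- lp + beta * rbinom(n_draws, 2, q)
    uniroot(function(a0) mean(plogis(a0 + lp)) - prevalence,
            lower = qlogis(prevalence) - 20, upper = qlogis(prevalence) + 20,
            tol = 1e-8)$root
  })
}

# Accrue ascertained subjects by chunked rejection sampling.
# Returns data frame columns z1, z2, eps, g (g only when maf is given), y.
accrue_subjects <- function(n_case, n_ctrl, alpha0, beta = 0, maf = NULL,
                            budget_factor = 50) {
  prev_guess <- plogis(alpha0)  # order of magnitude only, for chunk sizing
  expected <- n_case / max(prev_guess, 1e-3) + n_ctrl / max(1 - prev_guess, 1e-3)
  budget <- ceiling(budget_factor * (expected + 1))
  drawn <- 0
  cases <- list(); ctrls <- list()
  got_case <- 0; got_ctrl <- 0
  chunk <- min(max(2e4, ceiling(expected / 4)), 5e5)
  while ((got_case < n_case || got_ctrl < n_ctrl) && drawn < budget) {
    z1 <- rnorm(chunk); z2 <- rbinom(chunk, 1, 0.5); eps <- rnorm(chunk)
    lp <- alpha0 + 0.5 * z1 + 0.5 * z2 + eps
    g <- NULL
    if (!is.null(maf) && beta != 0) {
      g <- rbinom(chunk, 2, maf)
      lp <- lp + beta * g
    }
    y <- rbinom(chunk, 1, plogis(lp))
    df <- data.frame(z1 = z1, z2 = z2, eps = eps, y = y)
    if (!is.null(g)) df$g <- g
    if (got_case < n_case) {
      take <- df[df$y == 1, , drop = FALSE]
      take <- head(take, n_case - got_case)
      cases[[length(cases) + 1]] <- take
      got_case <- got_case + nrow(take)
    }
    if (got_ctrl < n_ctrl) {
      take <- df[df$y == 0, , drop = FALSE]
      take <- head(take, n_ctrl - got_ctrl)
      ctrls[[length(ctrls) + 1]] <- take
      got_ctrl <- got_ctrl + nrow(take)
    }
    drawn <- drawn + chunk
  }
  if (got_case < n_case || got_ctrl < n_ctrl) {
    abort(sprintf(
      "could not accrue the requested sample within the draw budget (short %d cases, %d controls).",
      n_case - got_case, n_ctrl - got_ctrl))
  }
  rbind(do.call(rbind, cases), do.call(rbind, ctrls))
}

#' Generate one simulated case-control dataset with external controls
#'
#' Simulates the internal cohort (n1I ascertained cases, n0I controls) and
#' the external control cohort (n0E controls drawn from a population whose
#' differential variants carry the perturbed MAF). Under `beta = 0`,
#' genotypes are independent of phenotype and all `n_variants` variants
#' share the subject panel; under `beta != 0` the dataset carries a single
#' causal variant (`n_variants` must be 1) drawn jointly with the phenotype.
#'
#' @param config An [sim_config()].
#' @return A list of class `iecat_sim_dataset`: `internal` and `external`
#'   [cohort_data()] cohorts (covariates z1, z2), `truth` (tibble:
#'   variant_id, q, q_ext, differential, beta), `alpha0`, `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "iecat_sim_config"))
  if (config$beta != 0 && config$n_variants != 1) {
    abort("datasets with a genotype effect carry a single (causal) variant.")
  }
  with_seed(config$seed, {
    q <- sample_maf(config$n_variants, config$maf_source)
    be <- apply_batch_effect(q, config$dvs, config$batch_mechanism)
    alpha0 <- solve_intercept(config$prevalence, config$beta, q[1],
                              n_draws = config$intercept_draws)
    vids <- sprintf("v%04d", seq_len(config$n_variants))

    int <- accrue_subjects(config$n1I, config$n0I, alpha0, config$beta,
                           maf = if (config$beta != 0) q[1])
    nI <- nrow(int)
    G_int <- if (config$beta != 0) {
      matrix(int$g, ncol = 1)
    } else {
      matrix(rbinom(nI * config$n_variants, 2, rep(q, each = nI)), nrow = nI)
    }
    colnames(G_int) <- vids

    ext <- accrue_subjects(0, config$n0E, alpha0, config$beta,
                           maf = if (config$beta != 0) be$q_ext[1])
    G_ext <- if (config$beta != 0) {
      matrix(ext$g, ncol = 1)
    } else {
      matrix(rbinom(config$n0E * config$n_variants, 2,
                    rep(be$q_ext, each = config$n0E)), nrow = config$n0E)
    }
    colnames(G_ext) <- vids

    structure(
      list(
        internal = cohort_data(G_int, phenotype = int$y,
                               covariates = int[, c("z1", "z2")]),
        external = cohort_data(G_ext,
                               covariates = ext[, c("z1", "z2")]),
        truth = tibble(variant_id = vids, q = q, q_ext = be$q_ext,
                       differential = be$differential, beta = config$beta),
        alpha0 = alpha0, config = config
      ),
      class = "iecat_sim_dataset"
    )
  })
}

# Redraw internal phenotypes from the null law: covariates fixed, eps
# redrawn, intercept re-solved so the expected case count matches the
# ascertained design (case-control sampling shifts only the logistic
# intercept, so this is the retrospective null law of the design).
resample_null_phenotypes <- function(lp_fixed, n_case_target) {
  n <- length(lp_fixed)
  lp <- lp_fixed + rnorm(n)
  f <- function(a0) mean(plogis(a0 + lp)) - n_case_target / n
  a0 <- uniroot(f, lower = -40, upper = 40, tol = 1e-10)$root
  rbinom(n, 1, plogis(a0 + lp))
}

#' Empirical type-I-error experiment
#'
#' Generates `n_variants` null genotype sets on a shared subject panel,
#' resamples the internal phenotypes `n_pheno_resamples` times (covariates
#' and genotypes fixed, noise redrawn, intercept re-solved to preserve the
#' ascertained case:control design), runs each analysis strategy on every
#' replicate, and tabulates rejection fractions at each significance level,
#' pooled and stratified by the differential-variant flag. The calibrated
#' method's external genotypes are calibrated once per genotype set, against
#' the ascertained control labels, and held fixed across resamples along
#' with the rest of the non-phenotype data.
#'
#' @param config An [sim_config()] with `beta = 0`.
#' @param methods Subset of `c("rc", "naive", "internal")`.
#' @param alpha_levels Significance levels (default from config).
#' @param dispatch A [dispatch_config()].
#' @param progress Print a line every 20 resamples.
#' @return An object of class `iecat_typei`: list with `rates` (tibble:
#'   method, alpha, stratum, n_reps, rejections, rate, mc_se),
#'   `per_variant` (per-variant rejection rates at each alpha), `routes`
#'   (route usage counts per method), `truth`, `config`.
#' @export
type1_error_experiment <- function(config, methods = c("rc", "naive", "internal"),
                                   alpha_levels = NULL,
                                   dispatch = dispatch_config(),
                                   progress = FALSE) {
  stopifnot(inherits(config, "iecat_sim_config"))
  if (config$beta != 0) abort("type-I-error evaluation requires beta = 0.")
  methods <- match.arg(methods, c("rc", "naive", "internal"), several.ok = TRUE)
  alpha_levels <- alpha_levels %||% config$alpha_levels
  ds <- generate_dataset(config)
  seeds <- derive_seeds(config$seed + 1L, 2L)
  V <- config$n_variants
  R <- config$n_pheno_resamples
  A <- length(alpha_levels)

  G_int <- ds$internal$genotypes
  G_ext <- ds$external$genotypes
  Z_int <- as.matrix(ds$internal$covariates)
  Z_comb <- rbind(Z_int, as.matrix(ds$external$covariates))
  G_naive <- rbind(G_int, G_ext)
  lp_fixed <- 0.5 * Z_int[, "z1"] + 0.5 * Z_int[, "z2"]
  nI <- nrow(G_int)
  # Calibration belongs to the fixed data of a genotype set: it is computed
  # once from the ascertained control labels and held fixed while phenotypes
  # are resampled. (Per-resample recalibration would tie the calibrated
  # genotypes to the current phenotype vector and invalidate the
  # conditional-on-genotypes null law of the score test.)
  G_rc <- if ("rc" %in% methods) {
    cal <- with_seed(seeds[2], calibrate_genotype_matrix(
      G_int[ds$internal$phenotype == 0, , drop = FALSE], G_ext,
      K = config$calibration_K))
    rbind(G_int, cal$calibrated)
  }

  rej <- array(0L, dim = c(length(methods), A, V),
               dimnames = list(methods, NULL, NULL))
  route_counts <- list()
  warm_int <- warm_comb <- NULL

  with_seed(seeds[1], {
    for (r in seq_len(R)) {
      y <- resample_null_phenotypes(lp_fixed, config$n1I)
      null_int <- if ("internal" %in% methods) {
        fit_null_model(y, Z_int, start = warm_int)
      }
      null_comb <- if (any(c("rc", "naive") %in% methods)) {
        fit_null_model(c(y, rep(0, config$n0E)), Z_comb, start = warm_comb)
      }
      if (!is.null(null_int)) warm_int <- null_int$alpha
      if (!is.null(null_comb)) warm_comb <- null_comb$alpha

      for (mi in seq_along(methods)) {
        m <- methods[mi]
        res <- switch(m,
          internal = pvalues_for_matrix(G_int, null_int, dispatch, FALSE),
          naive = pvalues_for_matrix(G_naive, null_comb, dispatch, TRUE),
          rc = pvalues_for_matrix(G_rc, null_comb, dispatch, TRUE)
        )
        for (ai in seq_len(A)) {
          rej[mi, ai, ] <- rej[mi, ai, ] + (res$p_value < alpha_levels[ai])
        }
        rt <- table(res$route)
        route_counts[[m]] <- if (is.null(route_counts[[m]])) rt else {
          all_r <- union(names(route_counts[[m]]), names(rt))
          acc <- setNames(numeric(length(all_r)), all_r)
          acc[names(route_counts[[m]])] <- route_counts[[m]]
          acc[names(rt)] <- acc[names(rt)] + rt
          acc
        }
      }
      if (progress && r %% 20 == 0) {
        message(sprintf("resample %d / %d", r, R))
      }
    }
  })

  strata <- list(pooled = rep(TRUE, V),
                 differential = ds$truth$differential,
                 non_differential = !ds$truth$differential)
  rates <- bind_rows(lapply(seq_along(methods), function(mi) {
    bind_rows(lapply(seq_len(A), function(ai) {
      bind_rows(lapply(names(strata), function(sn) {
        sel <- strata[[sn]]
        nrep <- R * sum(sel)
        k <- sum(rej[mi, ai, sel])
        rate <- if (nrep > 0) k / nrep else NA_real_
        tibble(method = methods[mi], alpha = alpha_levels[ai], stratum = sn,
               n_reps = nrep, rejections = k, rate = rate,
               mc_se = if (nrep > 0) sqrt(rate * (1 - rate) / nrep) else NA_real_)
      }))
    }))
  }))
  per_variant <- bind_rows(lapply(seq_along(methods), function(mi) {
    bind_rows(lapply(seq_len(A), function(ai) {
      tibble(method = methods[mi], alpha = alpha_levels[ai],
             variant_id = ds$truth$variant_id, q = ds$truth$q,
             differential = ds$truth$differential,
             rate = rej[mi, ai, ] / R)
    }))
  }))
  routes <- bind_rows(lapply(names(route_counts), function(m) {
    tibble(method = m, route = names(route_counts[[m]]),
           n = as.numeric(route_counts[[m]]))
  }))
  structure(
    list(rates = rates, per_variant = per_variant, routes = routes,
         truth = ds$truth, config = config),
    class = "iecat_typei"
  )
}

#' @export
print.iecat_typei <- function(x, ...) {
  cat("<iecat_typei> rejection rates (pooled):\n")
  print(as.data.frame(filter(x$rates, .data$stratum == "pooled")))
  invisible(x)
}

#' @rdname type1_error_experiment
#' @param x An `iecat_typei` object.
#' @param ... Unused.
#' @method tidy iecat_typei
#' @export
tidy.iecat_typei <- function(x, ...) x$rates

#' @method autoplot iecat_typei
#' @export
autoplot.iecat_typei <- function(object, alpha = NULL, ...) {
  d <- object$rates
  if (!is.null(alpha)) d <- filter(d, .data$alpha %in% !!alpha)
  ggplot(d, aes(x = .data$stratum, y = .data$rate, fill = .data$method)) +
    geom_col(position = position_dodge()) +
    geom_hline(aes(yintercept = .data$alpha), linetype = 2) +
    facet_wrap(~alpha, scales = "free_y") +
    labs(x = NULL, y = "empirical type-I error",
         title = "Type-I error by method and variant stratum") +
    theme_minimal()
}

#' Empirical power experiment
#'
#' Generates an independent single-variant dataset per replicate under the
#' configured genotype effect and reports the per-method rejection fraction
#' at the given significance level.
#'
#' @param config An [sim_config()] with `beta > 0` and `n_variants = 1`.
#' @param methods Subset of `c("rc", "naive", "internal")`.
#' @param alpha Significance level.
#' @param n_replicates Number of independent datasets.
#' @param dispatch A [dispatch_config()].
#' @return A tibble of class `iecat_power`: method, beta, alpha,
#'   n_replicates, rejections, power, mc_se.
#' @export
power_experiment <- function(config, methods = c("rc", "internal"),
                             alpha = 5e-8, n_replicates = 500,
                             dispatch = dispatch_config()) {
  stopifnot(inherits(config, "iecat_sim_config"))
  if (config$beta <= 0) {
    abort("power evaluation requires beta > 0 (use type1_error_experiment for the null).")
  }
  methods <- match.arg(methods, c("rc", "naive", "internal"), several.ok = TRUE)
  seeds <- derive_seeds(config$seed, n_replicates + 1L)
  rej <- setNames(numeric(length(methods)), methods)
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$n_variants <- 1L
    cfg$seed <- seeds[r]
    ds <- generate_dataset(cfg)
    cal_seed <- seeds[n_replicates + 1L] + r
    for (m in methods) {
      res <- iecat_scan(ds$internal, ds$external,
                        method = m, K = config$calibration_K,
                        dispatch = dispatch, seed = cal_seed)
      rej[m] <- rej[m] + (res$p_value[1] < alpha)
    }
  }
  out <- tibble(
    method = methods, beta = config$beta, alpha = alpha,
    n_replicates = n_replicates, rejections = as.numeric(rej),
    power = as.numeric(rej) / n_replicates,
    mc_se = sqrt(pmax(rej / n_replicates * (1 - rej / n_replicates), 0) / n_replicates)
  )
  class(out) <- c("iecat_power", class(out))
  out
}

#' @method autoplot iecat_power
#' @export
autoplot.iecat_power <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = factor(exp(.data$beta)), y = .data$power,
             group = .data$method, colour = .data$method)) +
    geom_point() + geom_line() +
    labs(x = "odds ratio", y = "empirical power") +
    theme_minimal()
}
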