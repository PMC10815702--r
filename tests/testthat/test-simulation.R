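test_that("model presets fix the design ratios and batch mechanisms", {
  c1 <- sim_config(model = 1)
  expect_identical(c(c1$n1I, c1$n0I, c1$n0E), c(5000, 5000, 10000))
  expect_identical(c1$batch_mechanism, "double")
  c2 <- sim_config(model = 2)
  expect_identical(c(c2$n1I, c2$n0I), c(6667, 3333))
  c6 <- sim_config(model = 6)
  expect_identical(c(c6$n1I, c6$n0I, c6$n0E), c(500, 5000, 10000))
  expect_identical(c6$batch_mechanism, "uniform")
  # explicit sizes win over the preset (scaled-down runs)
  cs <- sim_config(model = 1, n1I = 100, n0I = 100, n0E = 200)
  expect_identical(c(cs$n1I, cs$n0I, cs$n0E), c(100, 100, 200))
})

test_that("the MAF sampler has the right support and an exome-like rare excess", {
  withr::with_seed(1, q <- sample_maf(1e4))
  expect_true(all(q > 0 & q <= 0.5))
  expect_gt(mean(q < 0.05), 0.5)     # rare fraction dominates
  expect_gt(mean(q < 0.002), 0.3)    # heavy singleton/doubleton mass
  # empirical list: sampled with replacement, fixed value passes through
  withr::with_seed(2, q1 <- sample_maf(50, maf_source = 0.1))
  expect_true(all(q1 == 0.1))
  expect_error(sample_maf(10, maf_source = numeric(0)), "empty")
  # determinism
  a <- withr::with_seed(3, sample_maf(100))
  b <- withr::with_seed(3, sample_maf(100))
  expect_identical(a, b)
})

test_that("batch effects perturb exactly the DVS fraction", {
  q <- rep(0.1, 10)
  withr::with_seed(4, {
    none <- apply_batch_effect(q, dvs = 0, mechanism = "double")
    all2q <- apply_batch_effect(q, dvs = 1, mechanism = "double")
    half <- apply_batch_effect(q, dvs = 0.5, mechanism = "uniform")
  })
  expect_identical(none$q_ext, q)
  expect_identical(sum(none$differential), 0L)
  expect_true(all(all2q$q_ext == 0.2))
  expect_identical(sum(half$differential), 5L)
  expect_true(all(half$q_ext[half$differential] >= 0.1 * 0.1 - 1e-12))
  expect_true(all(half$q_ext <= 0.5))
  # doubling caps at 0.5
  withr::with_seed(5, capped <- apply_batch_effect(rep(0.4, 5), 1, "double"))
  expect_true(all(capped$q_ext == 0.5))
})

test_that("the prevalence intercept solves the anchoring equation", {
  # all covariate and noise terms off: closed form logit(prevalence)
  a0 <- solve_intercept(0.05, z1_sd = 0, z2_prob = 0, eps_sd = 0,
                        n_draws = 10, seed = 1)
  expect_equal(a0, qlogis(0.05), tolerance = 1e-6)
  # symmetric law at prevalence 0.5: intercept 0
  a0_sym <- solve_intercept(0.5, z2_prob = 0, n_draws = 5e5, seed = 2)
  expect_lt(abs(a0_sym), 0.01)
  # Monte-Carlo self-check on a fresh sample under the full law
  a0_full <- solve_intercept(0.05, n_draws = 1e6, seed = 3)
  withr::with_seed(4, {
    lp <- 0.5 * rnorm(1e6) + 0.5 * rbinom(1e6, 1, 0.5) + rnorm(1e6)
    prev <- mean(rbinom(1e6, 1, plogis(a0_full + lp)))
  })
  expect_gt(prev, 0.048)
  expect_lt(prev, 0.052)
})

test_that("generated datasets respect the design and the genotype laws", {
  cfg <- sim_config(model = 1, n1I = 400, n0I = 400, n0E = 800,
                    n_variants = 30, dvs = 0, seed = 6,
                    maf_source = c(0.2, 0.35), intercept_draws = 2e5)
  ds <- generate_dataset(cfg)
  expect_identical(ds$internal$n_case, 400L)
  expect_identical(ds$internal$n_control, 400L)
  expect_identical(ds$external$n, 800L)
  expect_identical(nrow(ds$truth), 30L)
  expect_true(all(ds$truth$q_ext == ds$truth$q))
  # sample MAF within 4 binomial SEs of the generating q, cohort by cohort
  for (v in c(1, 15, 30)) {
    q <- ds$truth$q[v]
    for (gmat in list(ds$internal$genotypes, ds$external$genotypes)) {
      n2 <- 2 * nrow(gmat)
      se <- sqrt(q * (1 - q) / n2)
      expect_lt(abs(mean(gmat[, v]) / 2 - q), 4 * se + 1e-12)
    }
  }
  # covariate law not distorted in controls under beta = 0
  z1_ctrl <- ds$internal$covariates$z1[ds$internal$phenotype == 0]
  expect_lt(abs(mean(z1_ctrl)), 3 / sqrt(length(z1_ctrl)) + 0.05)
})

test_that("a positive genotype effect enriches cases for the risk allele", {
  cfg <- sim_config(n1I = 500, n0I = 500, n0E = 500, n_variants = 1,
                    beta = log(2), maf_source = 0.3, seed = 7,
                    intercept_draws = 2e5)
  ds <- generate_dataset(cfg)
  g <- ds$internal$genotypes[, 1]
  y <- ds$internal$phenotype
  tt <- t.test(g[y == 1], g[y == 0], alternative = "greater")
  expect_lt(tt$p.value, 0.01)
  # multi-variant datasets with an effect are refused
  cfg_bad <- sim_config(beta = log(2), n_variants = 5)
  expect_error(generate_dataset(cfg_bad), "single")
})

test_that("an impossible accrual budget fails with the shortfall", {
  withr::with_seed(8, {
    expect_error(
      iecatrc:::accrue_subjects(1000, 0, qlogis(1e-6), budget_factor = 1e-4),
      "accrue.*short"
    )
  })
})

test_that("phenotype resampling preserves the ascertained case fraction", {
  withr::with_seed(9, {
    lp <- 0.5 * rnorm(2000) + 0.5 * rbinom(2000, 1, 0.5)
    ys <- replicate(200, sum(iecatrc:::resample_null_phenotypes(lp, 1000)))
  })
  expect_lt(abs(mean(ys) - 1000), 3 * sd(ys) / sqrt(200))
  expect_gt(sd(ys), 0)  # genuinely random, not conditioned exactly
})

test_that("the type-I harness is deterministic and accounts its strata", {
  cfg <- sim_config(model = 1, n1I = 150, n0I = 150, n0E = 300,
                    n_variants = 12, n_pheno_resamples = 4, dvs = 0.5,
                    seed = 10, intercept_draws = 1e5)
  a <- type1_error_experiment(cfg)
  b <- type1_error_experiment(cfg)
  expect_equal(a$rates, b$rates)
  expect_equal(a$per_variant, b$per_variant)
  pooled <- dplyr::filter(a$rates, stratum == "pooled", alpha == 0.05)
  expect_true(all(pooled$n_reps == 12 * 4))
  diff_n <- dplyr::filter(a$rates, stratum == "differential", alpha == 0.05)
  expect_true(all(diff_n$n_reps == 6 * 4))
  # rates consistent with per-variant tabulation
  pv <- dplyr::filter(a$per_variant, method == "naive", alpha == 0.05)
  expect_equal(mean(pv$rate),
               dplyr::filter(pooled, method == "naive")$rate,
               tolerance = 1e-12)
  expect_s3_class(autoplot(a, alpha = 0.05), "ggplot")
  expect_identical(tidy(a), a$rates)
})

test_that("zero variants yield an empty table without error", {
  cfg <- sim_config(n1I = 60, n0I = 60, n0E = 120, n_variants = 0,
                    n_pheno_resamples = 2, seed = 11, intercept_draws = 1e4)
  ex <- type1_error_experiment(cfg, methods = "internal")
  expect_identical(nrow(ex$per_variant), 0L)
  expect_true(all(ex$rates$n_reps == 0))
})

test_that("the power harness refuses null configurations and orders effects", {
  expect_error(power_experiment(sim_config(beta = 0)), "beta > 0")
  pow <- function(b, seed) {
    cfg <- sim_config(n1I = 150, n0I = 150, n0E = 300, beta = b,
                      n_variants = 1, maf_source = 0.25, seed = seed,
                      intercept_draws = 1e5, calibration_K = 3)
    power_experiment(cfg, methods = c("rc", "internal"), alpha = 0.05,
                     n_replicates = 60)
  }
  p_lo <- pow(log(1.4), 12)
  p_hi <- pow(log(3.2), 12)
  for (m in c("rc", "internal")) {
    lo <- dplyr::filter(p_lo, method == m)
    hi <- dplyr::filter(p_hi, method == m)
    expect_gte(hi$power, lo$power - 2 * (lo$mc_se + hi$mc_se))
  }
  expect_s3_class(autoplot(dplyr::bind_rows(p_lo, p_hi)), "ggplot")
})
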