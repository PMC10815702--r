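test_that("a single repeat recovers closed-form regressions", {
  # identity pairing of x on x: intercept 0, slope 1
  g <- c(0, 1, 2, 1, 0, 2, 1, 1)
  cf <- fit_calibration_repeat(g, g, pairing = list(int = 1:8, ext = 1:8))
  expect_equal(unname(cf[1:2]), c(0, 1), tolerance = 1e-12)

  # constant response: slope 0, intercept c
  cf2 <- fit_calibration_repeat(rep(1, 8), g,
                                pairing = list(int = 1:8, ext = 1:8),
                                on_singular = "zero")
  expect_equal(unname(cf2[1:2]), c(1, 0), tolerance = 1e-12)

  # six paired observations vs an independent normal-equations solve
  G <- c(0, 1, 1, 2, 1, 2)
  g6 <- c(0, 0, 1, 1, 2, 2)
  cf3 <- fit_calibration_repeat(G, g6, pairing = list(int = 1:6, ext = 1:6))
  expect_equal(unname(cf3[1:2]), ols_oracle(g6, G), tolerance = 1e-10)
})

test_that("rank-deficient designs error under 'error' and degrade under 'zero'", {
  G <- c(0, 1, 2, 1)
  g_const <- rep(1, 4)
  expect_error(
    fit_calibration_repeat(G, g_const, pairing = list(int = 1:4, ext = 1:4),
                           variant_id = "rs42"),
    "rs42.*singular"
  )
  cf <- fit_calibration_repeat(G, g_const, pairing = list(int = 1:4, ext = 1:4),
                               on_singular = "zero")
  expect_equal(unname(cf[2]), 0)
  expect_equal(unname(cf[1]), mean(G))
})

test_that("external pool smaller than the internal controls is rejected", {
  expect_error(fit_calibration_repeat(c(0, 1, 2), c(0, 1)), "smaller")
})

test_that("discretization follows the frequency-matching quantile rule", {
  withr::with_seed(1, {
    dz <- discretize_by_internal_frequency(
      c(0.1, 0.2, 0.3, 0.4), c(0, 0, 1, 2)  # internal freqs (.5, .25, .25)
    )
  })
  expect_identical(dz$discrete, c(0L, 0L, 1L, 2L))
  expect_lte(dz$a0, dz$a1)

  # all-zero internal controls: every calibrated genotype is 0
  withr::with_seed(1, {
    dz0 <- discretize_by_internal_frequency(rnorm(10), rep(0, 6))
  })
  expect_identical(dz0$discrete, rep(0L, 10))

  # already-discrete predictions with matching frequencies are preserved
  withr::with_seed(1, {
    preds <- c(0, 0, 1, 2)
    dz2 <- discretize_by_internal_frequency(preds, c(0, 0, 1, 2))
  })
  expect_identical(as.numeric(dz2$discrete), preds)
})

test_that("discretization matches frequencies to 1/m and is monotone", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      m <- sample(20:200, 1)
      internal <- rbinom(150, 2, runif(1, 0.05, 0.5))
      preds <- rnorm(m)  # distinct almost surely
      dz <- discretize_by_internal_frequency(preds, internal)
    })
    expect_lte(abs(mean(dz$discrete == 0) - mean(internal == 0)), 1 / m)
    expect_lte(abs(mean(dz$discrete <= 1) - mean(internal <= 1)), 1 / m)
    # monotone step function of the prediction when predictions are distinct
    expect_true(all(diff(dz$discrete[order(preds)]) >= 0))
  }
})

test_that("heavily tied predictions still match internal frequencies", {
  # three-level predictions (the p = 0 case) with a strong batch effect
  withr::with_seed(9, {
    internal <- rbinom(500, 2, 0.1)
    preds <- 0.4 + 0.05 * rbinom(400, 2, 0.35)  # only 3 distinct values
    dz <- discretize_by_internal_frequency(preds, internal)
  })
  expect_lte(abs(mean(dz$discrete == 0) - mean(internal == 0)), 1 / 400)
  expect_lte(abs(mean(dz$discrete <= 1) - mean(internal <= 1)), 1 / 400)
})

test_that("calibrate_block averages repeats and is seed-reproducible", {
  withr::with_seed(3, {
    G <- rbinom(50, 2, 0.3)
    g <- rbinom(80, 2, 0.45)
  })
  run <- function() {
    withr::with_seed(11, calibrate_block(G, g, K = 3))
  }
  a <- run()
  b <- run()
  expect_identical(a, b)  # bit-reproducible under the same seed
  expect_identical(a$K, 3L)
  expect_true(all(a$discrete %in% 0:2))
  expect_length(a$discrete, 80)
  # frequency match within rounding
  expect_lte(abs(mean(a$discrete == 0) - mean(G == 0)), 1 / 80)
})

test_that("identical genotype distributions calibrate to identical frequencies", {
  withr::with_seed(5, {
    G <- rbinom(120, 2, 0.25)
    cb <- calibrate_block(G, G, K = 1)
  })
  expect_equal(mean(cb$discrete == 0), mean(G == 0), tolerance = 1 / 120)
  expect_equal(mean(cb$discrete == 1), mean(G == 1), tolerance = 2 / 120)
})

test_that("calibrate_external partitions blocks and covers every subject once", {
  ch <- make_cohorts(n_int = 100, n_ext = 100, V = 3)
  # n0I = 50 controls; n0E = 100 -> two full blocks
  cal <- calibrate_external(ch$internal, ch$external, K = 2, seed = 7)
  expect_identical(dim(cal$calibrated), dim(ch$external$genotypes))
  expect_identical(sort(unique(cal$report$block)), c(1L, 2L))

  # ragged case: n0E = n0I + 3 gives a partial final block
  ch2 <- make_cohorts(n_int = 100, n_ext = 53, V = 2)
  cal2 <- calibrate_external(ch2$internal, ch2$external, K = 2, seed = 7)
  expect_identical(nrow(cal2$calibrated), 53L)
  expect_true(all(cal2$calibrated %in% 0:2))
  expect_identical(max(cal2$report$block), 2L)

  # determinism: same seed, same everything
  cal3 <- calibrate_external(ch2$internal, ch2$external, K = 2, seed = 7)
  expect_identical(cal2$calibrated, cal3$calibrated)
  expect_identical(cal2$report, cal3$report)
  # tidy() returns the per-variant report
  expect_identical(tidy(cal2), cal2$report)
})

test_that("vectorized engine agrees exactly with the per-block reference path", {
  withr::with_seed(21, {
    Gint <- matrix(rbinom(60 * 2, 2, 0.3), 60)
    Gext <- matrix(rbinom(90 * 2, 2, 0.4), 90)
  })
  K <- 3
  fast <- withr::with_seed(5, iecatrc:::calibrate_genotype_matrix(Gint, Gext, K = K))
  slow <- withr::with_seed(5, {
    blocks <- iecatrc:::block_partition(90, 60)
    pairings <- lapply(blocks, function(b) {
      replicate(K, draw_pairing(60, length(b)), simplify = FALSE)
    })
    out <- matrix(0L, 90, 2)
    for (v in 1:2) {
      for (bi in seq_along(blocks)) {
        b <- blocks[[bi]]
        cb <- calibrate_block(Gint[, v], Gext[b, v], K = K,
                              pairings = pairings[[bi]])
        out[b, v] <- cb$discrete
      }
    }
    out
  })
  expect_identical(unname(fast$calibrated), slow)
})

test_that("calibration with PCs runs and keeps the frequency match", {
  ch <- make_cohorts(n_int = 120, n_ext = 80, V = 12)
  cal <- calibrate_external(ch$internal, ch$external, K = 2, p = 2, seed = 3)
  ctrl <- ch$internal$genotypes[ch$internal$phenotype == 0, ]
  for (v in c(1, 5)) {
    expect_lte(abs(mean(cal$calibrated[, v] == 0) - mean(ctrl[, v] == 0)),
               1 / nrow(cal$calibrated) + 1e-9)
  }
})

test_that("null-consistency: no batch effect leaves frequencies unchanged at scale", {
  ch <- make_cohorts(n_int = 5000, n_ext = 5000, V = 2, maf_int = 0.3,
                     maf_ext = 0.3, seed = 33)
  cal <- calibrate_external(ch$internal, ch$external, K = 5, seed = 1)
  for (v in 1:2) {
    f_cal <- mean(cal$calibrated[, v]) / 2
    expect_lt(abs(f_cal - 0.3), 0.02)
  }
})

test_that("calibration pulls a batch-shifted external cohort onto the internal law", {
  ch <- make_cohorts(n_int = 2000, n_ext = 2000, V = 2, maf_int = 0.2,
                     maf_ext = 0.4, seed = 13)
  cal <- calibrate_external(ch$internal, ch$external, K = 5, seed = 2)
  ctrl <- ch$internal$genotypes[ch$internal$phenotype == 0, ]
  for (v in 1:2) {
    raw_gap <- abs(mean(ch$external$genotypes[, v]) - mean(ctrl[, v]))
    cal_gap <- abs(mean(cal$calibrated[, v]) - mean(ctrl[, v]))
    expect_lt(cal_gap, raw_gap / 5)
  }
})
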