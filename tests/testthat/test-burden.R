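test_that("competition fitness is the log2-frequency slope per generation", {
  const <- competition_series(0:4, rep(0.4, 5))
  expect_equal(fitness_from_competition(const)$fitness, 0)
  exact <- simulate_competition(fitness = 0.02, noise_sd = 0, seed = 1)
  expect_equal(fitness_from_competition(exact)$fitness, 0.02,
               tolerance = 1e-10)
  # WT frequency doubling over 10 generations: slope 0.1 per generation
  dbl <- competition_series(c(0, 5, 10), c(0.2, 0.2 * sqrt(2), 0.4))
  expect_equal(fitness_from_competition(dbl)$fitness, 0.1, tolerance = 1e-10)
  expect_equal(fitness_from_competition(dbl)$fitness_ln, 0.1 * log(2))
  expect_error(competition_series(0:3, c(0.5, 0.4, 0.2, 0)), "strictly")
})

test_that("competition fitness matches the closed-form OLS oracle", {
  withr::with_seed(55, {
    for (i in 1:10) {
      cs <- simulate_competition(fitness = runif(1, -0.05, 0.05),
                                 noise_sd = 0.03, seed = sample.int(1e6, 1))
      expect_equal(fitness_from_competition(cs)$fitness,
                   unname(ols_oracle(cs$generations,
                                     log2(cs$wt_frequency))["slope"]),
                   tolerance = 1e-10)
    }
  })
})

test_that("per-copy cost is the fitness-vs-copies slope", {
  expect_equal(per_copy_cost(c(0, 8), c(0, 0.16))$cost_per_copy, 0.02,
               tolerance = 1e-12)
  expect_equal(per_copy_cost(c(0, 2, 5), rep(0.03, 3))$cost_per_copy, 0,
               tolerance = 1e-12)
  expect_error(per_copy_cost(c(3, 3), c(0.1, 0.2)), "distinct")
  withr::with_seed(66, {
    cp <- c(0, 1, 2, 4, 8)
    for (i in 1:10) {
      fit <- 0.015 * cp + rnorm(5, 0, 0.004)
      est <- per_copy_cost(cp, fit)
      expect_equal(est$cost_per_copy, unname(ols_oracle(cp, fit)["slope"]),
                   tolerance = 1e-10)
      expect_lt(abs(est$cost_per_copy - 0.015), 4 * est$se)
    }
  })
})

test_that("mCherry calibration converts the TDH3 reference to copy fractions", {
  one <- mcherry_calibration(0.022, 0.145, 1)
  expect_equal(one, 0.022 * 0.855, tolerance = 1e-12)
  expect_equal(round(100 * one, 1), 1.9)
  expect_equal(mcherry_calibration(0.022, 0, 1), 0.022)
  expect_equal(mcherry_calibration(0.022, 0.145, 0), 0)
  expect_equal(mcherry_calibration(0.022, 0.145, 8), 8 * one)
  expect_equal(mcherry_calibration(0.022, 0.145, relative_levels = c(1, 3.5)),
               one * c(1, 3.5))
  expect_error(mcherry_calibration(0.5, 0, 3), "reaches 1")
})

# strains sharing the wild-type slope with copy-linear intercepts; noise at
# the per-condition precision of replicate-median MS fractions
make_burden_strains <- function(seed, noise_sd = 0.0015,
                                copies = c(0, 2, 4, 8),
                                s = 0.35, r0_wt = 0.081, r0_hi = 0.055) {
  withr::with_seed(seed, {
    per_copy_drop <- (r0_wt - r0_hi) / max(copies)
    do.call(rbind, lapply(copies, function(cp) {
      x <- seq(0.2, 0.65, length.out = 5)
      r0 <- r0_wt - per_copy_drop * cp
      data.frame(strain = sprintf("B%d", cp), copy_number = cp,
                 growth_rate = x,
                 ribosomal_fraction = s * x + r0 + rnorm(5, 0, noise_sd))
    }))
  })
}

test_that("burden scaling recovers shared slope and copy-linear intercepts", {
  # noiseless: exact generator inversion for the no-burden and burden lines
  exact <- burden_scaling(make_burden_strains(1, noise_sd = 0))
  expect_equal(exact$table$slope, rep(0.35, 4), tolerance = 1e-10)
  expect_equal(exact$table$intercept[exact$table$copy_number == 0], 0.081,
               tolerance = 1e-10)
  expect_equal(exact$table$intercept[exact$table$copy_number == 8], 0.055,
               tolerance = 1e-10)
  # structure recovery across 20 noisy replicates: the largest slope
  # contrast stays at sampling-error scale (z-like statistic ~1.5 in
  # expectation for four strains) while the intercepts track copy number
  homog <- sapply(1:20, function(s) {
    bs <- burden_scaling(make_burden_strains(s))
    expect_lt(bs$intercept_copy_cor, -0.95)
    expect_lt(bs$slope_spread, 4 * bs$pooled_slope_se)
    bs$slope_homogeneity
  })
  expect_lt(mean(homog), 2)
})

test_that("the active:inactive ratio is burden invariant at matched conditions", {
  # burden shrinks (s x, r0) proportionally, so r_a/r_0 depends only on the
  # condition; fits from noisy points must agree within 10 percent
  withr::with_seed(77, {
    xs_wt <- seq(0.2, 0.65, length.out = 6)
    shrink <- 0.055 / 0.081
    xs_b <- xs_wt * shrink
    wt <- scaling_fit(xs_wt, 0.35 * xs_wt + 0.081 + rnorm(6, 0, 0.002))
    bd <- scaling_fit(xs_b, 0.35 * xs_b + 0.055 + rnorm(6, 0, 0.002))
    for (i in seq_along(xs_wt)) {
      ratio_wt <- active_inactive_ratio(wt, xs_wt[i])
      ratio_bd <- active_inactive_ratio(bd, xs_b[i])
      expect_lt(abs(ratio_bd - ratio_wt) / ratio_wt, 0.10)
    }
  })
})

test_that("recovery-delay predictions scale with the residual pool", {
  expect_equal(predict_recovery_delay(0.08, 0.08)$fold, 1)
  d <- predict_recovery_delay(0.081, 0.081 * 0.85)
  expect_equal(d$fold, 1 / 0.85, tolerance = 1e-12)
  expect_equal(round(d$percent_prolongation), 18)
  folds <- sapply(seq(0.04, 0.08, by = 0.01), function(r0)
    predict_recovery_delay(0.081, r0)$fold)
  expect_true(all(diff(folds) < 0))
  expect_error(predict_recovery_delay(0.08, 0), "positive")
  # the log-pool alternative is milder for small changes
  expect_lt(predict_recovery_delay(0.081, 0.081 * 0.85, model = "log")$fold,
            d$fold)
})
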