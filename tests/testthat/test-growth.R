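test_that("rate series is exactly constant on an exact exponential", {
  gc <- simulate_growth_curve(od0 = 0.2, lag = 0, rate = 0.5, noise_cv = 0,
                              sampling = 10, t_max = 200, seed = 1)
  for (w in c(30, 60, 120)) {
    rs <- rate_series(gc, window_min = w)
    expect_equal(rs$rate, rep(0.5, nrow(rs)), tolerance = 1e-9)
  }
  flat <- growth_curve(seq(0, 100, 10), rep(0.3, 11))
  fr <- rate_series(flat, 60)$rate
  expect_equal(fr, rep(0, length(fr)), tolerance = 1e-12)
})

test_that("piecewise lag fit recovers lag and rate on synthetic curves", {
  # zero-lag exponential: lag collapses to the first sample
  gc0 <- simulate_growth_curve(lag = 0, rate = 0.4, noise_cv = 0,
                               sampling = 15, t_max = 240, seed = 1)
  fit0 <- lag_and_rate(gc0)
  expect_equal(fit0$lag, 0)
  expect_equal(fit0$rate, 0.4, tolerance = 1e-9)
  # stationary-exit conditions: lag 40 min, 0.55 gen/hr, cv 2 percent;
  # 5-min sampling so the breakpoint grid can resolve a 10 percent error
  est <- sapply(1:10, function(s) {
    gc <- simulate_growth_curve(od0 = 0.1, lag = 40, rate = 0.55,
                                noise_cv = 0.02, sampling = 5, t_max = 300,
                                seed = s)
    unlist(lag_and_rate(gc)[c("lag", "rate")])
  })
  expect_lt(abs(mean(est["lag", ]) - 40) / 40, 0.10)
  expect_lt(abs(mean(est["rate", ]) - 0.55) / 0.55, 0.10)
})

test_that("piecewise lag fit equals the exhaustive breakpoint oracle", {
  withr::with_seed(33, {
    for (i in 1:8) {
      gc <- simulate_growth_curve(od0 = 0.2, lag = sample(c(0, 30, 60), 1),
                                  rate = runif(1, 0.3, 0.7), noise_cv = 0.03,
                                  sampling = 10, t_max = 300,
                                  seed = sample.int(1e6, 1))
      got <- lag_and_rate(gc)
      want <- hinge_oracle(gc$time, gc$value)
      expect_equal(got$lag, want$lag)
      expect_equal(got$rate, want$rate, tolerance = 1e-8)
    }
  })
})

test_that("no-growth curves are flagged instead of fitted", {
  flat <- growth_curve(seq(0, 200, 15), rep(0.2, 14))
  expect_warning(fit <- lag_and_rate(flat), "no growth")
  expect_true(is.na(fit$lag))
  expect_false(fit$growth_detected)
})

test_that("recovery time obeys its closed form on noiseless curves", {
  for (L in c(0, 30, 60)) for (g in c(0.3, 0.55, 0.8)) {
    gc <- simulate_growth_curve(od0 = 0.15, lag = L, rate = g, noise_cv = 0,
                                sampling = 5, t_max = 400, seed = 1)
    expect_equal(recovery_time(gc), L + 60 * log2(1.5) / g, tolerance = 0.2)
    # scale invariance
    scaled <- growth_curve(gc$time, gc$value * 11)
    expect_equal(recovery_time(scaled), recovery_time(gc))
  }
  short <- growth_curve(c(0, 10, 20), c(1, 1.01, 1.02))
  expect_warning(rt <- recovery_time(short), "censored")
  expect_true(is.na(rt) && isTRUE(attr(rt, "censored")))
})

test_that("upshift response recovers both rates", {
  # noiseless instantaneous step: exact on both sides
  gc <- simulate_growth_curve(od0 = 50, lag = 0, rate = 0.36, t_shift = 60,
                              rate_after = 0.54, sampling = 3, t_max = 120,
                              noise_cv = 0, kind = "volume", seed = 1)
  sr <- shift_response(gc, 60)
  expect_equal(sr$rate_before, 0.36, tolerance = 1e-9)
  expect_equal(sr$rate_after, 0.54, tolerance = 1e-9)
  # no shift: both windows agree
  gc2 <- simulate_growth_curve(od0 = 50, lag = 0, rate = 0.45, sampling = 3,
                               t_max = 120, noise_cv = 0, seed = 2)
  sr2 <- shift_response(gc2, 60)
  expect_equal(sr2$rate_before, sr2$rate_after, tolerance = 1e-9)
  # galactose-to-glucose conditions, 50 averaged single-cell traces
  est <- sapply(1:5, function(s) {
    cells <- lapply(1:50, function(i)
      simulate_growth_curve(od0 = 50, lag = 0, rate = 0.36, t_shift = 60,
                            rate_after = 0.54, sampling = 3, t_max = 120,
                            noise_cv = 0.03, kind = "volume",
                            seed = s * 1000L + i))
    unlist(shift_response(average_growth_curves(cells), 60))
  })
  expect_lt(abs(mean(est["rate_before", ]) - 0.36) / 0.36, 0.10)
  expect_lt(abs(mean(est["rate_after", ]) - 0.54) / 0.54, 0.10)
  expect_error(shift_response(gc, 115), "post-shift")
})

test_that("lead time finds the offset between staggered declines", {
  tt <- seq(0, 20, by = 0.5)  # hours
  drop_at <- function(t0) 1 / (1 + exp(3 * (tt - t0)))
  a <- data.frame(time = tt, value = 0.3 * drop_at(8) + 0.02)
  same <- lead_time(a, a)
  expect_equal(same$lead, 0)
  for (off in c(4, 5)) {
    b <- data.frame(time = tt, value = 0.5 * drop_at(8 + off) + 0.05)
    expect_equal(lead_time(a, b)$lead, off, tolerance = 0.5)
  }
  const <- data.frame(time = tt, value = rep(1, length(tt)))
  expect_warning(res <- lead_time(a, const), "series_b")
  expect_true(is.na(res$lead))
})

test_that("growth statistics are invariant to positive rescaling", {
  gc <- simulate_growth_curve(od0 = 0.1, lag = 40, rate = 0.5, noise_cv = 0.02,
                              sampling = 10, t_max = 300, seed = 44)
  sc <- growth_curve(gc$time, gc$value * 3.7)
  expect_equal(rate_series(sc, 60)$rate, rate_series(gc, 60)$rate,
               tolerance = 1e-9)
  expect_equal(lag_and_rate(sc)[c("lag", "rate")],
               lag_and_rate(gc)[c("lag", "rate")], tolerance = 1e-9)
  expect_equal(shift_response(sc, 150, window_min = 60),
               shift_response(gc, 150, window_min = 60), tolerance = 1e-9)
})
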