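test_that("ct_series validates its contract", {
  s <- ct_series("NAL", c(1, 2, 4), c(10, 20, 5), dose = 162)
  expect_s3_class(s, "ct_series")
  expect_error(ct_series("M6", 1:3, 1:3, 162), "arg")
  expect_error(ct_series("NAL", c(1, 1, 2), c(1, 2, 3), 162),
               "strictly increasing")
  expect_error(ct_series("NAL", 1:2, c(-1, 2), 162), "non-negative")
  # censored points may be NA
  s2 <- ct_series("M1", 1:3, c(NA, 2, 3), 162, lloq = 0.5)
  expect_equal(s2$censored, c(TRUE, FALSE, FALSE))
})

test_that("trapezoidal AUC matches hand values and the exponential oracle", {
  flat <- ct_series("NAL", seq(0, 24, 2), rep(10, 13), 162)
  expect_equal(auc_trapezoid(flat, 0, 24), 240)
  two <- ct_series("NAL", c(0, 2), c(0, 10), 162)
  expect_equal(auc_trapezoid(two), 10)
  # subinterval with interpolated endpoints
  expect_equal(auc_trapezoid(flat, 1, 5), 40)
  expect_error(auc_trapezoid(flat, 0, 30), "outside sampled range")

  # exponential decay: trapezoid overestimates by a bounded discretization
  # error (convexity); closed form = (C0/k)(1 - exp(-k t))
  k <- 0.2
  tt <- seq(0, 24, 0.5)
  s <- ct_series("NAL", tt, 100 * exp(-k * tt), 162)
  exact <- 100 / k * (1 - exp(-k * 24))
  trap <- auc_trapezoid(s, 0, 24)
  expect_gt(trap, exact)
  expect_lt(trap - exact, 100 * k * 0.5^2 / 12 * 24)  # h^2/12 f'' bound
})

test_that("censored handling: LLOQ/2 interior, zero on the tails", {
  s <- ct_series("M3", 0:4, c(NA, 10, NA, 10, NA), 162, lloq = 1,
                 censored = c(TRUE, FALSE, TRUE, FALSE, TRUE))
  # tails 0, interior imputed at 0.5
  expect_equal(auc_trapezoid(s, 0, 4),
               (0 + 10) / 2 + (10 + 0.5) / 2 + (0.5 + 10) / 2 + (10 + 0) / 2)
})

test_that("model AUC agrees with trapezoid on the dense grid", {
  sim <- cached_sim("healthy")
  s <- sim_ct_series(sim, "NAL")
  expect_equal(auc_model(sim, "NAL", 0, 96), auc_trapezoid(s, 0, 96),
               tolerance = 1e-10)
  zero <- ct_series("NAL", s$time, rep(0, length(s$time)), 162)
  expect_equal(auc_trapezoid(zero), 0)
})

test_that("interval half-life recovers exact exponentials and flags junk", {
  tt <- seq(12, 36, 2)
  s <- ct_series("NAL", tt, 100 * 2^(-tt / 12), 162)
  expect_equal(interval_half_life(s, 12, 24), 12, tolerance = 1e-10)
  expect_equal(interval_half_life(s, 12, 24, two_point = TRUE), 12,
               tolerance = 1e-10)
  # scale invariance
  s10 <- ct_series("NAL", tt, 10 * 100 * 2^(-tt / 12), 162)
  expect_equal(interval_half_life(s10, 24, 36),
               interval_half_life(s, 24, 36))
  flat <- ct_series("NAL", tt, rep(5, length(tt)), 162)
  expect_true(is.na(interval_half_life(flat, 12, 36)))
  one <- ct_series("NAL", c(12, 20), c(5, NA), 162,
                   censored = c(FALSE, TRUE))
  expect_true(is.na(interval_half_life(one, 12, 24)))
})

test_that("dose normalization scales concentrations and commutes with AUC", {
  tt <- seq(0, 24, 2)
  s <- ct_series("NAL", tt, exp(-0.1 * tt) * 30, 27, lloq = 0.05)
  dn <- dose_normalize(s, 162)
  expect_equal(dn$conc, s$conc * 6)
  expect_equal(dn$dose, 162)
  expect_equal(dn$lloq, 0.3)
  expect_equal(auc_trapezoid(dn, 0, 24), 6 * auc_trapezoid(s, 0, 24))
  expect_equal(dose_normalize(s, 27)$conc, s$conc)
})

test_that("naive pooling averages uncensored subjects pointwise", {
  tt <- c(1, 2, 4)
  a <- ct_series("NAL", tt, c(0, 0, 0), 162)
  b <- ct_series("NAL", tt, c(10, 10, 10), 162)
  pool <- naive_pool(list(a, b))
  expect_equal(pool$mean$conc, c(5, 5, 5))
  expect_equal(pool$sd$conc, rep(sd(c(0, 10)), 3))
  expect_equal(pool$sd$conc[1], 7.07, tolerance = 1e-2)

  same <- naive_pool(list(b, b, b))
  expect_equal(same$mean$conc, b$conc)
  expect_equal(same$sd$conc, c(0, 0, 0))

  # censored points drop out; all-censored points stay censored
  cns <- ct_series("NAL", tt, c(NA, 10, NA), 162,
                   censored = c(TRUE, FALSE, TRUE))
  pool2 <- naive_pool(list(b, cns))
  expect_equal(pool2$mean$conc, c(10, 10, 10))
  expect_equal(pool2$n_obs, c(1, 2, 1))
  all_c <- ct_series("NAL", tt, rep(NA_real_, 3), 162,
                     censored = rep(TRUE, 3))
  pool3 <- naive_pool(list(all_c, all_c))
  expect_true(all(pool3$mean$censored))

  expect_error(naive_pool(list(a, ct_series("NAL", c(1, 2, 5), 1:3, 162))),
               "mismatched")
  expect_error(naive_pool(list(a, ct_series("M1", tt, 1:3, 162))),
               "mixed analytes")
})

test_that("pooled mean of a lognormal cohort exceeds its median profile", {
  # mean(exp(X)) > exp(mean(X)) pointwise; checked on generated cohorts
  set.seed(3)
  tt <- c(1, 2, 3)
  base <- c(10, 20, 15)
  cohort <- lapply(1:200, function(i) {
    ct_series("NAL", tt, base * exp(rnorm(1, 0, 0.4)), 162)
  })
  pool <- naive_pool(cohort)
  expect_true(all(pool$mean$conc > base * 0.98))
  expect_gt(mean(pool$mean$conc / base), 1.02)
})

test_that("aape and fold_change are plain arithmetic with guards", {
  expect_equal(aape(c(100, 50), c(100, 50)), 0)
  expect_equal(aape(1.07 * c(10, 20, 30), c(10, 20, 30)), 7)
  expect_equal(aape(c(110, 95), c(100, 100)), 7.5)
  expect_error(aape(1, c(1, 2)), "length mismatch")
  expect_error(aape(1, 0), "positive")
  expect_equal(fold_change(310, 100), 3.1)
  expect_equal(fold_change(7, 7), 1)
  expect_equal(fold_change(740, 100), 7.4)
  expect_error(fold_change(1, 0), "positive")
})

test_that("pk_summary collects the reported panel quantities", {
  tt <- c(seq(0.5, 8, 0.5), 12, 16, 24, 36, 48)
  cc <- 50 * (exp(-0.15 * tt) - exp(-1.2 * tt))
  s <- ct_series("NAL", tt, cc, 162)
  out <- pk_summary(s)
  expect_equal(out$cmax, max(cc))
  expect_equal(out$tmax, tt[which.max(cc)])
  expect_gt(out$thalf_24_36, 3)
  expect_equal(out$auc, auc_trapezoid(s))
})
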