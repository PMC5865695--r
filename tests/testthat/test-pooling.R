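test_that("fixed-effect pooling matches hand inverse-variance arithmetic", {
  p <- pool_fixed(c(1, 1), c(0.25, 0.25))
  expect_equal(p$theta, 1)
  expect_equal(p$se, sqrt(1 / 8))
  expect_equal(p$het$q, 0)
  expect_equal(p$het$i_squared, 0)

  p2 <- pool_fixed(c(0, 2), c(1, 1))
  expect_equal(p2$theta, 1)
  expect_equal(p2$se, sqrt(0.5))
  expect_equal(p2$het$q, 2)
  expect_equal(p2$het$df, 1L)

  expect_error(pool_fixed(1, 0.5), ">= 2 datasets")
})

test_that("pooling is invariant under permutation of inputs", {
  set.seed(5)
  th <- rnorm(10); v <- runif(10, 0.1, 1)
  o <- sample(10)
  for (fun in list(pool_fixed, pool_random_dl)) {
    a <- fun(th, v); b <- fun(th[o], v[o])
    expect_equal(a$theta, b$theta)
    expect_equal(a$se, b$se)
    expect_equal(a$het$q, b$het$q)
  }
})

test_that("DerSimonian-Laird reproduces the hand-computed fixture", {
  p <- pool_random_dl(c(0, 2, 4), c(1, 1, 1))
  expect_equal(p$het$q, 8)
  expect_equal(p$het$df, 2L)
  expect_equal(p$het$tau_squared, 3)
  expect_equal(p$theta, 2)
  expect_equal(p$se, sqrt(4 / 3)) # 1/sqrt(sum(1/(1+3)))
})

test_that("DL truncates to the fixed-effect answer when Q <= df", {
  th <- c(1, 1.05, 0.95); v <- c(1, 1, 1)
  r <- pool_random_dl(th, v)
  f <- pool_fixed(th, v)
  expect_identical(r$theta, f$theta)
  expect_identical(r$se, f$se)
  expect_equal(r$het$tau_squared, 0)
})

test_that("DL pooling agrees with an independent reference implementation", {
  set.seed(42)
  th <- rnorm(12, 0.5, 0.6); v <- runif(12, 0.05, 0.4)
  mine <- pool_random_dl(th, v)
  ref <- metafor::rma(yi = th, vi = v, method = "DL")
  expect_equal(mine$theta, as.numeric(ref$beta), tolerance = 1e-10)
  expect_equal(mine$se, ref$se, tolerance = 1e-10)
  expect_equal(mine$het$tau_squared, ref$tau2, tolerance = 1e-10)
  expect_equal(mine$het$q, ref$QE, tolerance = 1e-10)

  fix <- pool_fixed(th, v)
  reff <- metafor::rma(yi = th, vi = v, method = "FE")
  expect_equal(fix$theta, as.numeric(reff$beta), tolerance = 1e-10)
  expect_equal(fix$se, reff$se, tolerance = 1e-10)
})

test_that("DL recovers a known between-study variance in simulation", {
  set.seed(314)
  tau2_hat <- replicate(500, {
    th <- rnorm(40, 0, sqrt(0.09 + 0.01))
    heterogeneity(th, rep(0.01, 40))$tau_squared
  })
  expect_gte(mean(tau2_hat), 0.07)
  expect_lte(mean(tau2_hat), 0.11)
})

test_that("heterogeneity statistics are internally consistent with printed anchors", {
  # nine equal-weight estimates constructed so that Q = 19.42 on 8 df
  t <- sqrt(19.42 * 9 / 8)
  h <- heterogeneity(c(rep(0, 8), t), rep(1, 9))
  expect_equal(h$q, 19.42, tolerance = 1e-12)
  expect_equal(h$df, 8L)
  expect_lt(abs(h$i_squared - 58.8), 0.05)
  expect_lt(abs(h$p_value - 0.013), 5e-4)

  # eight remaining after dropping the outlier: I2 = 48.7% on 7 df -> p = 0.058
  t2 <- sqrt((7 / (1 - 0.487)) * 8 / 7)
  h2 <- heterogeneity(c(rep(0, 7), t2), rep(1, 8))
  expect_lt(abs(h2$i_squared - 48.7), 0.05)
  expect_lt(abs(h2$p_value - 0.058), 5e-4)

  # degenerate and truncated cases
  h0 <- heterogeneity(rep(1.3, 5), rep(0.2, 5))
  expect_equal(h0$q, 0)
  expect_equal(h0$i_squared, 0)
  expect_equal(h0$p_value, 1)
  hq <- heterogeneity(c(rep(0, 8), 0.5), rep(1, 9))
  expect_lt(hq$q, hq$df)
  expect_equal(hq$i_squared, 0)
  expect_equal(hq$tau_squared, 0)
})

test_that("Q and I-squared obey their invariance properties", {
  set.seed(8)
  th <- rnorm(7); v <- runif(7, 0.1, 1)
  h <- heterogeneity(th, v)
  expect_equal(heterogeneity(th + 5, v)$q, h$q)
  expect_equal(heterogeneity(th, v)$i_squared,
               heterogeneity(th * 3, v * 9)$i_squared)
})

test_that("model selection follows the configured heterogeneity gate", {
  h_high <- heterogeneity(c(rep(0, 8), sqrt(19.42 * 9 / 8)), rep(1, 9))
  expect_equal(select_model(h_high, "joint", quiet = TRUE), "random")
  h_mid <- heterogeneity(c(rep(0, 7), sqrt((7 / (1 - 0.487)) * 8 / 7)), rep(1, 8))
  expect_equal(select_model(h_mid, "i2_only", quiet = TRUE), "fixed")
  expect_equal(select_model(h_mid, "joint", quiet = TRUE), "random")
  h_none <- heterogeneity(c(0, 0.01, -0.01), rep(1, 3))
  expect_equal(select_model(h_none, "joint", quiet = TRUE), "fixed")
  expect_equal(select_model(h_mid, "p_only", p_min = 0.05, quiet = TRUE), "fixed")
})

test_that("proportion pooling works on the logit scale with boundary correction", {
  p <- pool_proportions(c(50, 50), c(100, 100))
  expect_equal(p$point, 0.5)
  expect_equal(p$scale, "logit")

  # a 0/20 record is corrected to 0.5/21 before the transform
  pb <- pool_proportions(c(0, 5), c(20, 20))
  byhand <- pool_random_dl(qlogis(c(0.5 / 21, 5 / 20)),
                           c(1 / 0.5 + 1 / 20.5, 1 / 5 + 1 / 15),
                           scale = "logit")
  expect_equal(pb$theta, byhand$theta)
  expect_equal(pb$se, byhand$se)
  expect_equal(pb$per_study_weights$weight, byhand$per_study_weights$weight)

  expect_error(pool_proportions(3, 10), ">= 2")
  expect_error(pool_proportions(c(3, 11), c(10, 10)), "x <= n")
})

test_that("proportion pooling recovers a heterogeneous true rate", {
  set.seed(59)
  pts <- replicate(200, {
    n <- sample(30:120, 36, replace = TRUE)
    lg <- rnorm(36, qlogis(0.59), 0.8)
    x <- rbinom(36, n, plogis(lg))
    pool_proportions(x, n)$point
  })
  expect_lt(abs(mean(pts) - 0.59), 0.05)
})

test_that("back-transformed intervals respect their scale ranges", {
  set.seed(21)
  for (i in 1:20) {
    x <- rbinom(6, 40, runif(1, 0.05, 0.95)); n <- rep(40, 6)
    p <- pool_proportions(x, n)
    expect_true(p$ci_low > 0 && p$ci_high < 1)
    expect_true(p$ci_low < p$point && p$point < p$ci_high)
    pl <- pool_random_dl(rnorm(6), runif(6, 0.1, 1), scale = "log")
    expect_true(pl$ci_low > 0)
    expect_true(is.finite(pl$ci_high))
  }
})

test_that("fixed-effect pooled SE is smaller than every study SE", {
  set.seed(13)
  v <- runif(8, 0.1, 2)
  p <- pool_fixed(rnorm(8), v)
  expect_true(all(p$se < sqrt(v)))
})
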