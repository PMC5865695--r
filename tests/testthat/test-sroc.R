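# metrics frame with a common DOR across a range of thresholds
const_dor_metrics <- function(dor, fpr = c(0.05, 0.1, 0.2, 0.35, 0.5)) {
  data.frame(tpr = plogis(log(dor) + qlogis(fpr)), fpr = fpr,
             var_d = rep(0.2, length(fpr)))
}

test_that("studies sharing one DOR give a symmetric curve with a = ln(DOR)", {
  # exact fit: suppress the perfect-fit note from the regression summary
  fit <- suppressWarnings(fit_sroc(const_dor_metrics(36)))
  expect_equal(fit$b, 0, tolerance = 1e-10)
  expect_equal(fit$a, log(36), tolerance = 1e-10)
  expect_equal(fit$q_star, 1 / (1 + 36^-0.5), tolerance = 1e-8)
  expect_equal(fit$q_star, 6 / 7, tolerance = 1e-8)
})

test_that("the no-discrimination curve is the chance diagonal", {
  s <- sroc_from_coef(0, 0)
  expect_equal(s$auc, 0.5, tolerance = 1e-12)
  expect_equal(s$q_star, 0.5)
})

test_that("trapezoid AUC matches the analytic symmetric-curve integral", {
  for (R in c(2, 10, 38.55)) {
    analytic <- R * (R - 1 - log(R)) / (R - 1)^2
    expect_lt(abs(sroc_from_coef(log(R))$auc - analytic), 1e-4)
  }
})

test_that("swapping diseased and non-diseased roles negates the intercept", {
  df <- apply_continuity(simulate_accuracy(accuracy_sim_config(k = 12, seed = 6)))
  m <- compute_metrics(df)
  swapped <- df
  swapped[, c("tp", "fn")] <- df[, c("fn", "tp")]
  swapped[, c("tn", "fp")] <- df[, c("fp", "tn")]
  ms <- compute_metrics(swapped)
  f1 <- fit_sroc(m); f2 <- fit_sroc(ms)
  expect_equal(f2$a, -f1$a, tolerance = 1e-8)
  expect_equal(f2$b, f1$b, tolerance = 1e-8)
  expect_equal(f2$q_star, 1 - f1$q_star, tolerance = 1e-8)
})

test_that("fitted coefficients match long-hand normal equations", {
  m <- compute_metrics(apply_continuity(simulate_accuracy(
    accuracy_sim_config(k = 15, seed = 9))))
  D <- qlogis(m$tpr) - qlogis(m$fpr)
  S <- qlogis(m$tpr) + qlogis(m$fpr)
  f_un <- fit_sroc(m, weighting = "none")
  ab <- oracle_lsq(S, D)
  expect_equal(f_un$a, unname(ab["a"]), tolerance = 1e-10)
  expect_equal(f_un$b, unname(ab["b"]), tolerance = 1e-10)
  f_w <- fit_sroc(m, weighting = "inverse_variance")
  abw <- oracle_lsq(S, D, w = 1 / m$var_d)
  expect_equal(f_w$a, unname(abw["a"]), tolerance = 1e-10)
  expect_equal(f_w$b, unname(abw["b"]), tolerance = 1e-10)
})

test_that("the AUC grid is converged: halving the step moves it < 1e-5", {
  for (a in c(log(5), log(38.55))) {
    expect_lt(abs(sroc_from_coef(a, 0.2, grid_step = 0.001)$auc -
                  sroc_from_coef(a, 0.2, grid_step = 0.0005)$auc), 1e-5)
  }
})

test_that("Q* from the DOR is monotone with the right anchors", {
  expect_equal(qstar_from_dor(1), 0.5)
  qs <- qstar_from_dor(exp(seq(log(1.01), log(1e6), length.out = 50)))
  expect_true(all(diff(qs) > 0))
  expect_gt(qstar_from_dor(1e10), 0.9999)
  expect_error(qstar_from_dor(-1), "positive")
  expect_error(qstar_from_dor(0), "positive")
})

test_that("Q* rises with the intercept and its SE is positive", {
  a <- seq(-3, 3, 0.5)
  qs <- vapply(a, function(ai) sroc_from_coef(ai)$q_star, 0)
  expect_true(all(diff(qs) > 0))
  expect_gt(sroc_from_coef(1, se_a = 0.3)$se_q_star, 0)
})

test_that("degenerate and improper inputs are handled explicitly", {
  expect_error(fit_sroc(const_dor_metrics(36)[1:2, ]), ">= 3")
  bad <- const_dor_metrics(36); bad$tpr[1] <- 1
  expect_error(fit_sroc(bad), "strictly inside")
  expect_warning(sroc_from_coef(1, 1.2), "non-monotone")
})

test_that("observed-range AUC is a partial area within the window", {
  m <- const_dor_metrics(10)
  f <- suppressWarnings(fit_sroc(m, auc_range = "observed"))
  expect_lt(f$auc_observed, f$auc)
  expect_equal(f$fpr_window, range(m$fpr))
})
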