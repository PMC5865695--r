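#' Cochran Q, I-squared and the DerSimonian-Laird tau-squared
#'
#' Heterogeneity statistics for a set of study estimates with known
#' within-study variances. Q is the inverse-variance weighted sum of squared
#' deviations from the fixed-effect pooled value, referred to a chi-square
#' distribution with k - 1 degrees of freedom; I-squared is the percentage
#' of total variation attributable to between-study heterogeneity,
#' `max(0, 100 * (Q - df) / Q)`; tau-squared is the DerSimonian-Laird moment
#' estimate truncated at zero.
#'
#' @param theta study estimates on the analysis (transform) scale.
#' @param var within-study variances, all positive.
#' @param theta_fixed optional pooled value to measure deviations against;
#'   defaults to the inverse-variance fixed-effect pool of `theta`.
#' @return an object of class `dta_het`: list with `q`, `df`, `p_value`,
#'   `i_squared` (percent), `tau_squared`, `k`.
#' @export
heterogeneity <- function(theta, var, theta_fixed = NULL) {
  k <- length(theta)
  if (length(var) != k) stop("theta and var lengths differ")
  if (k < 2L) stop("heterogeneity requires >= 2 datasets")
  if (any(var <= 0)) stop("variances must be positive")
  w <- 1 / var
  if (is.null(theta_fixed)) theta_fixed <- sum(w * theta) / sum(w)
  q <- sum(w * (theta - theta_fixed)^2)
  df <- k - 1L
  p <- stats::pchisq(q, df, lower.tail = FALSE)
  i2 <- if (q > 0) max(0, 100 * (q - df) / q) else 0
  tau2 <- max(0, (q - df) / (sum(w) - sum(w^2) / sum(w)))
  structure(list(q = q, df = df, p_value = p, i_squared = i2,
                 tau_squared = tau2, k = k),
            class = "dta_het")
}

# shared inverse-variance engine; tau2 = 0 gives the fixed-effect pool
.pool <- function(theta, var, tau2, scale, model, labels) {
  k <- length(theta)
  if (k < 2L) stop("pooling requires >= 2 datasets")
  if (any(var <= 0)) stop("variances must be positive")
  het <- heterogeneity(theta, var)
  w <- 1 / (var + tau2)
  est <- sum(w * theta) / sum(w)
  se <- 1 / sqrt(sum(w))
  back <- switch(scale, identity = identity, logit = stats::plogis, log = exp)
  if (is.null(labels)) labels <- sprintf("S%02d", seq_len(k))
  structure(list(
    scale = scale, theta = est, se = se,
    point = back(est),
    ci_low = back(est - Z975 * se),
    ci_high = back(est + Z975 * se),
    model = model, k = k, het = het,
    per_study_weights = data.frame(study_id = labels, weight = w / sum(w),
                                   stringsAsFactors = FALSE)),
    class = "dta_pooled")
}

#' Fixed-effect inverse-variance pooling
#'
#' Pools study estimates with weights `w_i = 1/var_i`; the pooled standard
#' error is `1/sqrt(sum(w))`. Heterogeneity (Q, I-squared, tau-squared) is
#' computed against the fixed pooled value and attached.
#'
#' @param theta study estimates on the analysis scale.
#' @param var within-study variances.
#' @param scale transform scale of `theta`: `"identity"`, `"logit"` or
#'   `"log"`; point and CI are back-transformed through its inverse.
#' @param labels optional study labels for the weight table.
#' @return an object of class `dta_pooled`.
#' @export
pool_fixed <- function(theta, var, scale = c("identity", "logit", "log"),
                       labels = NULL) {
  scale <- match.arg(scale)
  .pool(theta, var, tau2 = 0, scale = scale, model = "fixed", labels = labels)
}

#' DerSimonian-Laird random-effects pooling
#'
#' Moment-based random-effects pooling: the between-study variance
#' tau-squared is estimated as `max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))`
#' with fixed-effect weights `w = 1/var`, then studies are re-weighted by
#' `1/(var + tau^2)`. When Q does not exceed its degrees of freedom the
#' estimate truncates to zero and the result coincides with [pool_fixed()].
#'
#' @inheritParams pool_fixed
#' @return an object of class `dta_pooled`.
#' @export
pool_random_dl <- function(theta, var, scale = c("identity", "logit", "log"),
                           labels = NULL) {
  scale <- match.arg(scale)
  het <- heterogeneity(theta, var)
  .pool(theta, var, tau2 = het$tau_squared, scale = scale,
        model = "random", labels = labels)
}

#' Choose between fixed- and random-effects models
#'
#' Applies a heterogeneity gate to a [heterogeneity()] result. Presets:
#' \describe{
#'   \item{joint}{random if I-squared >= `i2_max` or heterogeneity
#'     p < `p_min` (default 0.10); otherwise fixed.}
#'   \item{i2_only}{random iff I-squared >= `i2_max` (the gate used for the
#'     odds-ratio analyses).}
#'   \item{p_only}{random iff heterogeneity p < `p_min` (set `p_min = 0.05`
#'     for the "apparent heterogeneity" gate).}
#' }
#'
#' @param het a `dta_het` object.
#' @param rule gate preset.
#' @param i2_max I-squared threshold (percent), default 50.
#' @param p_min heterogeneity p-value threshold, default 0.10.
#' @param quiet suppress the message stating the chosen model.
#' @return `"fixed"` or `"random"`.
#' @export
select_model <- function(het, rule = c("joint", "i2_only", "p_only"),
                         i2_max = 50, p_min = 0.10, quiet = FALSE) {
  rule <- match.arg(rule)
  stopifnot(inherits(het, "dta_het"))
  random <- switch(rule,
    joint   = het$i_squared >= i2_max || het$p_value < p_min,
    i2_only = het$i_squared >= i2_max,
    p_only  = het$p_value < p_min)
  chosen <- if (random) "random" else "fixed"
  if (!quiet)
    message(sprintf("model selection (%s): I2 = %.1f%%, p = %.3f -> %s",
                    rule, het$i_squared, het$p_value, chosen))
  chosen
}

#' Pool proportions on the logit scale
#'
#' Generic inverse-variance pooling of event proportions (e.g. scan
#' detection rates). Each `x/n` is transformed to the logit with variance
#' `1/x + 1/(n - x)`; records with `x = 0` or `x = n` first receive the 0.5
#' continuity correction (`x + 0.5`, `n + 1`). Detection-rate pooling uses
#' the random-effects model by default; the pooled point and CI are
#' back-transformed through the inverse logit, so they always lie in (0, 1).
#'
#' @param x event counts.
#' @param n totals (all >= 1).
#' @param labels optional study labels.
#' @param model `"random"` (default) or `"fixed"`.
#' @return an object of class `dta_pooled` on the logit scale.
#' @export
pool_proportions <- function(x, n, labels = NULL, model = c("random", "fixed")) {
  model <- match.arg(model)
  if (length(x) != length(n)) stop("x and n lengths differ")
  if (length(x) < 2L) stop("pooling requires >= 2 datasets")
  if (any(x < 0 | x > n)) stop("need 0 <= x <= n")
  boundary <- x == 0 | x == n
  x <- x + 0.5 * boundary
  n <- n + 1 * boundary
  theta <- stats::qlogis(x / n)
  v <- 1 / x + 1 / (n - x)
  if (model == "random") pool_random_dl(theta, v, scale = "logit", labels = labels)
  else pool_fixed(theta, v, scale = "logit", labels = labels)
}

#' @export
print.dta_het <- function(x, ...) {
  cat(sprintf("Heterogeneity: Q = %.4g on %d df (p = %.4g), I2 = %.1f%%, tau2 = %.4g\n",
              x$q, x$df, x$p_value, x$i_squared, x$tau_squared))
  invisible(x)
}

#' @export
print.dta_pooled <- function(x, digits = 4, ...) {
  cat(sprintf("Pooled estimate (%s-effect, %s scale, k = %d)\n",
              x$model, x$scale, x$k))
  cat(sprintf("  point = %.*g  [95%% CI %.*g, %.*g]\n",
              digits, x$point, digits, x$ci_low, digits, x$ci_high))
  print(x$het)
  invisible(x)
}
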