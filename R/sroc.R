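#' Summary ROC curve from regression coefficients
#'
#' Builds the Moses-Littenberg summary ROC curve for intercept `a` and slope
#' `b` of the regression `D = a + b S`, where `D = logit(TPR) - logit(FPR)`
#' and `S = logit(TPR) + logit(FPR)`. The curve is
#' `logit(TPR) = a/(1-b) + ((1+b)/(1-b)) logit(FPR)`, evaluated on an FPR
#' grid of step `grid_step` over (0, 1); the AUC is the trapezoid integral
#' over \[0, 1\] with endpoints (0,0) and (1,1). The Q* index — the point
#' where sensitivity equals specificity — is `1/(1 + exp(-a/2))`, with
#' standard error `se_a * exp(-a/2) / (2 (1 + exp(-a/2))^2)` by the delta
#' method.
#'
#' @param a regression intercept (log-DOR at S = 0).
#' @param b regression slope; `|b| >= 1` yields an improper, non-monotone
#'   curve and triggers a warning (the AUC is still reported over the grid).
#' @param se_a,se_b optional coefficient standard errors.
#' @param weighted logical flag recording whether the fit was weighted.
#' @param grid_step FPR grid step, default 0.001.
#' @return an object of class `dta_sroc`: `a`, `b`, `se_a`, `se_b`,
#'   `weighted`, `auc`, `q_star`, `se_q_star`, and `curve` (data.frame of
#'   `fpr`, `tpr` including the (0,0) and (1,1) endpoints).
#' @export
sroc_from_coef <- function(a, b = 0, se_a = NA_real_, se_b = NA_real_,
                           weighted = FALSE, grid_step = 0.001) {
  if (!is.finite(a) || !is.finite(b)) stop("a and b must be finite")
  if (abs(b) >= 1)
    warning("|slope| >= 1: summary ROC curve is non-monotone / improper")
  fpr <- seq(grid_step, 1 - grid_step, by = grid_step)
  tpr <- stats::plogis(a / (1 - b) + ((1 + b) / (1 - b)) * stats::qlogis(fpr))
  curve <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  auc <- .trapezoid(curve$fpr, curve$tpr)
  q_star <- stats::plogis(a / 2)
  se_q_star <- se_a * exp(-a / 2) / (2 * (1 + exp(-a / 2))^2)
  structure(list(a = a, b = b, se_a = se_a, se_b = se_b, weighted = weighted,
                 auc = auc, q_star = q_star, se_q_star = se_q_star,
                 curve = curve),
            class = "dta_sroc")
}

.trapezoid <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Fit the Moses-Littenberg summary ROC regression
#'
#' Regresses `D_i = logit(tpr_i) - logit(fpr_i)` on
#' `S_i = logit(tpr_i) + logit(fpr_i)` across studies by least squares,
#' unweighted by default (the original recommendation) or weighted by
#' `1/var(D_i)` with `var(D_i) = 1/tp + 1/fp + 1/fn + 1/tn`. The fitted
#' intercept and slope feed [sroc_from_coef()].
#'
#' @param metrics per-study metrics from [compute_metrics()] (needs columns
#'   `tpr`, `fpr`, `var_d`), or any data frame with those columns; `tpr` and
#'   `fpr` must lie strictly inside (0, 1) (guaranteed after continuity
#'   correction).
#' @param weighting `"none"` (default) or `"inverse_variance"`.
#' @param auc_range `"full"` integrates the extrapolated curve over the
#'   whole \[0, 1\] FPR axis; `"observed"` reports the partial area over the
#'   observed FPR window only.
#' @param grid_step FPR grid step, default 0.001.
#' @return an object of class `dta_sroc`; with `auc_range = "observed"` the
#'   element `auc_observed` holds the partial area and `fpr_window` its
#'   limits.
#' @export
fit_sroc <- function(metrics, weighting = c("none", "inverse_variance"),
                     auc_range = c("full", "observed"), grid_step = 0.001) {
  weighting <- match.arg(weighting)
  auc_range <- match.arg(auc_range)
  need <- c("tpr", "fpr")
  if (!all(need %in% names(metrics))) stop("need columns tpr and fpr")
  k <- nrow(metrics)
  if (k < 3L) stop("SROC regression requires >= 3 studies")
  tpr <- metrics$tpr; fpr <- metrics$fpr
  if (any(tpr <= 0 | tpr >= 1 | fpr <= 0 | fpr >= 1))
    stop("tpr and fpr must lie strictly inside (0, 1); apply continuity correction")
  D <- stats::qlogis(tpr) - stats::qlogis(fpr)
  S <- stats::qlogis(tpr) + stats::qlogis(fpr)
  w <- if (weighting == "inverse_variance") {
    if (!"var_d" %in% names(metrics)) stop("inverse-variance weighting needs var_d")
    1 / metrics$var_d
  } else NULL
  fit <- stats::lm(D ~ S, weights = w)
  cf <- summary(fit)$coefficients
  out <- sroc_from_coef(a = cf[1, 1], b = cf[2, 1],
                        se_a = cf[1, 2], se_b = cf[2, 2],
                        weighted = weighting == "inverse_variance",
                        grid_step = grid_step)
  if (auc_range == "observed") {
    win <- range(fpr)
    cv <- out$curve
    keep <- cv$fpr >= win[1] & cv$fpr <= win[2]
    out$auc_observed <- .trapezoid(cv$fpr[keep], cv$tpr[keep])
    out$fpr_window <- win
  }
  out
}

#' Q* index implied by a diagnostic odds ratio
#'
#' For the symmetric summary ROC (slope 0) whose intercept is `ln(dor)`,
#' the sensitivity-equals-specificity point is `1/(1 + dor^(-1/2))`,
#' strictly increasing in the DOR with Q* = 0.5 at DOR = 1 (chance).
#'
#' @param dor diagnostic odds ratio, positive.
#' @return the Q* index in (0, 1).
#' @export
qstar_from_dor <- function(dor) {
  if (any(!is.finite(dor)) || any(dor <= 0)) stop("dor must be positive")
  1 / (1 + dor^(-0.5))
}

#' @export
print.dta_sroc <- function(x, ...) {
  cat(sprintf("Summary ROC (Moses-Littenberg, %s fit)\n",
              if (x$weighted) "inverse-variance weighted" else "unweighted"))
  cat(sprintf("  a = %.4f (SE %.4f), b = %.4f (SE %.4f)\n",
              x$a, x$se_a, x$b, x$se_b))
  cat(sprintf("  AUC = %.4f, Q* = %.4f (SE %.4f)\n", x$auc, x$q_star, x$se_q_star))
  if (!is.null(x$auc_observed))
    cat(sprintf("  partial AUC over FPR [%.3f, %.3f] = %.4f\n",
                x$fpr_window[1], x$fpr_window[2], x$auc_observed))
  invisible(x)
}
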