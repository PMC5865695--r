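#' Z-test comparison of two pooled estimates
#'
#' Two-sided Z test for the difference between two independently pooled
#' subgroups, performed on the transform scale (logit for proportions, log
#' for ratios): `z = (theta_a - theta_b) / sqrt(se_a^2 + se_b^2)`,
#' `p = 2 (1 - Phi(|z|))`.
#'
#' @param pool_a,pool_b `dta_pooled` objects on the same transform scale.
#' @param label_a,label_b subgroup labels for reporting.
#' @return an object of class `dta_subgroup`: labels, transform-scale
#'   estimates and SEs, `z` and `p_value`.
#' @export
compare_subgroups <- function(pool_a, pool_b, label_a = "A", label_b = "B") {
  stopifnot(inherits(pool_a, "dta_pooled"), inherits(pool_b, "dta_pooled"))
  if (pool_a$scale != pool_b$scale)
    stop("subgroup comparison requires a common transform scale (",
         pool_a$scale, " vs ", pool_b$scale, ")")
  z <- (pool_a$theta - pool_b$theta) / sqrt(pool_a$se^2 + pool_b$se^2)
  structure(list(label_a = label_a, label_b = label_b,
                 theta_a = pool_a$theta, theta_b = pool_b$theta,
                 se_a = pool_a$se, se_b = pool_b$se,
                 z = z, p_value = 2 * stats::pnorm(-abs(z))),
            class = "dta_subgroup")
}

#' Leave-one-out sensitivity analysis
#'
#' Re-pools the remaining k - 1 datasets after omitting each dataset in
#' turn, recording the pooled estimate and residual I-squared. Rows are
#' sorted by descending |delta I-squared| (full-set I-squared minus the
#' I-squared without the study), so the first row flags the dominant source
#' of heterogeneity.
#'
#' @param theta study estimates on the analysis scale.
#' @param var within-study variances.
#' @param labels study identifiers (defaults to S01, S02, ...).
#' @param scale transform scale for back-transformed points.
#' @param model `"random"` (DerSimonian-Laird) or `"fixed"` re-pooling.
#' @return a data.frame of class `dta_loo`: `omitted_id`, `theta`, `point`,
#'   `i_squared_without`, `delta_i_squared`; attribute `i_squared_full`.
#' @export
leave_one_out <- function(theta, var, labels = NULL,
                          scale = c("identity", "logit", "log"),
                          model = c("random", "fixed")) {
  scale <- match.arg(scale)
  model <- match.arg(model)
  k <- length(theta)
  if (k < 3L) stop("leave-one-out requires >= 3 datasets")
  if (is.null(labels)) labels <- sprintf("S%02d", seq_len(k))
  pool_fun <- if (model == "random") pool_random_dl else pool_fixed
  i2_full <- heterogeneity(theta, var)$i_squared
  rows <- lapply(seq_len(k), function(i) {
    p <- pool_fun(theta[-i], var[-i], scale = scale, labels = labels[-i])
    data.frame(omitted_id = labels[i], theta = p$theta, point = p$point,
               i_squared_without = p$het$i_squared,
               delta_i_squared = i2_full - p$het$i_squared,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-abs(out$delta_i_squared)), ]
  rownames(out) <- NULL
  attr(out, "i_squared_full") <- i2_full
  class(out) <- c("dta_loo", "data.frame")
  out
}

#' Deeks' funnel-plot asymmetry test for publication bias
#'
#' The recommended small-study-effect test for diagnostic accuracy
#' meta-analyses: weighted least-squares regression of the log diagnostic
#' odds ratio on `1/sqrt(ESS)`, weighted by the effective sample size
#' `ESS = 4 n1 n2 / (n1 + n2)` with `n1 = tp + fn` diseased and
#' `n2 = fp + tn` non-diseased subjects. A two-sided p-value for the slope
#' uses the t distribution with k - 2 degrees of freedom; p < 0.05 indicates
#' significant funnel asymmetry.
#'
#' @param studies accuracy data frame; zero cells are continuity-corrected
#'   internally for the log-DOR, while ESS uses the original integer counts.
#' @return an object of class `dta_deeks`: `slope`, `intercept`, `p_value`,
#'   `funnel_points` (data.frame of `study_id`, `ln_dor`, `inv_sqrt_ess`,
#'   `ess`).
#' @export
deeks_test <- function(studies) {
  cells <- c("tp", "fp", "fn", "tn")
  if (!all(cells %in% names(studies))) stop("need columns tp, fp, fn, tn")
  k <- nrow(studies)
  if (k < 3L) stop("Deeks' test requires >= 3 studies")
  studies <- apply_continuity(studies)
  m <- as.matrix(studies[, cells])
  raw <- m - 0.5 * studies$corrected
  n1 <- raw[, "tp"] + raw[, "fn"]
  n2 <- raw[, "fp"] + raw[, "tn"]
  ess <- 4 * n1 * n2 / (n1 + n2)
  ln_dor <- log(m[, "tp"] * m[, "tn"] / (m[, "fp"] * m[, "fn"]))
  x <- 1 / sqrt(ess)
  labels <- if ("study_id" %in% names(studies)) studies$study_id else
    sprintf("S%02d", seq_len(k))
  pts <- data.frame(study_id = labels, ln_dor = ln_dor,
                    inv_sqrt_ess = x, ess = ess, stringsAsFactors = FALSE)
  if (stats::var(x) == 0) {
    warning("effective sample size constant across studies; slope degenerate")
    return(structure(list(slope = 0, intercept = mean(ln_dor),
                          p_value = NA_real_, funnel_points = pts),
                     class = "dta_deeks"))
  }
  fit <- stats::lm(ln_dor ~ x, weights = ess)
  cf <- summary(fit)$coefficients
  structure(list(slope = cf[2, 1], intercept = cf[1, 1],
                 p_value = cf[2, 4], funnel_points = pts),
            class = "dta_deeks")
}

#' @export
print.dta_subgroup <- function(x, ...) {
  cat(sprintf("Subgroup comparison %s vs %s: z = %.3f, p = %.4g\n",
              x$label_a, x$label_b, x$z, x$p_value))
  invisible(x)
}

#' @export
print.dta_deeks <- function(x, ...) {
  cat(sprintf("Deeks' funnel asymmetry test (k = %d): slope = %.3f, p = %s\n",
              nrow(x$funnel_points), x$slope,
              if (is.na(x$p_value)) "NA (degenerate)" else sprintf("%.4g", x$p_value)))
  invisible(x)
}
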