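#' Per-study diagnostic accuracy metrics
#'
#' Computes sensitivity, specificity, predictive values, likelihood ratios
#' and the diagnostic odds ratio (DOR) for every 2x2 table, with 95%
#' confidence intervals. Proportions get Clopper-Pearson exact intervals
#' computed on the uncorrected integer counts; ratio intervals are
#' log-normal Wald, exp(ln theta +/- 1.96 SE), on the continuity-corrected
#' cells with SE(ln DOR) = sqrt(1/tp + 1/fp + 1/fn + 1/tn) and the Simel
#' log-SE formulas for LR+ and LR-.
#'
#' Point estimates use the cells as given (corrected where the zero-cell
#' rule applied), so `dor = lr_pos / lr_neg` holds exactly on every row.
#'
#' @param studies accuracy data frame, continuity-corrected via
#'   [apply_continuity()] when any cell is zero.
#' @return a data.frame with one row per study arm: the point estimates,
#'   their CI bounds (`*_lcl`, `*_ucl`), `log_dor`, `var_log_dor`, and the
#'   ROC coordinates `tpr`, `fpr` with `var_d` (the variance of the
#'   log-DOR difference used by SROC weighting).
#' @export
compute_metrics <- function(studies) {
  cells <- c("tp", "fp", "fn", "tn")
  if (!all(cells %in% names(studies))) stop("need columns tp, fp, fn, tn")
  m <- as.matrix(studies[, cells])
  corrected <- if ("corrected" %in% names(studies)) studies$corrected else
    rep(FALSE, nrow(studies))
  if (any(m[!corrected, ] == 0))
    stop("zero cell without continuity correction; run apply_continuity() first")
  tp <- m[, "tp"]; fp <- m[, "fp"]; fn <- m[, "fn"]; tn <- m[, "tn"]
  # uncorrected integer counts back out of the 0.5 adjustment
  tp0 <- tp - 0.5 * corrected; fp0 <- fp - 0.5 * corrected
  fn0 <- fn - 0.5 * corrected; tn0 <- tn - 0.5 * corrected

  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  ppv  <- tp / (tp + fp)
  npv  <- tn / (tn + fn)
  lr_pos <- sens / (1 - spec)
  lr_neg <- (1 - sens) / spec
  dor <- (tp * tn) / (fp * fn)
  log_dor <- log(dor)
  var_log_dor <- 1 / tp + 1 / fp + 1 / fn + 1 / tn

  se_lr_pos <- sqrt(1 / tp - 1 / (tp + fn) + 1 / fp - 1 / (fp + tn))
  se_lr_neg <- sqrt(1 / fn - 1 / (tp + fn) + 1 / tn - 1 / (fp + tn))
  se_dor <- sqrt(var_log_dor)

  out <- data.frame(
    study_id = if ("study_id" %in% names(studies)) studies$study_id else
      sprintf("S%02d", seq_len(nrow(studies))),
    stringsAsFactors = FALSE)
  if ("arm" %in% names(studies)) out$arm <- studies$arm
  if ("tracer" %in% names(studies)) out$tracer <- studies$tracer

  cp <- function(x, n) {
    lcl <- ifelse(x == 0, 0, stats::qbeta(0.025, x, n - x + 1))
    ucl <- ifelse(x == n, 1, stats::qbeta(0.975, x + 1, n - x))
    list(lcl = lcl, ucl = ucl)
  }
  ci_sens <- cp(tp0, tp0 + fn0)
  ci_spec <- cp(tn0, tn0 + fp0)
  ci_ppv  <- cp(tp0, tp0 + fp0)
  ci_npv  <- cp(tn0, tn0 + fn0)

  out$sens <- sens; out$sens_lcl <- ci_sens$lcl; out$sens_ucl <- ci_sens$ucl
  out$spec <- spec; out$spec_lcl <- ci_spec$lcl; out$spec_ucl <- ci_spec$ucl
  out$ppv <- ppv;   out$ppv_lcl <- ci_ppv$lcl;   out$ppv_ucl <- ci_ppv$ucl
  out$npv <- npv;   out$npv_lcl <- ci_npv$lcl;   out$npv_ucl <- ci_npv$ucl
  out$lr_pos <- lr_pos
  out$lr_pos_lcl <- exp(log(lr_pos) - Z975 * se_lr_pos)
  out$lr_pos_ucl <- exp(log(lr_pos) + Z975 * se_lr_pos)
  out$lr_neg <- lr_neg
  out$lr_neg_lcl <- exp(log(lr_neg) - Z975 * se_lr_neg)
  out$lr_neg_ucl <- exp(log(lr_neg) + Z975 * se_lr_neg)
  out$dor <- dor
  out$dor_lcl <- exp(log_dor - Z975 * se_dor)
  out$dor_ucl <- exp(log_dor + Z975 * se_dor)
  out$log_dor <- log_dor
  out$var_log_dor <- var_log_dor
  out$tpr <- sens
  out$fpr <- 1 - spec
  out$var_d <- var_log_dor
  out
}

#' Log-odds-ratio and standard error from a reported confidence interval
#'
#' Converts reported odds (or hazard) ratios with 95% confidence intervals
#' to the log scale for inverse-variance pooling:
#' `log_or = ln(or_point)` and
#' `se_log_or = (ln(or_ucl) - ln(or_lcl)) / (2 * 1.959964)`.
#'
#' @param effects effect data frame with columns `or_point`, `or_lcl`,
#'   `or_ucl` (and optionally `study_id`).
#' @return a data.frame with columns `study_id`, `log_or`, `se_log_or`.
#' @export
effect_to_log <- function(effects) {
  need <- c("or_point", "or_lcl", "or_ucl")
  if (!all(need %in% names(effects))) stop("need columns ", paste(need, collapse = ", "))
  with_id <- "study_id" %in% names(effects)
  bad <- which(!(effects$or_lcl <= effects$or_point &
                 effects$or_point <= effects$or_ucl))
  if (length(bad)) stop("inverted CI in row ", bad[1])
  se <- (log(effects$or_ucl) - log(effects$or_lcl)) / (2 * Z975)
  if (any(se == 0)) warning("degenerate (zero-width) confidence interval")
  data.frame(
    study_id = if (with_id) effects$study_id else
      sprintf("S%02d", seq_len(nrow(effects))),
    log_or = log(effects$or_point),
    se_log_or = se,
    stringsAsFactors = FALSE)
}
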