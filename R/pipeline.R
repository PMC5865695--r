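#' Configure a full meta-analysis run
#'
#' Bundles the inputs and analysis options consumed by [run_pipeline()].
#' Each input may be a CSV path (read via [read_studies()]) or an in-memory
#' data frame in the same schema; any of the three may be omitted, and the
#' corresponding analyses are skipped.
#'
#' Heterogeneity-rule presets map onto [select_model()]: `"joint"` (random
#' if I-squared >= 50% or p < 0.10), `"i2_only"` (I-squared gate alone, the
#' convention for odds-ratio pooling), `"p_only"` (chi-square p < 0.05
#' gate). Detection rates are always pooled with random effects regardless
#' of preset.
#'
#' @param accuracy,detection,effect CSV path or data frame for each record
#'   kind (or `NULL` to skip).
#' @param quadas_min minimum QUADAS score retained, default 10.
#' @param het_rule heterogeneity gate preset.
#' @param sroc_weighting `"none"` or `"inverse_variance"`.
#' @param auc_range `"full"` or `"observed"`.
#' @param seed integer seed recorded in the report metadata.
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(accuracy = NULL, detection = NULL, effect = NULL,
                            quadas_min = 10,
                            het_rule = c("joint", "i2_only", "p_only"),
                            sroc_weighting = c("none", "inverse_variance"),
                            auc_range = c("full", "observed"),
                            seed = 1) {
  het_rule <- match.arg(het_rule)
  sroc_weighting <- match.arg(sroc_weighting)
  auc_range <- match.arg(auc_range)
  for (nm in c("accuracy", "detection", "effect")) {
    x <- get(nm)
    if (!is.null(x) && is.character(x) && !file.exists(x))
      stop("input file for '", nm, "' not found: ", x)
  }
  structure(list(accuracy = accuracy, detection = detection, effect = effect,
                 quadas_min = quadas_min, het_rule = het_rule,
                 sroc_weighting = sroc_weighting, auc_range = auc_range,
                 seed = seed),
            class = "analysis_config")
}

.load_input <- function(x, kind) {
  if (is.null(x)) return(NULL)
  if (is.character(x)) read_studies(x, kind) else validate_studies(x, kind)
}

.gate_pool <- function(theta, var, scale, rule, labels = NULL) {
  het <- heterogeneity(theta, var)
  p_min <- if (rule == "p_only") 0.05 else 0.10
  model <- select_model(het, rule = rule, p_min = p_min, quiet = TRUE)
  if (model == "random") pool_random_dl(theta, var, scale = scale, labels = labels)
  else pool_fixed(theta, var, scale = scale, labels = labels)
}

# pooled sens/spec/LRs/DOR for one set of corrected accuracy studies
.accuracy_pools <- function(studies, metrics, rule) {
  raw <- as.matrix(studies[, c("tp", "fp", "fn", "tn")]) - 0.5 * studies$corrected
  list(
    sens = pool_proportions(raw[, "tp"], raw[, "tp"] + raw[, "fn"],
                            labels = studies$study_id),
    spec = pool_proportions(raw[, "tn"], raw[, "tn"] + raw[, "fp"],
                            labels = studies$study_id),
    lr_pos = .gate_pool(log(metrics$lr_pos),
                        (log(metrics$lr_pos_ucl) - log(metrics$lr_pos_lcl))^2 /
                          (2 * Z975)^2,
                        "log", rule, studies$study_id),
    lr_neg = .gate_pool(log(metrics$lr_neg),
                        (log(metrics$lr_neg_ucl) - log(metrics$lr_neg_lcl))^2 /
                          (2 * Z975)^2,
                        "log", rule, studies$study_id),
    dor = .gate_pool(metrics$log_dor, metrics$var_log_dor, "log", rule,
                     studies$study_id))
}

#' Run the full diagnostic-accuracy meta-analysis pipeline
#'
#' Executes, in order: ingestion and validation, QUADAS quality filtering,
#' zero-cell continuity correction, per-study metrics, pooled
#' sensitivity/specificity/likelihood ratios/DOR (overall and per tracer,
#' with Z-test subgroup comparisons), the summary ROC with AUC and Q*,
#' Deeks' publication-bias test, detection-rate pooling overall, per tracer
#' and per PSA stratum (with per-stratum tracer comparisons), odds-ratio
#' pooling under the configured heterogeneity gate, and a leave-one-out
#' sensitivity analysis of the odds-ratio pool.
#'
#' @param config an [analysis_config()].
#' @return an object of class `dta_report`; see [render_tables()] to export
#'   its tables.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  bundle <- list(meta = list(seed = config$seed,
                             het_rule = config$het_rule,
                             sroc_weighting = config$sroc_weighting,
                             auc_range = config$auc_range,
                             quadas_min = config$quadas_min,
                             package_version = as.character(
                               utils::packageVersion("dtameta"))))

  acc <- stage("ingest accuracy", .load_input(config$accuracy, "accuracy"))
  det <- stage("ingest detection", .load_input(config$detection, "detection"))
  eff <- stage("ingest effect", .load_input(config$effect, "effect"))

  if (!is.null(acc)) {
    acc <- stage("quality filter", filter_by_quadas(acc, config$quadas_min))
    acc <- stage("continuity correction", apply_continuity(acc))
    message("accuracy: ", nrow(acc), " study arms after filtering")
    metrics <- stage("per-study metrics", compute_metrics(acc))
    pools <- stage("accuracy pooling",
                   .accuracy_pools(acc, metrics, config$het_rule))
    by_tracer <- list()
    for (tr in intersect(c("C11", "F18"), unique(acc$tracer))) {
      idx <- acc$tracer == tr
      if (sum(idx) >= 3)
        by_tracer[[tr]] <- stage(paste("accuracy pooling", tr),
                                 .accuracy_pools(acc[idx, ], metrics[idx, ],
                                                 config$het_rule))
    }
    comparisons <- NULL
    if (all(c("C11", "F18") %in% names(by_tracer))) {
      comparisons <- stage("subgroup comparison", do.call(rbind, lapply(
        c("sens", "spec", "lr_pos", "lr_neg", "dor"), function(mm) {
          cmp <- compare_subgroups(by_tracer$C11[[mm]], by_tracer$F18[[mm]],
                                   "C11", "F18")
          data.frame(metric = mm, z = cmp$z, p_value = cmp$p_value,
                     stringsAsFactors = FALSE)
        })))
    }
    bundle$accuracy <- list(studies = acc, metrics = metrics,
                            pools = pools, by_tracer = by_tracer,
                            comparisons = comparisons)
    bundle$sroc <- stage("summary ROC",
                         fit_sroc(metrics, weighting = config$sroc_weighting,
                                  auc_range = config$auc_range))
    bundle$deeks <- stage("publication bias", deeks_test(acc))
  }

  if (!is.null(det)) {
    det <- stage("quality filter (detection)",
                 filter_by_quadas(det, config$quadas_min))
    message("detection: ", nrow(det), " records after filtering")
    overall <- stage("detection pooling",
                     pool_proportions(det$positives, det$scanned,
                                      labels = det$study_id))
    by_tracer <- list()
    for (tr in intersect(c("C11", "F18"), unique(det$tracer))) {
      idx <- det$tracer == tr
      if (sum(idx) >= 2)
        by_tracer[[tr]] <- pool_proportions(det$positives[idx],
                                            det$scanned[idx],
                                            labels = det$study_id[idx])
    }
    strata <- intersect(.psa_levels, unique(det$psa_stratum))
    by_stratum <- list()
    stratum_cmp <- NULL
    for (ss in strata) {
      idx <- det$psa_stratum == ss
      if (sum(idx) < 2) next
      cell <- list(all = pool_proportions(det$positives[idx],
                                          det$scanned[idx],
                                          labels = det$study_id[idx]))
      for (tr in c("C11", "F18")) {
        jj <- idx & det$tracer == tr
        if (sum(jj) >= 2)
          cell[[tr]] <- pool_proportions(det$positives[jj], det$scanned[jj],
                                         labels = det$study_id[jj])
      }
      if (all(c("C11", "F18") %in% names(cell))) {
        cmp <- compare_subgroups(cell$C11, cell$F18, "C11", "F18")
        stratum_cmp <- rbind(stratum_cmp,
                             data.frame(psa_stratum = ss, z = cmp$z,
                                        p_value = cmp$p_value,
                                        stringsAsFactors = FALSE))
      }
      by_stratum[[ss]] <- cell
    }
    bundle$detection <- list(records = det, overall = overall,
                             by_tracer = by_tracer, by_stratum = by_stratum,
                             comparisons = stratum_cmp)
  }

  if (!is.null(eff)) {
    eff <- stage("quality filter (effect)",
                 filter_by_quadas(eff, config$quadas_min))
    le <- stage("effect transform", effect_to_log(eff))
    pool <- stage("effect pooling",
                  .gate_pool(le$log_or, le$se_log_or^2, "log",
                             config$het_rule, le$study_id))
    loo <- stage("leave-one-out",
                 leave_one_out(le$log_or, le$se_log_or^2, le$study_id,
                               scale = "log", model = pool$model))
    bundle$effect <- list(records = eff, log_effects = le, pool = pool,
                          leave_one_out = loo)
  }

  structure(bundle, class = "dta_report")
}

.fmt_pool_pct <- function(p)
  sprintf("%.2f%% (%.2f%%-%.2f%%)", 100 * p$point, 100 * p$ci_low, 100 * p$ci_high)
.fmt_pool_ratio <- function(p)
  sprintf("%.2f (%.2f-%.2f)", p$point, p$ci_low, p$ci_high)

.table1_df <- function(acc) {
  rows <- c(list(Overall = acc$pools), acc$by_tracer)
  out <- do.call(rbind, lapply(names(rows), function(nm) {
    p <- rows[[nm]]
    data.frame(subgroup = nm,
               k = p$dor$k,
               sens = p$sens$point, sens_lcl = p$sens$ci_low, sens_ucl = p$sens$ci_high,
               spec = p$spec$point, spec_lcl = p$spec$ci_low, spec_ucl = p$spec$ci_high,
               lr_pos = p$lr_pos$point, lr_pos_lcl = p$lr_pos$ci_low,
               lr_pos_ucl = p$lr_pos$ci_high,
               lr_neg = p$lr_neg$point, lr_neg_lcl = p$lr_neg$ci_low,
               lr_neg_ucl = p$lr_neg$ci_high,
               dor = p$dor$point, dor_lcl = p$dor$ci_low, dor_ucl = p$dor$ci_high,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

.table2_df <- function(det) {
  out <- NULL
  for (ss in names(det$by_stratum)) {
    cell <- det$by_stratum[[ss]]
    for (tr in names(cell)) {
      p <- cell[[tr]]
      out <- rbind(out, data.frame(
        psa_stratum = ss, tracer = tr, k = p$k,
        rate = p$point, rate_lcl = p$ci_low, rate_ucl = p$ci_high,
        stringsAsFactors = FALSE))
    }
  }
  out
}

#' Export the report tables of a pipeline run
#'
#' Writes plot- and publication-ready files into `dir`: the pooled-accuracy
#' table (`table1.csv`/`.md`, rows Overall and per tracer with subgroup
#' p-values), the detection-rate-by-stratum table (`table2.csv`/`.md`), the
#' summary ROC curve (`sroc_curve.csv`), Deeks' funnel coordinates
#' (`funnel.csv`), the leave-one-out table (`loo.csv`) and the full numeric
#' bundle (`report.json`, unrounded). Markdown tables round proportions to
#' two-decimal percentages, ratios to 2 decimals and p-values to 3.
#'
#' @param bundle a `dta_report` from [run_pipeline()].
#' @param dir output directory, created if absent.
#' @param formats subset of `c("csv", "md", "json")`.
#' @return invisibly, the paths written.
#' @export
render_tables <- function(bundle, dir, formats = c("csv", "md", "json")) {
  stopifnot(inherits(bundle, "dta_report"))
  formats <- match.arg(formats, several.ok = TRUE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  md <- function(lines, name) {
    p <- file.path(dir, name)
    writeLines(lines, p)
    paths <<- c(paths, p)
  }

  if (!is.null(bundle$accuracy)) {
    t1 <- .table1_df(bundle$accuracy)
    if ("csv" %in% formats) wr(t1, "table1.csv")
    if ("md" %in% formats) {
      rows <- c(list(Overall = bundle$accuracy$pools), bundle$accuracy$by_tracer)
      lines <- c("| Subgroup | Sensitivity (95% CI) | Specificity (95% CI) | LR+ (95% CI) | LR- (95% CI) | DOR (95% CI) |",
                 "|---|---|---|---|---|---|")
      for (nm in names(rows)) {
        p <- rows[[nm]]
        lines <- c(lines, sprintf("| %s | %s | %s | %s | %s | %s |", nm,
                                  .fmt_pool_pct(p$sens), .fmt_pool_pct(p$spec),
                                  .fmt_pool_ratio(p$lr_pos),
                                  .fmt_pool_ratio(p$lr_neg),
                                  .fmt_pool_ratio(p$dor)))
      }
      cmp <- bundle$accuracy$comparisons
      if (!is.null(cmp))
        lines <- c(lines, sprintf("| *P* (C11 vs F18) | %s |",
                                  paste(sprintf("%.3f", cmp$p_value),
                                        collapse = " | ")))
      md(lines, "table1.md")
    }
    if ("csv" %in% formats) {
      wr(bundle$sroc$curve, "sroc_curve.csv")
      wr(bundle$deeks$funnel_points, "funnel.csv")
    }
  }
  if (!is.null(bundle$detection)) {
    t2 <- .table2_df(bundle$detection)
    if (!is.null(t2) && "csv" %in% formats) wr(t2, "table2.csv")
    if (!is.null(t2) && "md" %in% formats) {
      lines <- c("| PSA stratum | Tracer | k | Detection rate (95% CI) |",
                 "|---|---|---|---|")
      for (i in seq_len(nrow(t2)))
        lines <- c(lines, sprintf("| %s | %s | %d | %.2f%% (%.2f%%-%.2f%%) |",
                                  t2$psa_stratum[i], t2$tracer[i], t2$k[i],
                                  100 * t2$rate[i], 100 * t2$rate_lcl[i],
                                  100 * t2$rate_ucl[i]))
      md(lines, "table2.md")
    }
  }
  if (!is.null(bundle$effect) && "csv" %in% formats)
    wr(as.data.frame(bundle$effect$leave_one_out), "loo.csv")
  if ("json" %in% formats) {
    p <- file.path(dir, "report.json")
    jsonlite::write_json(.bundle_to_list(bundle), p, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

.pooled_to_list <- function(p) {
  list(scale = p$scale, theta = p$theta, se = p$se, point = p$point,
       ci_low = p$ci_low, ci_high = p$ci_high, model = p$model, k = p$k,
       q = p$het$q, het_p = p$het$p_value, i_squared = p$het$i_squared,
       tau_squared = p$het$tau_squared)
}

.bundle_to_list <- function(bundle) {
  out <- list(meta = bundle$meta)
  if (!is.null(bundle$accuracy)) {
    pl <- function(x) lapply(x, .pooled_to_list)
    out$accuracy <- list(
      k = nrow(bundle$accuracy$studies),
      pools = pl(bundle$accuracy$pools),
      by_tracer = lapply(bundle$accuracy$by_tracer, pl),
      comparisons = bundle$accuracy$comparisons)
    out$sroc <- list(a = bundle$sroc$a, b = bundle$sroc$b,
                     se_a = bundle$sroc$se_a, se_b = bundle$sroc$se_b,
                     auc = bundle$sroc$auc, q_star = bundle$sroc$q_star,
                     se_q_star = bundle$sroc$se_q_star)
    out$deeks <- list(slope = bundle$deeks$slope,
                      intercept = bundle$deeks$intercept,
                      p_value = bundle$deeks$p_value)
  }
  if (!is.null(bundle$detection)) {
    out$detection <- list(
      overall = .pooled_to_list(bundle$detection$overall),
      by_tracer = lapply(bundle$detection$by_tracer, .pooled_to_list),
      by_stratum = lapply(bundle$detection$by_stratum,
                          function(cell) lapply(cell, .pooled_to_list)),
      comparisons = bundle$detection$comparisons)
  }
  if (!is.null(bundle$effect)) {
    out$effect <- list(pool = .pooled_to_list(bundle$effect$pool),
                       leave_one_out = as.data.frame(bundle$effect$leave_one_out))
  }
  out
}

#' @export
print.dta_report <- function(x, ...) {
  cat("Diagnostic test accuracy meta-analysis report\n")
  if (!is.null(x$accuracy)) {
    cat(sprintf("  accuracy: %d arms; pooled sens %.3f, spec %.3f, DOR %.2f\n",
                nrow(x$accuracy$studies), x$accuracy$pools$sens$point,
                x$accuracy$pools$spec$point, x$accuracy$pools$dor$point))
    cat(sprintf("  SROC: AUC %.4f, Q* %.4f; Deeks p %s\n",
                x$sroc$auc, x$sroc$q_star,
                if (is.na(x$deeks$p_value)) "NA" else sprintf("%.3f", x$deeks$p_value)))
  }
  if (!is.null(x$detection))
    cat(sprintf("  detection: %d records; pooled rate %.3f (I2 %.1f%%)\n",
                nrow(x$detection$records), x$detection$overall$point,
                x$detection$overall$het$i_squared))
  if (!is.null(x$effect))
    cat(sprintf("  odds ratio: k = %d; pooled OR %.3f (%s-effect)\n",
                x$effect$pool$k, x$effect$pool$point, x$effect$pool$model))
  invisible(x)
}
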