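#' Read study-level records from CSV
#'
#' Reads one of the three record kinds used throughout the package and
#' validates every row. Accuracy records carry a 2x2 contingency table
#' (tp/fp/fn/tn) per study arm; detection records carry positives/scanned
#' counts with a trigger-PSA stratum label; effect records carry an odds
#' (or hazard) ratio with its 95% confidence interval.
#'
#' Required columns:
#' \describe{
#'   \item{accuracy}{study_id, year, tracer, quadas_score, arm, tp, fp, fn, tn}
#'   \item{detection}{study_id, year, tracer, quadas_score, psa_stratum,
#'     positives, scanned}
#'   \item{effect}{study_id, year, tracer, quadas_score, or_point, or_lcl,
#'     or_ucl}
#' }
#'
#' `tracer` must be one of `"C11"`, `"F18"`, `"mixed"`; `psa_stratum` one of
#' `"lt0.5"`, `"lt1"`, `"lt1.5"`, `"gt2"`, `"gt3"`, `"gt4"`, `"gt5"`,
#' `"gt10"`, `"all"`. Unknown labels are rejected, not coerced.
#'
#' @param path path to a UTF-8 comma-separated file with a header row.
#' @param kind one of `"accuracy"`, `"detection"`, `"effect"`.
#' @return a validated `data.frame` of the requested kind.
#' @export
read_studies <- function(path, kind = c("accuracy", "detection", "effect")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no records in ", path)
  validate_studies(df, kind)
}

#' Validate a study-level data frame
#'
#' Applies the schema and invariant checks of [read_studies()] to an
#' in-memory data frame; errors name the offending row and column.
#'
#' @param df a data frame.
#' @param kind one of `"accuracy"`, `"detection"`, `"effect"`.
#' @return `df`, invisibly unchanged apart from column order checks.
#' @export
validate_studies <- function(df, kind = c("accuracy", "detection", "effect")) {
  kind <- match.arg(kind)
  schema <- switch(kind,
    accuracy  = c("study_id", "year", "tracer", "quadas_score", "arm",
                  "tp", "fp", "fn", "tn"),
    detection = c("study_id", "year", "tracer", "quadas_score", "psa_stratum",
                  "positives", "scanned"),
    effect    = c("study_id", "year", "tracer", "quadas_score",
                  "or_point", "or_lcl", "or_ucl"))
  missing <- setdiff(schema, names(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(df) == 0L) stop("no records")

  num_cols <- setdiff(schema, c("study_id", "tracer", "psa_stratum"))
  for (cc in num_cols) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[cc]]))))
    if (length(bad))
      stop(sprintf("non-numeric value in column '%s', row %d", cc, bad[1]))
    df[[cc]] <- as.numeric(df[[cc]])
  }
  if (any(!nzchar(df$study_id)))
    stop("empty study_id in row ", which(!nzchar(df$study_id))[1])
  bad_tr <- which(!df$tracer %in% .tracer_levels)
  if (length(bad_tr))
    stop(sprintf("unknown tracer '%s' in row %d (allowed: %s)",
                 df$tracer[bad_tr[1]], bad_tr[1],
                 paste(.tracer_levels, collapse = ", ")))
  bad_q <- which(df$quadas_score < 0 | df$quadas_score > 14)
  if (length(bad_q))
    stop("quadas_score outside [0, 14] in row ", bad_q[1])

  key <- switch(kind,
    accuracy  = paste(df$study_id, df$arm),
    detection = paste(df$study_id, df$psa_stratum),
    effect    = df$study_id)
  if (anyDuplicated(key))
    stop("duplicate record key in row ", which(duplicated(key))[1],
         " (", key[which(duplicated(key))[1]], ")")

  if (kind == "accuracy") {
    cells <- as.matrix(df[, c("tp", "fp", "fn", "tn")])
    neg <- which(rowSums(cells < 0) > 0)
    if (length(neg)) stop("negative cell count in row ", neg[1])
  } else if (kind == "detection") {
    bad_s <- which(!df$psa_stratum %in% .psa_levels)
    if (length(bad_s))
      stop(sprintf("unknown psa_stratum '%s' in row %d",
                   df$psa_stratum[bad_s[1]], bad_s[1]))
    if (any(df$scanned < 1)) stop("scanned < 1 in row ", which(df$scanned < 1)[1])
    bad_p <- which(df$positives > df$scanned | df$positives < 0)
    if (length(bad_p)) stop("positives > scanned in row ", bad_p[1])
  } else {
    bad_ci <- which(!(df$or_lcl < df$or_point & df$or_point < df$or_ucl))
    if (length(bad_ci)) stop("inverted or degenerate CI in row ", bad_ci[1])
    if (any(df$or_lcl <= 0)) stop("non-positive odds ratio bound in row ",
                                  which(df$or_lcl <= 0)[1])
  }
  df
}

#' Write study-level records to CSV
#'
#' Inverse of [read_studies()]: writes only the schema columns so that
#' reading the file back reproduces the records.
#'
#' @param df a validated study data frame.
#' @param path output path.
#' @param kind record kind, as in [read_studies()].
#' @return `path`, invisibly.
#' @export
write_studies <- function(df, path, kind = c("accuracy", "detection", "effect")) {
  kind <- match.arg(kind)
  df <- validate_studies(df, kind)
  schema <- switch(kind,
    accuracy  = c("study_id", "year", "tracer", "quadas_score", "arm",
                  "tp", "fp", "fn", "tn"),
    detection = c("study_id", "year", "tracer", "quadas_score", "psa_stratum",
                  "positives", "scanned"),
    effect    = c("study_id", "year", "tracer", "quadas_score",
                  "or_point", "or_lcl", "or_ucl"))
  utils::write.csv(df[, schema], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Zero-cell continuity correction
#'
#' Adds 0.5 to all four cells of any 2x2 table containing a zero count, the
#' standard correction that keeps odds-based quantities (DOR, likelihood
#' ratios) finite for studies with 100% sensitivity or specificity. Tables
#' without a zero cell are left untouched. A logical `corrected` column
#' records which rows were adjusted, so the original integer counts remain
#' recoverable (cell - 0.5 when corrected). The operation is idempotent.
#'
#' @param studies accuracy data frame with columns `tp`, `fp`, `fn`, `tn`.
#' @return the data frame with corrected cells and a `corrected` column.
#' @export
apply_continuity <- function(studies) {
  cells <- c("tp", "fp", "fn", "tn")
  if (!all(cells %in% names(studies)))
    stop("need columns tp, fp, fn, tn")
  m <- as.matrix(studies[, cells])
  if (any(m < 0)) stop("negative cell count")
  already <- if ("corrected" %in% names(studies)) studies$corrected else
    rep(FALSE, nrow(studies))
  raw <- m - 0.5 * already
  if (any(raw != round(raw)))
    stop("cell counts must be integers before correction")
  needs <- !already & apply(m == 0, 1L, any)
  m[needs, ] <- m[needs, ] + 0.5
  studies[, cells] <- m
  studies$corrected <- already | needs
  studies
}

#' Filter studies by QUADAS quality score
#'
#' Keeps studies whose count of "yes" answers on the 14-item QUADAS
#' checklist reaches `min_yes`. The default of 10 retains studies scoring
#' strictly more than 9 of 14.
#'
#' @param studies a study data frame with a `quadas_score` column.
#' @param min_yes minimum score to keep, in \[0, 14\].
#' @return the filtered data frame, original order preserved.
#' @export
filter_by_quadas <- function(studies, min_yes = 10) {
  if (!"quadas_score" %in% names(studies)) stop("need column quadas_score")
  if (min_yes < 0 || min_yes > 14) stop("min_yes must be in [0, 14]")
  keep <- studies$quadas_score >= min_yes
  removed <- sum(!keep)
  if (removed > 0)
    message(removed, " stud", if (removed == 1) "y" else "ies",
            " removed by QUADAS filter (score < ", min_yes, ")")
  out <- studies[keep, , drop = FALSE]
  if (nrow(out) == 0L) warning("no studies pass the QUADAS filter")
  out
}
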