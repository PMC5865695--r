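# build a minimal accuracy data frame around explicit 2x2 cells
make_accuracy <- function(tp, fp, fn, tn, tracer = "C11") {
  k <- length(tp)
  data.frame(
    study_id = sprintf("S%02d", seq_len(k)),
    year = 2010L, tracer = rep_len(tracer, k), quadas_score = 12L, arm = 1L,
    tp = tp, fp = fp, fn = fn, tn = tn,
    stringsAsFactors = FALSE)
}

# least-squares normal equations computed long-hand, optional weights
oracle_lsq <- function(x, y, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  sw <- sum(w)
  sxx <- sum(w * x^2) - sum(w * x)^2 / sw
  sxy <- sum(w * x * y) - sum(w * x) * sum(w * y) / sw
  b <- sxy / sxx
  a <- (sum(w * y) - b * sum(w * x)) / sw
  c(a = a, b = b)
}

# write a study data frame to a temporary CSV and return the path
tmp_csv <- function(df) {
  p <- tempfile(fileext = ".csv")
  utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
  p
}
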