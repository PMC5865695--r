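test_that("accuracy CSV rows map directly onto 2x2 records", {
  p <- tmp_csv(make_accuracy(tp = 5, fp = 3, fn = 2, tn = 18))
  df <- read_studies(p, "accuracy")
  expect_equal(nrow(df), 1L)
  expect_equal(unlist(df[1, c("tp", "fp", "fn", "tn")], use.names = FALSE),
               c(5, 3, 2, 18))
  expect_equal(df$tracer, "C11")
})

test_that("validation rejects malformed input with row-level messages", {
  det <- data.frame(study_id = "D1", year = 2012, tracer = "C11",
                    quadas_score = 11, psa_stratum = "lt1",
                    positives = 12, scanned = 10)
  expect_error(validate_studies(det, "detection"), "positives > scanned")

  empty <- tmp_csv(make_accuracy(5, 3, 2, 18)[0, ])
  expect_error(read_studies(empty, "accuracy"), "no records")

  expect_error(validate_studies(make_accuracy(5, 3, 2, 18)[, -6], "accuracy"),
               "missing column")

  dup <- make_accuracy(c(5, 5), c(3, 3), c(2, 2), c(18, 18))
  dup$study_id <- "S01"
  expect_error(validate_studies(dup, "accuracy"), "duplicate")

  bad_tracer <- make_accuracy(5, 3, 2, 18); bad_tracer$tracer <- "O15"
  expect_error(validate_studies(bad_tracer, "accuracy"), "unknown tracer")

  det$positives <- 5; det$psa_stratum <- "psa<7"
  expect_error(validate_studies(det, "detection"), "unknown psa_stratum")

  eff <- data.frame(study_id = "E1", year = 2012, tracer = "F18",
                    quadas_score = 11, or_point = 1.2, or_lcl = 1.5, or_ucl = 2)
  expect_error(validate_studies(eff, "effect"), "inverted")
})

test_that("read after write is the identity on all three record kinds", {
  acc <- simulate_accuracy(accuracy_sim_config(k = 8, seed = 3))
  det <- simulate_detection(detection_sim_config(k_per_stratum = 2, seed = 3))
  eff <- simulate_effects(k = 5, seed = 3)
  for (x in list(list(acc, "accuracy"), list(det, "detection"),
                 list(eff, "effect"))) {
    back <- read_studies(write_studies(x[[1]], tempfile(fileext = ".csv"),
                                       x[[2]]), x[[2]])
    expect_equal(back, x[[1]], tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("continuity correction follows the zero-cell rule and is idempotent", {
  df <- make_accuracy(tp = c(10, 8, 0), fp = c(0, 2, 0),
                      fn = c(2, 2, 0), tn = c(20, 18, 0))
  out <- apply_continuity(df)
  expect_equal(unlist(out[1, c("tp", "fp", "fn", "tn")], use.names = FALSE),
               c(10.5, 0.5, 2.5, 20.5))
  expect_equal(unlist(out[2, c("tp", "fp", "fn", "tn")], use.names = FALSE),
               c(8, 2, 2, 18))
  expect_equal(unlist(out[3, c("tp", "fp", "fn", "tn")], use.names = FALSE),
               rep(0.5, 4))
  expect_equal(out$corrected, c(TRUE, FALSE, TRUE))
  expect_identical(apply_continuity(out), out)

  expect_error(apply_continuity(make_accuracy(-1, 2, 3, 4)), "negative")
  half <- make_accuracy(1.5, 2, 3, 4)
  expect_error(apply_continuity(half), "integers")
})

test_that("continuity correction is idempotent on simulated datasets", {
  for (s in 1:5) {
    df <- simulate_accuracy(accuracy_sim_config(k = 15, tau_sens = 0.8,
                                                n_diseased_range = c(3, 30),
                                                n_nondiseased_range = c(3, 30),
                                                seed = s))
    once <- apply_continuity(df)
    expect_identical(apply_continuity(once), once)
    expect_true(all(once$tp + once$fn > 0 & once$fp + once$tn > 0))
  }
})

test_that("QUADAS filter applies the score threshold and preserves order", {
  df <- make_accuracy(rep(5, 4), rep(3, 4), rep(2, 4), rep(18, 4))
  df$quadas_score <- c(8, 9, 10, 14)
  kept <- suppressMessages(filter_by_quadas(df, 10))
  expect_equal(nrow(kept), 2L)
  expect_equal(kept$study_id, c("S03", "S04"))
  expect_identical(filter_by_quadas(df, 0), df)
  df$quadas_score <- rep(8, 4)
  expect_warning(suppressMessages(filter_by_quadas(df, 10)), "no studies")
  expect_error(filter_by_quadas(df, 15), "0, 14")
})
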