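# run expr under a local RNG state so generators are pure functions of seed
.with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Configuration for the accuracy-study generator
#'
#' Defaults describe a body of evidence like a typical PET/CT recurrence
#' meta-analysis: 29 study arms with mean sensitivity 0.82 and specificity
#' 0.92, moderate between-study spread on the logit scale (SD 0.3), a mild
#' negative logit-scale correlation (-0.3) encoding the threshold-driven
#' sensitivity/specificity trade-off, and arm sizes of 20-150 subjects.
#'
#' @param k number of study arms.
#' @param mu_sens,mu_spec true mean sensitivity and specificity in (0, 1).
#' @param tau_sens,tau_spec between-study SDs on the logit scale.
#' @param rho logit-scale correlation between sensitivity and specificity,
#'   in \[-1, 1\]; set 0 for independent draws.
#' @param n_diseased_range,n_nondiseased_range integer ranges (length-2,
#'   low/high) for the diseased and non-diseased arm sizes.
#' @param prop_c11 fraction of arms labelled with the C11 tracer (the rest
#'   are F18), used by subgroup analyses.
#' @param seed integer RNG seed.
#' @return an object of class `accuracy_sim_config`.
#' @export
accuracy_sim_config <- function(k = 29, mu_sens = 0.82, mu_spec = 0.92,
                                tau_sens = 0.3, tau_spec = 0.3, rho = -0.3,
                                n_diseased_range = c(20, 150),
                                n_nondiseased_range = c(20, 150),
                                prop_c11 = 0.6, seed = 1) {
  stopifnot(k >= 1, mu_sens > 0, mu_sens < 1, mu_spec > 0, mu_spec < 1,
            tau_sens >= 0, tau_spec >= 0, rho >= -1, rho <= 1,
            length(n_diseased_range) == 2, length(n_nondiseased_range) == 2,
            n_diseased_range[1] >= 1, n_diseased_range[1] <= n_diseased_range[2],
            n_nondiseased_range[1] >= 1,
            n_nondiseased_range[1] <= n_nondiseased_range[2],
            prop_c11 >= 0, prop_c11 <= 1)
  structure(list(k = k, mu_sens = mu_sens, mu_spec = mu_spec,
                 tau_sens = tau_sens, tau_spec = tau_spec, rho = rho,
                 n_diseased_range = n_diseased_range,
                 n_nondiseased_range = n_nondiseased_range,
                 prop_c11 = prop_c11, seed = seed),
            class = "accuracy_sim_config")
}

#' Simulate study-level accuracy data
#'
#' Draws per-study (logit sensitivity, logit specificity) pairs from a
#' bivariate normal with the configured means, SDs and correlation, draws
#' arm sizes uniformly from the configured ranges, then generates
#' `tp ~ Binomial(n_diseased, sens_i)` and `tn ~ Binomial(n_nondiseased,
#' spec_i)` with fn and fp as complements. Output is deterministic given the
#' config (including its seed) and satisfies the accuracy schema of
#' [read_studies()].
#'
#' @param config an [accuracy_sim_config()].
#' @return an accuracy data frame (study_id, year, tracer, quadas_score,
#'   arm, tp, fp, fn, tn).
#' @export
simulate_accuracy <- function(config) {
  stopifnot(inherits(config, "accuracy_sim_config"))
  .with_seed(config$seed, {
    k <- config$k
    z1 <- stats::rnorm(k)
    z2 <- stats::rnorm(k)
    l_sens <- stats::qlogis(config$mu_sens) + config$tau_sens * z1
    l_spec <- stats::qlogis(config$mu_spec) +
      config$tau_spec * (config$rho * z1 + sqrt(1 - config$rho^2) * z2)
    nd <- sample(config$n_diseased_range[1]:config$n_diseased_range[2], k,
                 replace = TRUE)
    nn <- sample(config$n_nondiseased_range[1]:config$n_nondiseased_range[2],
                 k, replace = TRUE)
    tp <- stats::rbinom(k, nd, stats::plogis(l_sens))
    tn <- stats::rbinom(k, nn, stats::plogis(l_spec))
    n_c11 <- round(config$prop_c11 * k)
    tracer <- sample(rep(c("C11", "F18"), c(n_c11, k - n_c11)))
    data.frame(
      study_id = sprintf("S%02d", seq_len(k)),
      year = sample(2005:2017, k, replace = TRUE),
      tracer = tracer,
      quadas_score = sample(10:14, k, replace = TRUE),
      arm = 1L,
      tp = tp, fp = nn - tn, fn = nd - tp, tn = tn,
      stringsAsFactors = FALSE)
  })
}

.default_psa_midpoints <- c(
  "lt0.5" = 0.25, "lt1" = 0.5, "lt1.5" = 0.75,
  "gt2" = 3, "gt3" = 4.5, "gt4" = 6, "gt5" = 7.5, "gt10" = 15)

#' Configuration for the detection-rate generator
#'
#' Study-level scan positivity rates follow a logistic model in log trigger
#' PSA: `logit(rate_i) = beta0 + beta1 * ln(midpoint) + N(0, tau)`. The
#' default coefficients (beta0 = -0.832, beta1 = 1.757) put the expected
#' rate near 4% at PSA 0.25 ng/ml, 21% at 0.75 ng/ml, 75% at 3 ng/ml and
#' 88% at 5 ng/ml — the characteristic low-below-1.5 / high-above-2 pattern
#' of choline PET/CT detection. Stratum midpoints are half the bound for
#' "<" strata and 1.5x the bound for open ">" strata.
#'
#' @param k_per_stratum number of study records per PSA stratum.
#' @param beta0,beta1 logistic intercept and slope on ln(PSA); `beta1 >= 0`
#'   encodes a detection rate that rises with trigger PSA.
#' @param tau between-study SD on the logit scale.
#' @param psa_strata named numeric vector of stratum midpoints (ng/ml);
#'   names must be valid stratum labels.
#' @param n_range length-2 integer range of per-study sample sizes.
#' @param prop_c11 fraction of records labelled C11.
#' @param seed integer RNG seed.
#' @return an object of class `detection_sim_config`.
#' @export
detection_sim_config <- function(k_per_stratum = 6, beta0 = -0.832,
                                 beta1 = 1.757, tau = 0.4,
                                 psa_strata = .default_psa_midpoints,
                                 n_range = c(30, 120), prop_c11 = 0.5,
                                 seed = 1) {
  stopifnot(k_per_stratum >= 1, beta1 >= 0, tau >= 0,
            length(psa_strata) >= 1, !is.null(names(psa_strata)),
            all(psa_strata > 0), length(n_range) == 2,
            n_range[1] >= 1, n_range[1] <= n_range[2])
  if (!all(names(psa_strata) %in% .psa_levels))
    stop("unknown stratum label(s): ",
         paste(setdiff(names(psa_strata), .psa_levels), collapse = ", "))
  structure(list(k_per_stratum = k_per_stratum, beta0 = beta0, beta1 = beta1,
                 tau = tau, psa_strata = psa_strata, n_range = n_range,
                 prop_c11 = prop_c11, seed = seed),
            class = "detection_sim_config")
}

#' Simulate study-level detection-rate data
#'
#' For each configured stratum midpoint m, draws `k_per_stratum` study-level
#' logit rates `beta0 + beta1 ln(m) + N(0, tau)` and binomial positive
#' counts. Deterministic given the config.
#'
#' @param config a [detection_sim_config()].
#' @return a detection data frame (study_id, year, tracer, quadas_score,
#'   psa_stratum, positives, scanned).
#' @export
simulate_detection <- function(config) {
  stopifnot(inherits(config, "detection_sim_config"))
  .with_seed(config$seed, {
    k <- config$k_per_stratum
    strata <- names(config$psa_strata)
    rows <- lapply(seq_along(strata), function(j) {
      m <- config$psa_strata[j]
      n <- sample(config$n_range[1]:config$n_range[2], k, replace = TRUE)
      lg <- config$beta0 + config$beta1 * log(m) + stats::rnorm(k, 0, config$tau)
      x <- stats::rbinom(k, n, stats::plogis(lg))
      n_c11 <- round(config$prop_c11 * k)
      data.frame(
        study_id = sprintf("D%s_%02d", gsub("[^0-9a-zA-Z]", "", strata[j]),
                           seq_len(k)),
        year = sample(2005:2017, k, replace = TRUE),
        tracer = sample(rep(c("C11", "F18"), c(n_c11, k - n_c11))),
        quadas_score = sample(10:14, k, replace = TRUE),
        psa_stratum = strata[j],
        positives = x, scanned = n,
        stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Simulate study-level odds-ratio records
#'
#' Draws study log odds ratios `N(true_log_or, se_i^2)` with standard
#' errors uniform on `se_range`, then back-computes the reported 95% CI as
#' `exp(log_or +/- 1.959964 se)`. Deterministic given the seed.
#'
#' @param k number of studies.
#' @param true_log_or common true log odds ratio; the default is
#'   `log(1.25)`, a modest positive PSA effect on scan positivity.
#' @param se_range length-2 range of per-study standard errors.
#' @param prop_c11 fraction of records labelled C11.
#' @param seed integer RNG seed.
#' @return an effect data frame (study_id, year, tracer, quadas_score,
#'   or_point, or_lcl, or_ucl).
#' @export
simulate_effects <- function(k = 9, true_log_or = log(1.25),
                             se_range = c(0.05, 0.5), prop_c11 = 0.5,
                             seed = 1) {
  stopifnot(k >= 2, length(se_range) == 2, se_range[1] > 0,
            se_range[1] <= se_range[2])
  .with_seed(seed, {
    se <- stats::runif(k, se_range[1], se_range[2])
    lo <- stats::rnorm(k, true_log_or, se)
    n_c11 <- round(prop_c11 * k)
    data.frame(
      study_id = sprintf("E%02d", seq_len(k)),
      year = sample(2005:2017, k, replace = TRUE),
      tracer = sample(rep(c("C11", "F18"), c(n_c11, k - n_c11))),
      quadas_score = sample(10:14, k, replace = TRUE),
      or_point = exp(lo),
      or_lcl = exp(lo - Z975 * se),
      or_ucl = exp(lo + Z975 * se),
      stringsAsFactors = FALSE)
  })
}
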