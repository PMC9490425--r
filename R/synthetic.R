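#' Define a synthetic two-sample instrument scenario
#'
#' Generative parameters for paired exposure/outcome per-SNP summary
#' statistics with known ground truth. True instrument strengths `gamma_k`
#' are drawn uniformly from `gamma_range` (exposure-SD units, kept away from
#' zero by default so tests are not confounded by weak-instrument
#' artifacts). A fraction `prop_invalid` of instruments receives a direct
#' (horizontally pleiotropic) effect `alpha_k` on the outcome: mean 0 under
#' balanced pleiotropy, mean `pleiotropy_mean` under directional
#' pleiotropy, sd `pleiotropy_sd` either way. Observed effects are
#' `beta_x ~ N(gamma_k, se_exposure^2)` and
#' `beta_y ~ N(theta_true * gamma_k + alpha_k, se_outcome^2)`.
#'
#' @param k_snps number of instruments (>= 1).
#' @param theta_true true causal slope, log-odds of outcome per SD exposure.
#' @param gamma_range length-2 interval of true instrument strengths.
#' @param se_exposure,se_outcome sampling standard errors; `0` is permitted
#'   as a degenerate noise-free switch for exact-recovery tests.
#' @param pleiotropy_mode `"none"`, `"balanced"` or `"directional"`.
#' @param pleiotropy_mean mean pleiotropic effect (directional mode only).
#' @param pleiotropy_sd sd of pleiotropic effects (>= 0).
#' @param prop_invalid fraction of instruments with pleiotropic effects.
#' @param seed integer seed; all randomness flows from it.
#' @return List of class `sim_scenario`.
#' @export
sim_scenario <- function(k_snps, theta_true, gamma_range = c(0.05, 0.15),
                         se_exposure = 0.01, se_outcome = 0.02,
                         pleiotropy_mode = c("none", "balanced", "directional"),
                         pleiotropy_mean = 0, pleiotropy_sd = 0,
                         prop_invalid = 0, seed = 1) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  if (!is_scalar_number(k_snps) || k_snps < 1 || k_snps != round(k_snps)) {
    stop("`k_snps` must be a positive integer", call. = FALSE)
  }
  if (!is_scalar_number(theta_true)) stop("`theta_true` must be a number", call. = FALSE)
  if (length(gamma_range) != 2L || !all(is.finite(gamma_range)) ||
      gamma_range[1] > gamma_range[2]) {
    stop("`gamma_range` must be a non-decreasing length-2 interval", call. = FALSE)
  }
  if (!is_scalar_number(se_exposure) || se_exposure < 0 ||
      !is_scalar_number(se_outcome) || se_outcome < 0) {
    stop("standard errors must be >= 0", call. = FALSE)
  }
  if (!is_scalar_number(prop_invalid) || prop_invalid < 0 || prop_invalid > 1) {
    stop("`prop_invalid` must lie in [0,1]", call. = FALSE)
  }
  if (!is_scalar_number(pleiotropy_sd) || pleiotropy_sd < 0) {
    stop("`pleiotropy_sd` must be >= 0", call. = FALSE)
  }
  if (pleiotropy_mode == "none" &&
      (pleiotropy_mean != 0 || pleiotropy_sd != 0 || prop_invalid != 0)) {
    stop("pleiotropy_mode 'none' requires pleiotropy_mean = pleiotropy_sd = ",
         "prop_invalid = 0", call. = FALSE)
  }
  if (pleiotropy_mode == "balanced" && pleiotropy_mean != 0) {
    stop("balanced pleiotropy requires pleiotropy_mean = 0", call. = FALSE)
  }
  structure(list(k_snps = as.integer(k_snps), theta_true = theta_true,
                 gamma_range = as.numeric(gamma_range),
                 se_exposure = se_exposure, se_outcome = se_outcome,
                 pleiotropy_mode = pleiotropy_mode,
                 pleiotropy_mean = pleiotropy_mean,
                 pleiotropy_sd = pleiotropy_sd,
                 prop_invalid = prop_invalid, seed = as.integer(seed)),
            class = "sim_scenario")
}

#' Simulate a harmonized two-sample instrument set
#'
#' Draws one realization of the scenario. The result is already expressed on
#' a common effect allele, so it enters the estimators exactly as a
#' harmonized real-data set would. When a scenario standard error is 0 the
#' corresponding observed betas are noise-free and the stored SE column is
#' set to 1 (equal weights), a degenerate switch used by exact-recovery
#' tests.
#'
#' @param s a [sim_scenario()].
#' @return List of class `sim_result`: `instruments` (a `harmonized_set`),
#'   `truth` (the scenario), `gamma` and `alpha` (per-SNP true strengths
#'   and pleiotropic effects).
#' @export
simulate_instruments <- function(s) {
  stopifnot(inherits(s, "sim_scenario"))
  k <- s$k_snps
  with_seed(s$seed, {
    gamma <- stats::runif(k, s$gamma_range[1], s$gamma_range[2])
    alpha <- numeric(k)
    n_invalid <- round(s$prop_invalid * k)
    if (n_invalid > 0) {
      idx <- sample.int(k, n_invalid)
      mu <- if (s$pleiotropy_mode == "directional") s$pleiotropy_mean else 0
      alpha[idx] <- stats::rnorm(n_invalid, mu, s$pleiotropy_sd)
    }
    bx <- stats::rnorm(k, gamma, s$se_exposure)
    by <- stats::rnorm(k, s$theta_true * gamma + alpha, s$se_outcome)
    inst <- harmonized_set(
      data.frame(SNP = sprintf("snp_%03d", seq_len(k)), EA = "A",
                 BETA_EXP = bx,
                 SE_EXP = if (s$se_exposure > 0) s$se_exposure else 1,
                 BETA_OUT = by,
                 SE_OUT = if (s$se_outcome > 0) s$se_outcome else 1,
                 STATUS = "kept", stringsAsFactors = FALSE),
      exposure_name = "sim_exposure", outcome_name = "sim_outcome")
    structure(list(instruments = inst, truth = s, gamma = gamma,
                   alpha = alpha),
              class = "sim_result")
  })
}

#' Monte-Carlo benchmark of the MR estimators
#'
#' Runs seeded replicates of a scenario and summarizes, per method, the
#' bias, empirical standard error, confidence-interval coverage of the true
#' slope, and rejection rate of the causal null at level `alpha`. Two
#' further diagnostic rows report pleiotropy-detection power: the rejection
#' rates of the Egger-intercept test and of Cochran's Q. Replicate seeds are
#' split deterministically from the scenario seed, so the full table is
#' reproducible.
#'
#' @param s a [sim_scenario()]; its `seed` drives the whole benchmark.
#' @param n_reps number of replicates (>= 100).
#' @param methods subset of `c("ivw_fixed", "ivw_mre", "weighted_median",
#'   "egger")` to benchmark; Q is always reported.
#' @param n_boot bootstrap replicates for the weighted median (the default
#'   is reduced relative to [mr_weighted_median()] because the bootstrap
#'   runs inside every replicate).
#' @param alpha test level for rejection rates and CI coverage.
#' @return Data frame with columns `method`, `n_reps`, `bias`,
#'   `empirical_se`, `mean_se`, `coverage`, `rejection_rate`. Rows
#'   `egger_intercept` and `cochran_q` carry detection power in
#'   `rejection_rate` (coverage/bias refer to the intercept's own target,
#'   0 under no pleiotropy).
#' @export
estimator_benchmark <- function(s, n_reps,
                                methods = c("ivw_fixed", "ivw_mre",
                                            "weighted_median", "egger"),
                                n_boot = 200, alpha = 0.05) {
  stopifnot(inherits(s, "sim_scenario"))
  if (!is_scalar_number(n_reps) || n_reps < 100) {
    stop("`n_reps` must be at least 100", call. = FALSE)
  }
  methods <- match.arg(methods, several.ok = TRUE)
  seeds <- derive_seeds(s$seed, 2L * n_reps)
  z <- stats::qnorm(1 - alpha / 2)

  collect <- c(methods[methods != "egger"],
               if ("egger" %in% methods) c("egger_slope", "egger_intercept"),
               "cochran_q")
  est <- matrix(NA_real_, n_reps, length(collect),
                dimnames = list(NULL, collect))
  se <- est
  pval <- est

  for (r in seq_len(n_reps)) {
    srep <- s
    srep$seed <- seeds[r]
    sim <- simulate_instruments(srep)
    h <- sim$instruments
    record <- function(name, e) {
      est[r, name] <<- e$beta; se[r, name] <<- e$se; pval[r, name] <<- e$pvalue
    }
    if ("ivw_fixed" %in% methods) record("ivw_fixed", mr_ivw(h, "fixed"))
    if ("ivw_mre" %in% methods) {
      record("ivw_mre", mr_ivw(h, "multiplicative_random"))
    }
    if ("weighted_median" %in% methods) {
      record("weighted_median",
             suppressWarnings(mr_weighted_median(h, n_boot = n_boot,
                                                 seed = seeds[n_reps + r])))
    }
    if ("egger" %in% methods) {
      eg <- mr_egger(h)
      record("egger_slope", eg$slope)
      record("egger_intercept", eg$intercept)
    }
    q <- cochran_q(h)
    est[r, "cochran_q"] <- q$q_stat
    pval[r, "cochran_q"] <- q$pvalue
  }

  truth <- ifelse(collect %in% c("egger_intercept", "cochran_q"),
                  0, s$theta_true)
  rows <- lapply(seq_along(collect), function(j) {
    m <- collect[j]
    covered <- if (m == "cochran_q") NA_real_ else {
      mean(est[, m] - z * se[, m] <= truth[j] &
             truth[j] <= est[, m] + z * se[, m])
    }
    data.frame(method = m, n_reps = n_reps,
               bias = if (m == "cochran_q") NA_real_ else mean(est[, m]) - truth[j],
               empirical_se = if (m == "cochran_q") NA_real_ else stats::sd(est[, m]),
               mean_se = if (m == "cochran_q") NA_real_ else mean(se[, m]),
               coverage = covered,
               rejection_rate = mean(pval[, m] < alpha),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
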