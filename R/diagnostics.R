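#' Cochran's Q heterogeneity statistic
#'
#' Measures dispersion of the per-SNP Wald ratios around the fixed-effect
#' IVW estimate: `Q = sum(((theta_k - theta_ivw) / se_k)^2)` with `se_k` the
#' Wald-ratio standard error. Under instrument validity Q follows a
#' chi-square distribution with K - 1 degrees of freedom; excess Q signals
#' heterogeneity, a symptom of invalid (e.g. pleiotropic) instruments.
#'
#' @param h a `harmonized_set` with at least 2 usable instruments.
#' @return List of class `heterogeneity_result` with `q_stat`, `df`,
#'   `pvalue`, `n_snps`.
#' @export
cochran_q <- function(h) {
  d <- usable_instruments(h)
  k <- nrow(d)
  if (k < 2L) stop("Cochran's Q requires at least 2 instruments", call. = FALSE)
  wr <- wald_ratio(h)
  center <- mr_ivw(h, model = "fixed")$beta
  q <- sum(((wr$theta - center) / wr$se)^2)
  structure(list(q_stat = q, df = k - 1L,
                 pvalue = stats::pchisq(q, df = k - 1L, lower.tail = FALSE),
                 n_snps = k),
            class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.3f, df = %d, p = %.3g (K = %d)\n",
              x$q_stat, x$df, x$pvalue, x$n_snps))
  invisible(x)
}

#' Leave-one-out IVW analysis
#'
#' Recomputes the IVW estimate K times, each time excluding one instrument,
#' to expose single variants that drive the pooled estimate.
#'
#' @param h a `harmonized_set` with at least 3 usable instruments.
#' @param model IVW variant passed to [mr_ivw()].
#' @return Data frame with one row per excluded instrument (in input order):
#'   `excluded_id` plus the [mr_ivw()] estimate columns for the remaining
#'   K - 1 instruments.
#' @export
leave_one_out <- function(h, model = "fixed") {
  d <- usable_instruments(h)
  k <- nrow(d)
  if (k < 3L) {
    stop("leave-one-out requires at least 3 instruments", call. = FALSE)
  }
  rows <- lapply(seq_len(k), function(i) {
    est <- mr_ivw(harmonized_set(d[-i, , drop = FALSE],
                                 exposure_name = attr(h, "exposure_name"),
                                 outcome_name = attr(h, "outcome_name")),
                  model = model)
    cbind(data.frame(excluded_id = d$SNP[i], stringsAsFactors = FALSE),
          as.data.frame(est))
  })
  do.call(rbind, rows)
}

#' Single-SNP forest-plot table
#'
#' One odds-ratio row per instrument (its Wald ratio with CI) plus a pooled
#' IVW row, the numeric content of a forest plot.
#'
#' @param h a `harmonized_set` with at least 1 usable instrument.
#' @param model IVW variant for the pooled row.
#' @param ci_level confidence level.
#' @return Data frame with columns `SNP`, `beta`, `se`, `odds_ratio`,
#'   `ci_low`, `ci_high`, `pooled`.
#' @export
single_snp_forest <- function(h, model = "fixed", ci_level = 0.95) {
  wr <- wald_ratio(h)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  per_snp <- data.frame(SNP = wr$SNP, beta = wr$theta, se = wr$se,
                        odds_ratio = exp(wr$theta),
                        ci_low = exp(wr$theta - z * wr$se),
                        ci_high = exp(wr$theta + z * wr$se),
                        pooled = FALSE, stringsAsFactors = FALSE)
  est <- mr_ivw(h, model = model, ci_level = ci_level)
  pooled <- data.frame(SNP = "All - IVW", beta = est$beta, se = est$se,
                       odds_ratio = est$odds_ratio, ci_low = est$ci_low,
                       ci_high = est$ci_high, pooled = TRUE,
                       stringsAsFactors = FALSE)
  rbind(per_snp, pooled)
}

#' Scatter-plot data for harmonized instruments and fitted lines
#'
#' Returns the per-SNP effect pairs (oriented to non-negative exposure
#' betas) and one fitted line per estimator: slope through the origin for
#' IVW and the weighted median, slope plus free intercept for MR-Egger.
#'
#' @param h a `harmonized_set`.
#' @param fits a list of `mr_estimate` rows (and/or the list returned by
#'   [mr_egger()]), e.g. `list(mr_ivw(h), mr_egger(h))`.
#' @return List with `points` (columns `SNP`, `beta_exposure`,
#'   `se_exposure`, `beta_outcome`, `se_outcome`) and `lines` (columns
#'   `method`, `slope`, `intercept`).
#' @export
scatter_data <- function(h, fits) {
  if (length(fits) == 0L) stop("`fits` must be nonempty", call. = FALSE)
  d <- usable_instruments(h)
  flip <- sign(d$BETA_EXP)
  flip[flip == 0] <- 1
  points <- data.frame(SNP = d$SNP,
                       beta_exposure = d$BETA_EXP * flip,
                       se_exposure = d$SE_EXP,
                       beta_outcome = d$BETA_OUT * flip,
                       se_outcome = d$SE_OUT, stringsAsFactors = FALSE)
  flat <- list()
  for (f in fits) {
    if (inherits(f, "mr_estimate")) flat <- c(flat, list(f))
    else if (is.list(f)) flat <- c(flat, Filter(function(x) inherits(x, "mr_estimate"), f))
  }
  egger_int <- NA_real_
  for (f in flat) if (f$method == "egger_intercept") egger_int <- f$beta
  lines <- do.call(rbind, lapply(flat, function(f) {
    if (f$method == "egger_intercept") return(NULL)
    data.frame(method = f$method, slope = f$beta,
               intercept = if (f$method == "egger_slope") egger_int else 0,
               stringsAsFactors = FALSE)
  }))
  list(points = points, lines = lines)
}
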