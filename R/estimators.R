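#' Per-SNP Wald ratio estimates
#'
#' For each usable instrument the causal effect of the exposure on the
#' outcome is estimated as the ratio of the outcome and exposure per-allele
#' effects, `theta_k = beta_outcome / beta_exposure`, with first-order
#' standard error `se_outcome / |beta_exposure|` (exposure-side measurement
#' error ignored, the usual no-measurement-error assumption).
#'
#' @param h a `harmonized_set` (see [harmonize_sets()]).
#' @return Data frame with columns `SNP`, `theta`, `se`, one row per usable
#'   instrument in input order.
#' @export
wald_ratio <- function(h) {
  d <- usable_instruments(h)
  if (nrow(d) == 0L) stop("no usable instruments", call. = FALSE)
  if (any(d$BETA_EXP == 0)) {
    stop("degenerate instrument(s) with beta_exposure = 0: ",
         paste(d$SNP[d$BETA_EXP == 0], collapse = ", "), call. = FALSE)
  }
  data.frame(SNP = d$SNP,
             theta = d$BETA_OUT / d$BETA_EXP,
             se = d$SE_OUT / abs(d$BETA_EXP),
             stringsAsFactors = FALSE)
}

#' Convert a log-odds estimate to an odds ratio with confidence interval
#'
#' @param beta estimate on the log-odds scale.
#' @param se standard error, > 0.
#' @param ci_level confidence level (default 0.95); bounds use the two-sided
#'   normal quantile.
#' @return List with `odds_ratio`, `ci_low`, `ci_high`.
#' @export
to_odds_ratio <- function(beta, se, ci_level = 0.95) {
  if (!is_scalar_number(se) || se <= 0) {
    stop("`se` must be a positive number", call. = FALSE)
  }
  if (!is_scalar_number(ci_level) || ci_level <= 0 || ci_level >= 1) {
    stop("`ci_level` must lie in (0,1)", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  list(odds_ratio = exp(beta), ci_low = exp(beta - z * se),
       ci_high = exp(beta + z * se))
}

# One-row MR result on the log-odds scale plus its OR-scale report.
mr_estimate <- function(method, n_snps, beta, se, pvalue, ci_level = 0.95) {
  or <- to_odds_ratio(beta, se, ci_level)
  structure(data.frame(method = method, n_snps = as.integer(n_snps),
                       beta = beta, se = se,
                       odds_ratio = or$odds_ratio, ci_low = or$ci_low,
                       ci_high = or$ci_high, pvalue = pvalue,
                       ci_level = ci_level, stringsAsFactors = FALSE),
            class = c("mr_estimate", "data.frame"))
}

#' Inverse-variance weighted (IVW) estimator
#'
#' Pools the instruments into one causal estimate
#' `beta = sum(bx * by / sy^2) / sum(bx^2 / sy^2)`, equivalently the
#' precision-weighted average of the per-SNP Wald ratios. The fixed-effect
#' standard error is the closed form `1 / sqrt(sum(bx^2 / sy^2))`; the
#' multiplicative random-effects variant inflates it by
#' `max(1, sqrt(Q / (K - 1)))` where `Q` is Cochran's heterogeneity
#' statistic. P-values are two-sided normal.
#'
#' @param h a `harmonized_set`.
#' @param model `"fixed"` or `"multiplicative_random"`.
#' @param ci_level confidence level for the odds-ratio interval.
#' @return An `mr_estimate` row (method `ivw_fixed` or `ivw_mre`).
#' @export
mr_ivw <- function(h, model = c("fixed", "multiplicative_random"),
                   ci_level = 0.95) {
  model <- match.arg(model)
  d <- usable_instruments(h)
  k <- nrow(d)
  if (k < 1L) stop("IVW requires at least one instrument", call. = FALSE)
  if (any(d$BETA_EXP == 0)) {
    stop("degenerate instrument(s) with beta_exposure = 0", call. = FALSE)
  }
  w <- d$BETA_EXP^2 / d$SE_OUT^2
  beta <- sum(d$BETA_EXP * d$BETA_OUT / d$SE_OUT^2) / sum(w)
  se <- 1 / sqrt(sum(w))
  method <- "ivw_fixed"
  if (model == "multiplicative_random") {
    if (k == 1L) {
      warning("single instrument: multiplicative random-effects IVW falls ",
              "back to fixed-effect", call. = FALSE)
    } else {
      theta <- d$BETA_OUT / d$BETA_EXP
      se_theta <- d$SE_OUT / abs(d$BETA_EXP)
      q <- sum(((theta - beta) / se_theta)^2)
      se <- se * max(1, sqrt(q / (k - 1)))
      method <- "ivw_mre"
    }
  }
  p <- 2 * stats::pnorm(-abs(beta / se))
  mr_estimate(method, k, beta, se, p, ci_level)
}

# Interpolated weighted median of ratios `theta` with weights `w`:
# order the ratios, form cumulative midpoints p_j = (S_j - w_j/2) / S_K,
# and linearly interpolate theta at p = 0.5.
weighted_median_point <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]
  w <- w[ord] / sum(w)
  s <- cumsum(w)
  p <- s - w / 2
  if (0.5 <= p[1L]) return(theta[1L])
  k <- length(theta)
  if (0.5 >= p[k]) return(theta[k])
  j <- max(which(p <= 0.5))
  theta[j] + (theta[j + 1L] - theta[j]) * (0.5 - p[j]) / (p[j + 1L] - p[j])
}

#' Weighted median estimator
#'
#' The weighted median of the per-SNP Wald ratios, weighting each ratio by
#' its inverse variance. It is consistent when at least half the weight
#' comes from valid instruments, making it the standard sensitivity
#' analysis against a minority of pleiotropic SNPs. The standard error is
#' obtained by a seeded parametric bootstrap: exposure and outcome betas are
#' resampled from normal distributions at their reported standard errors and
#' the weighted median recomputed.
#'
#' @param h a `harmonized_set` with at least 3 usable instruments.
#' @param n_boot bootstrap replicates (default 5000; fewer than 100 warns).
#' @param seed integer seed making the bootstrap reproducible.
#' @param ci_level confidence level for the odds-ratio interval.
#' @return An `mr_estimate` row (method `weighted_median`).
#' @export
mr_weighted_median <- function(h, n_boot = 5000, seed = 1, ci_level = 0.95) {
  d <- usable_instruments(h)
  k <- nrow(d)
  if (k < 3L) {
    stop("weighted median requires at least 3 instruments", call. = FALSE)
  }
  if (any(d$BETA_EXP == 0)) {
    stop("degenerate instrument(s) with beta_exposure = 0", call. = FALSE)
  }
  if (n_boot < 100) {
    warning("n_boot < 100 gives an unstable bootstrap standard error",
            call. = FALSE)
  }
  theta <- d$BETA_OUT / d$BETA_EXP
  w <- (d$BETA_EXP / d$SE_OUT)^2   # 1 / Wald-ratio variance
  beta <- weighted_median_point(theta, w)
  boot <- with_seed(seed, {
    bx <- matrix(stats::rnorm(k * n_boot, d$BETA_EXP, d$SE_EXP), nrow = k)
    by <- matrix(stats::rnorm(k * n_boot, d$BETA_OUT, d$SE_OUT), nrow = k)
    vapply(seq_len(n_boot), function(j) {
      weighted_median_point(by[, j] / bx[, j], (bx[, j] / d$SE_OUT)^2)
    }, numeric(1))
  })
  se <- stats::sd(boot)
  p <- 2 * stats::pnorm(-abs(beta / se))
  mr_estimate("weighted_median", k, beta, se, p, ci_level)
}

#' MR-Egger regression
#'
#' Weighted least-squares regression of the outcome betas on the exposure
#' betas with inverse outcome-variance weights and a free intercept, after
#' orienting every instrument to a non-negative exposure beta. The intercept
#' estimates the average directional (unbalanced) pleiotropic effect; the
#' slope is a causal estimate robust to such pleiotropy under the InSIDE
#' assumption. Both are tested against zero with the t distribution on
#' K - 2 degrees of freedom; the residual scale is floored at 1 so the
#' standard errors never undercut the fixed-effect weighting (the
#' multiplicative random-effects convention).
#'
#' @param h a `harmonized_set` with at least 3 usable instruments.
#' @param ci_level confidence level for the slope's odds-ratio interval.
#' @return List with elements `slope` and `intercept`, each an `mr_estimate`
#'   row (methods `egger_slope`, `egger_intercept`).
#' @export
mr_egger <- function(h, ci_level = 0.95) {
  d <- usable_instruments(h)
  k <- nrow(d)
  if (k < 3L) stop("MR-Egger requires at least 3 instruments", call. = FALSE)
  flip <- sign(d$BETA_EXP)
  flip[flip == 0] <- 1
  bx <- d$BETA_EXP * flip
  by <- d$BETA_OUT * flip
  if (stats::var(bx) == 0) {
    stop("oriented exposure betas have zero variance; Egger regression is ",
         "unidentified", call. = FALSE)
  }
  fit <- stats::lm(by ~ bx, weights = 1 / d$SE_OUT^2)
  sm <- summary(fit)
  est <- sm$coefficients[, "Estimate"]
  se <- sm$coefficients[, "Std. Error"] / min(1, sm$sigma)
  p <- 2 * stats::pt(-abs(est / se), df = k - 2)
  list(slope = mr_estimate("egger_slope", k, est[["bx"]], se[["bx"]],
                           p[["bx"]], ci_level),
       intercept = mr_estimate("egger_intercept", k, est[["(Intercept)"]],
                               se[["(Intercept)"]], p[["(Intercept)"]],
                               ci_level))
}
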