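# Independent brute-force oracles and fixture builders. These deliberately
# avoid the package's code paths: explicit sums, normal equations solved
# with solve(), and approx()-based interpolation.

oracle_ivw <- function(bx, by, sy) {
  num <- 0; den <- 0
  for (k in seq_along(bx)) {
    num <- num + bx[k] * by[k] / sy[k]^2
    den <- den + bx[k]^2 / sy[k]^2
  }
  list(beta = num / den, se = 1 / sqrt(den))
}

# Weighted normal equations with a free intercept, instruments oriented to
# non-negative exposure betas first.
oracle_egger <- function(bx, by, sy) {
  s <- ifelse(bx < 0, -1, 1)
  bx <- bx * s; by <- by * s
  X <- cbind(1, bx)
  W <- diag(1 / sy^2)
  coefs <- solve(t(X) %*% W %*% X, t(X) %*% W %*% by)
  list(intercept = coefs[1], slope = coefs[2])
}

# Weighted median via approx() over the cumulative weight midpoints.
oracle_weighted_median <- function(theta, w) {
  o <- order(theta)
  theta <- theta[o]; w <- w[o] / sum(w)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1]) return(theta[1])
  if (0.5 >= p[length(p)]) return(theta[length(theta)])
  stats::approx(p, theta, xout = 0.5)$y
}

oracle_q <- function(bx, by, sy) {
  center <- oracle_ivw(bx, by, sy)$beta
  q <- 0
  for (k in seq_along(bx)) {
    theta_k <- by[k] / bx[k]
    se_k <- sy[k] / abs(bx[k])
    q <- q + ((theta_k - center) / se_k)^2
  }
  q
}

# A random usable harmonized set (no zero exposure betas).
rand_h <- function(k, seed) {
  set.seed(seed)
  harmonized_set(data.frame(
    SNP = paste0("rs", seq_len(k)),
    EA = sample(c("A", "C", "G", "T"), k, replace = TRUE),
    BETA_EXP = sample(c(-1, 1), k, replace = TRUE) * runif(k, 0.03, 0.3),
    SE_EXP = runif(k, 0.005, 0.03),
    BETA_OUT = rnorm(k, 0, 0.05),
    SE_OUT = runif(k, 0.005, 0.05),
    stringsAsFactors = FALSE))
}

make_h <- function(bx, by, sy, sx = 0.01,
                   snp = paste0("rs", seq_along(bx), recycle0 = TRUE)) {
  k <- length(bx)
  harmonized_set(data.frame(SNP = as.character(snp),
                            EA = rep("A", k),
                            BETA_EXP = as.numeric(bx),
                            SE_EXP = rep_len(sx, k),
                            BETA_OUT = as.numeric(by),
                            SE_OUT = rep_len(sy, k),
                            stringsAsFactors = FALSE))
}

# A small exposure study-set table (glycine-instrument-like: 23 rows).
make_exposure_table <- function(n = 23, trait = "exposure", seed = 11,
                                p_max = 1e-9, id_offset = 1000) {
  set.seed(seed)
  pairs <- list(c("A", "G"), c("C", "T"), c("G", "T"), c("A", "C"))
  al <- pairs[sample.int(4, n, replace = TRUE)]
  study_set(data.frame(
    SNP = paste0("rs", id_offset + seq_len(n)),
    CHR = sample(1:22, n, replace = TRUE),
    POS = sample.int(1e8, n),
    EA = vapply(al, `[`, "", 1),
    OA = vapply(al, `[`, "", 2),
    EAF = runif(n, 0.05, 0.95),
    BETA = rnorm(n, 0, 0.08),
    SE = runif(n, 0.005, 0.02),
    P = runif(n, 1e-12, p_max),
    stringsAsFactors = FALSE), trait_name = trait, role = "exposure")
}

# An outcome study set covering (a subset of) the exposure's variants.
make_outcome_table <- function(exposure, trait = "outcome", seed = 12,
                               drop = character()) {
  set.seed(seed)
  d <- as.data.frame(exposure)
  d <- d[!(d$SNP %in% drop), , drop = FALSE]
  d$BETA <- rnorm(nrow(d), 0.25 * d$BETA, 0.02)
  d$SE <- runif(nrow(d), 0.01, 0.03)
  d$P <- pmin(1, 2 * pnorm(-abs(d$BETA / d$SE)))
  study_set(d, trait_name = trait, role = "outcome")
}
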