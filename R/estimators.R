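.Z95 <- 1.959964

# Smallest reportable two-sided p; p-values are floored, never 0.
.p_two_sided <- function(z) {
  p <- 2 * pnorm(-abs(z))
  pmax(p, .Machine$double.xmin)
}

# Assemble the common one-row estimate record with the OR block.
mr_row <- function(method, beta, se, n_snp, q = NA_real_, q_df = NA_real_,
                   q_pval = NA_real_, extra = NULL) {
  row <- data.frame(
    method = method, n_snp = n_snp, beta = beta, se = se,
    pval = .p_two_sided(beta / se),
    or = exp(beta), or_lo = exp(beta - .Z95 * se), or_hi = exp(beta + .Z95 * se),
    q = q, q_df = q_df, q_pval = q_pval,
    stringsAsFactors = FALSE)
  if (!is.null(extra)) row <- cbind(row, extra)
  class(row) <- c("mr_result", "data.frame")
  row
}

#' Per-SNP Wald ratio estimates
#'
#' ratio = beta_out / beta_exp with the first-order delta-method SE
#' `se_out / |beta_exp|`; the IVW weight is `1/se_ratio^2`. A
#' second-order SE accounting for exposure uncertainty is available via
#' `second_order = TRUE`.
#'
#' @param hs A `harmonized_set` (or data.frame with `beta_exp, se_exp,
#'   beta_out, se_out, snp`).
#' @param second_order Use the second-order delta SE.
#' @return data.frame `snp, ratio, se, weight`.
#' @export
wald_ratios <- function(hs, second_order = FALSE) {
  if (any(hs$beta_exp == 0)) {
    stop("zero exposure effect; enforce the F-statistic filter upstream")
  }
  ratio <- hs$beta_out / hs$beta_exp
  se <- hs$se_out / abs(hs$beta_exp)
  if (second_order) {
    se <- sqrt(hs$se_out^2 / hs$beta_exp^2 +
               hs$beta_out^2 * hs$se_exp^2 / hs$beta_exp^4)
  }
  data.frame(snp = hs$snp, ratio = ratio, se = se, weight = 1 / se^2,
             stringsAsFactors = FALSE)
}

#' Single-SNP Wald ratio test
#'
#' @param hs A one-row harmonized set.
#' @return One-row `mr_result`.
#' @export
mr_wald <- function(hs) {
  r <- wald_ratios(hs)
  mr_row("wald", r$ratio[1], r$se[1], 1L)
}

#' Inverse-variance weighted estimate with multiplicative random effects
#'
#' The IVW estimate is the precision-weighted mean of the per-SNP Wald
#' ratios; Cochran's Q over the ratios yields the dispersion
#' `phi = max(1, Q/(J-1))` which multiplies the fixed-effect variance
#' (the multiplicative-random-effects model; `phi` never deflates the SE
#' below its fixed-effect value). With one SNP the estimate degrades to
#' the Wald ratio and is flagged.
#'
#' @param hs A `harmonized_set`.
#' @param ratios Optionally, precomputed [wald_ratios()] output.
#' @return One-row `mr_result` with Q block and `phi`.
#' @export
mr_ivw <- function(hs = NULL, ratios = NULL) {
  r <- if (is.null(ratios)) wald_ratios(hs) else ratios
  J <- nrow(r)
  if (J < 1) stop("no ratios supplied")
  if (J == 1) {
    row <- mr_row("wald", r$ratio[1], r$se[1], 1L,
                  extra = data.frame(phi = NA_real_, degraded = TRUE))
    return(row)
  }
  w <- r$weight
  beta <- sum(w * r$ratio) / sum(w)
  se_fixed <- 1 / sqrt(sum(w))
  q <- sum(w * (r$ratio - beta)^2)
  phi <- max(1, q / (J - 1))
  mr_row("ivw_mre", beta, se_fixed * sqrt(phi), J,
         q = q, q_df = J - 1, q_pval = pchisq(q, J - 1, lower.tail = FALSE),
         extra = data.frame(phi = phi, se_fixed = se_fixed, degraded = FALSE))
}

#' Cochran's Q heterogeneity test over Wald ratios
#'
#' @inheritParams mr_ivw
#' @return list `q`, `df`, `pval`.
#' @export
cochran_q <- function(hs = NULL, ratios = NULL) {
  r <- if (is.null(ratios)) wald_ratios(hs) else ratios
  if (nrow(r) < 2) stop("Cochran's Q needs at least 2 ratios")
  w <- r$weight
  beta <- sum(w * r$ratio) / sum(w)
  q <- sum(w * (r$ratio - beta)^2)
  df <- nrow(r) - 1
  list(q = q, df = df, pval = pchisq(q, df, lower.tail = FALSE))
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome effects on the exposure effects
#' with a free intercept and weights `1/se_out^2`, after orienting every
#' SNP so its exposure effect is non-negative (flipping both members of
#' the pair). The slope is the causal estimate; the intercept tests
#' directional pleiotropy. Both SEs are inflated by
#' `sqrt(max(1, RSS_w/(J-2)))` (multiplicative random effects) and
#' inference uses normal quantiles.
#'
#' @param hs A `harmonized_set` with at least 3 SNPs.
#' @return One-row `mr_result` with `intercept`, `intercept_se`,
#'   `intercept_pval`, `rss`.
#' @export
mr_egger <- function(hs) {
  J <- nrow(hs)
  if (J < 3) stop("MR-Egger needs at least 3 SNPs")
  flip <- sign(hs$beta_exp)
  flip[flip == 0] <- 1
  gx <- hs$beta_exp * flip
  gy <- hs$beta_out * flip
  w <- 1 / hs$se_out^2
  # closed-form WLS with intercept
  sw <- sum(w); sx <- sum(w * gx); sy <- sum(w * gy)
  sxx <- sum(w * gx^2); sxy <- sum(w * gx * gy)
  denom <- sw * sxx - sx^2
  if (abs(denom) < .Machine$double.eps * sw * sxx) {
    stop("degenerate design: exposure effects have no spread")
  }
  slope <- (sw * sxy - sx * sy) / denom
  inter <- (sy - slope * sx) / sw
  resid <- gy - inter - slope * gx
  rss <- sum(w * resid^2)
  sigma2 <- max(1, rss / (J - 2))
  se_slope <- sqrt(sw / denom * sigma2)
  se_inter <- sqrt(sxx / denom * sigma2)
  mr_row("egger", slope, se_slope, J,
         extra = data.frame(
           intercept = inter, intercept_se = se_inter,
           intercept_pval = .p_two_sided(inter / se_inter), rss = rss))
}

# Weighted-median point estimate: interpolate ratio against the
# standardized cumulative weight p_i = (S_i - w_i/2)/S at p = 0.5.
weighted_median_point <- function(ratio, weight) {
  ord <- order(ratio)
  r <- ratio[ord]; w <- weight[ord]
  cs <- cumsum(w)
  p <- (cs - w / 2) / sum(w)
  if (p[1] >= 0.5) return(r[1])
  if (p[length(p)] <= 0.5) return(r[length(r)])
  stats::approx(p, r, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median MR estimate
#'
#' Consistent when at least half the total instrument weight comes from
#' valid instruments. The SE is the standard deviation of the estimate
#' over `n_boot` parametric-bootstrap resamples in which each ratio is
#' redrawn from `Normal(ratio_i, se_i^2)` (seeded).
#'
#' @param hs A `harmonized_set` with at least 3 SNPs.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @param ratios Optionally, precomputed [wald_ratios()].
#' @return One-row `mr_result`.
#' @export
mr_weighted_median <- function(hs = NULL, n_boot = 1000, seed = 1,
                               ratios = NULL) {
  r <- if (is.null(ratios)) wald_ratios(hs) else ratios
  if (nrow(r) < 3) stop("weighted median needs at least 3 ratios")
  est <- weighted_median_point(r$ratio, r$weight)
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(b) {
    rb <- stats::rnorm(nrow(r), r$ratio, r$se)
    weighted_median_point(rb, r$weight)
  }, numeric(1))
  mr_row("weighted_median", est, stats::sd(boot), nrow(r))
}

#' Multivariable IVW (MVMR)
#'
#' Weighted least squares of the outcome effects on K exposure-effect
#' columns without intercept, weights `1/se_out^2`. With K = 1 this is
#' exactly the fixed-effect IVW estimate. Fixed-effect SEs by default;
#' `random_effects = TRUE` inflates them by
#' `sqrt(max(1, RSS_w/(J-K)))`.
#'
#' @param beta_exp Numeric matrix (J SNPs x K exposures), column names
#'   are exposure labels.
#' @param beta_out,se_out Outcome effect and SE per SNP.
#' @param random_effects Apply multiplicative SE inflation.
#' @return `mr_result` with one row per exposure (`exposure` column).
#' @export
mr_mvmr <- function(beta_exp, beta_out, se_out, random_effects = FALSE) {
  X <- as.matrix(beta_exp)
  J <- nrow(X); K <- ncol(X)
  if (J < K + 2) stop("MVMR needs at least K + 2 SNPs")
  if (qr(X)$rank < K) {
    stop("rank-deficient exposure matrix; collinear exposures: ",
         paste(colnames(X), collapse = ", "))
  }
  w <- 1 / se_out^2
  XtWX <- crossprod(X * sqrt(w))
  XtWy <- crossprod(X, w * beta_out)
  V <- solve(XtWX)
  beta <- drop(V %*% XtWy)
  sigma2 <- 1
  if (random_effects && J > K) {
    rss <- sum(w * (beta_out - drop(X %*% beta))^2)
    sigma2 <- max(1, rss / (J - K))
  }
  se <- sqrt(diag(V) * sigma2)
  labs <- colnames(X)
  if (is.null(labs)) labs <- paste0("exposure", seq_len(K))
  rows <- do.call(rbind, lapply(seq_len(K), function(k)
    mr_row("mvmr_ivw", beta[k], se[k], J)))
  cbind(data.frame(exposure = labs, stringsAsFactors = FALSE), rows)
}

#' Recover a two-sided Wald p-value from an OR and its 95% CI
#'
#' `se = (log(ci_hi) - log(ci_lo)) / (2 * 1.959964)`,
#' `z = log(or) / se`, `p = 2 * (1 - pnorm(|z|))` — the inverse of the
#' delta-method OR/CI reporting convention.
#'
#' @param or_point Odds ratio point estimate.
#' @param ci_lo,ci_hi 95% confidence limits (`0 < ci_lo < or_point < ci_hi`).
#' @return Two-sided p-value.
#' @export
p_from_or_ci <- function(or_point, ci_lo, ci_hi) {
  if (any(!(ci_lo > 0 & ci_lo < or_point & or_point < ci_hi))) {
    stop("require 0 < ci_lo < or_point < ci_hi")
  }
  se <- (log(ci_hi) - log(ci_lo)) / (2 * .Z95)
  .p_two_sided(log(or_point) / se)
}

#' Odds-ratio block from a log-odds estimate
#'
#' @param beta,se Estimate and SE on the log-odds scale.
#' @return data.frame `or, or_lo, or_hi`.
#' @export
or_ci <- function(beta, se) {
  data.frame(or = exp(beta), or_lo = exp(beta - .Z95 * se),
             or_hi = exp(beta + .Z95 * se))
}
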