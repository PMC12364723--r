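# Leave-one-out fixed-effect IVW slopes for every SNP at once.
# gx, gy: effect vectors; w: outcome-precision weights 1/se_out^2.
loo_ivw <- function(gx, gy, w) {
  a <- w * gx * gy
  b <- w * gx^2
  (sum(a) - a) / (sum(b) - b)
}

# Weighted residual sum of squares against the leave-one-out slopes.
presso_rss <- function(gx, gy, w) {
  beta_loo <- loo_ivw(gx, gy, w)
  w * (gy - beta_loo * gx)^2
}

#' MR-PRESSO: global pleiotropy, outlier, and distortion tests
#'
#' The observed statistic is the weighted residual sum of squares of the
#' outcome effects around leave-one-out fixed-effect IVW fits,
#' `RSS = sum_j w_j (beta_out_j - beta_IVW(-j) * beta_exp_j)^2` with
#' `w_j = 1/se_out_j^2`. The null distribution is simulated `n_sim`
#' times by redrawing `beta_out*_j ~ N(beta_IVW(-j) beta_exp_j, se_out_j^2)`
#' and `beta_exp*_j ~ N(beta_exp_j, se_exp_j^2)` and recomputing RSS;
#' the global p is the add-one tail fraction. Per-SNP outlier p-values
#' compare each observed residual contribution with its simulated
#' distribution; SNPs below the Bonferroni level `outlier_alpha / J` are
#' flagged. When outliers are flagged and at least 3 SNPs remain, the
#' distortion test compares the IVW estimate before and after removal
#' against random pseudo-outlier sets of the same size.
#'
#' All p-values use the add-one estimator, so they lie in
#' `[1/(n_sim+1), 1]` and are never zero. Results are reproducible under
#' `seed`.
#'
#' @param hs A `harmonized_set` with at least 4 SNPs.
#' @param n_sim Null simulations (default 1000).
#' @param seed RNG seed.
#' @param outlier_alpha Family-wise level for outlier flagging
#'   (Bonferroni `outlier_alpha / J`; default 0.05).
#' @return list of class `presso_result`: `global` (rss_obs, pval),
#'   `outliers` (data.frame snp, rss_contrib, pval, flagged),
#'   `outlier_ids`, `distortion` (stat, pval, beta_before, beta_after;
#'   `NULL` when not applicable), `n_sim`, `seed`.
#' @export
mr_presso <- function(hs, n_sim = 1000, seed = 1, outlier_alpha = 0.05) {
  J <- nrow(hs)
  if (J < 4) stop("MR-PRESSO needs at least 4 SNPs")
  gx <- hs$beta_exp; gy <- hs$beta_out
  sx <- hs$se_exp;  sy <- hs$se_out
  w <- 1 / sy^2
  contrib_obs <- presso_rss(gx, gy, w)
  rss_obs <- sum(contrib_obs)
  mu_y <- loo_ivw(gx, gy, w) * gx

  set.seed(seed)
  gx_sim <- matrix(stats::rnorm(n_sim * J, rep(gx, each = n_sim),
                                rep(sx, each = n_sim)), n_sim, J)
  gy_sim <- matrix(stats::rnorm(n_sim * J, rep(mu_y, each = n_sim),
                                rep(sy, each = n_sim)), n_sim, J)
  # vectorized leave-one-out slopes per simulated dataset
  A <- sweep(gx_sim * gy_sim, 2, w, `*`)
  B <- sweep(gx_sim^2, 2, w, `*`)
  beta_loo_sim <- (rowSums(A) - A) / (rowSums(B) - B)
  contrib_sim <- sweep((gy_sim - beta_loo_sim * gx_sim)^2, 2, w, `*`)
  rss_sim <- rowSums(contrib_sim)

  global_pval <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)
  outlier_pval <- (1 + colSums(contrib_sim >=
                               rep(contrib_obs, each = n_sim))) / (n_sim + 1)
  flagged <- outlier_pval < outlier_alpha / J
  outliers <- data.frame(snp = hs$snp, rss_contrib = contrib_obs,
                         pval = outlier_pval, flagged = flagged,
                         stringsAsFactors = FALSE)

  distortion <- NULL
  if (any(flagged) && sum(!flagged) >= 3) {
    ivw_slope <- function(keep) {
      sum(w[keep] * gx[keep] * gy[keep]) / sum(w[keep] * gx[keep]^2)
    }
    beta_before <- ivw_slope(rep(TRUE, J))
    beta_after <- ivw_slope(!flagged)
    stat_obs <- (beta_before - beta_after) / abs(beta_after)
    k <- sum(flagged)
    stat_null <- vapply(seq_len(n_sim), function(i) {
      pseudo <- sample.int(J, k)
      drop <- rep(TRUE, J); drop[pseudo] <- FALSE
      b_wo <- ivw_slope(drop)
      (beta_before - b_wo) / abs(b_wo)
    }, numeric(1))
    dist_pval <- (1 + sum(abs(stat_null) >= abs(stat_obs))) / (n_sim + 1)
    distortion <- list(stat = stat_obs, pval = dist_pval,
                       beta_before = beta_before, beta_after = beta_after)
  }

  structure(list(global = list(rss_obs = rss_obs, pval = global_pval),
                 outliers = outliers, outlier_ids = hs$snp[flagged],
                 distortion = distortion, n_sim = n_sim, seed = seed),
            class = "presso_result")
}

#' Combined pleiotropy / heterogeneity screening report
#'
#' One row per exposure-outcome pair combining the Egger-intercept
#' pleiotropy p-value, Cochran's Q heterogeneity p-value, and the
#' MR-PRESSO global p-value, each with a pass flag at `alpha`. A pair is
#' `consistent` (robust in sensitivity analyses) only when every
#' available flag passes; pairs failing any test are the ones the
#' screening policy excludes.
#'
#' @param hs A `harmonized_set`.
#' @param n_sim,seed Passed to [mr_presso()] (skipped below 4 SNPs).
#' @param alpha Screening level (default 0.05).
#' @return One-row data.frame: `n_snp, egger_intercept_pval, q_pval,
#'   presso_global_pval`, pass flags, and `consistent`.
#' @export
pleiotropy_report <- function(hs, n_sim = 1000, seed = 1, alpha = 0.05) {
  q <- cochran_q(hs)
  eg <- if (nrow(hs) >= 3) mr_egger(hs) else NULL
  pr <- if (nrow(hs) >= 4) mr_presso(hs, n_sim = n_sim, seed = seed) else NULL
  ip <- if (is.null(eg)) NA_real_ else eg$intercept_pval
  pp <- if (is.null(pr)) NA_real_ else pr$global$pval
  pass <- function(p) is.na(p) | p >= alpha
  out <- data.frame(
    n_snp = nrow(hs),
    egger_intercept_pval = ip, q_pval = q$pval, presso_global_pval = pp,
    egger_pass = pass(ip), q_pass = pass(q$pval), presso_pass = pass(pp))
  out$consistent <- out$egger_pass & out$q_pass & out$presso_pass
  out
}
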