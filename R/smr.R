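#' Summary-data-based MR (SMR) test at the top cis-eQTL SNP
#'
#' The top SNP is the one maximising `|z_eqtl|`; a strength gate
#' `z_eqtl^2 >= z2_min` (default 10, paralleling the F >= 10 instrument
#' rule) must hold or the gene is skipped. The SMR estimate is
#' `beta_smr = b_gwas / b_eqtl` at the top SNP, with delta-method SE,
#' and the test statistic
#' `t_smr = z_gwas^2 z_eqtl^2 / (z_gwas^2 + z_eqtl^2)` referred to the
#' upper tail of chi-squared with 1 df. `t_smr <= min(z_gwas^2,
#' z_eqtl^2)` always, approaching `z_gwas^2` as the eQTL becomes
#' arbitrarily strong.
#'
#' @param locus A `cis_locus` (or list with `snp, b_eqtl, se_eqtl,
#'   b_gwas, se_gwas`).
#' @param z2_min Instrument-strength gate on the top eQTL z^2.
#' @return One-row data.frame: `gene_id, top_snp, beta_smr, se_smr,
#'   t_smr, p_smr, or, or_lo, or_hi, skipped, skip_reason`.
#' @export
smr_test <- function(locus, z2_min = 10) {
  z_e <- locus$b_eqtl / locus$se_eqtl
  top <- which.max(abs(z_e))
  gene <- if (!is.null(locus$gene_id)) locus$gene_id else NA_character_
  if (z_e[top]^2 < z2_min) {
    return(data.frame(gene_id = gene, top_snp = locus$snp[top],
                      beta_smr = NA_real_, se_smr = NA_real_,
                      t_smr = NA_real_, p_smr = NA_real_,
                      or = NA_real_, or_lo = NA_real_, or_hi = NA_real_,
                      skipped = TRUE, skip_reason = "weak_top_eqtl",
                      stringsAsFactors = FALSE))
  }
  z_g <- locus$b_gwas[top] / locus$se_gwas[top]
  beta_smr <- locus$b_gwas[top] / locus$b_eqtl[top]
  se_smr <- abs(beta_smr) * sqrt(1 / z_g^2 + 1 / z_e[top]^2)
  if (z_g == 0) se_smr <- abs(locus$se_gwas[top] / locus$b_eqtl[top])
  t_smr <- if (z_g == 0) 0 else z_g^2 * z_e[top]^2 / (z_g^2 + z_e[top]^2)
  p_smr <- max(pchisq(t_smr, 1, lower.tail = FALSE), .Machine$double.xmin)
  ci <- or_ci(beta_smr, se_smr)
  data.frame(gene_id = gene, top_snp = locus$snp[top], beta_smr = beta_smr,
             se_smr = se_smr, t_smr = t_smr, p_smr = p_smr,
             or = ci$or, or_lo = ci$or_lo, or_hi = ci$or_hi,
             skipped = FALSE, skip_reason = "", stringsAsFactors = FALSE)
}

# HEIDI SNP selection: non-top SNPs with eQTL p below eqtl_p_max and LD
# r^2 with the top SNP inside [r2_min, r2_max], capped at the max_snp
# largest |z_eqtl|. Returns indices including the top SNP first.
heidi_select <- function(locus, top, eqtl_p_max = 1.6e-3,
                         r2_min = 0.05, r2_max = 0.9, max_snp = 20) {
  z_e <- locus$b_eqtl / locus$se_eqtl
  p_e <- 2 * pnorm(-abs(z_e))
  r2 <- locus$ld[, top]^2
  cand <- which(seq_along(z_e) != top & p_e < eqtl_p_max &
                r2 >= r2_min & r2 <= r2_max)
  if (length(cand) > max_snp) {
    cand <- cand[order(-abs(z_e[cand]))[seq_len(max_snp)]]
    cand <- sort(cand)
  }
  c(top, cand)
}

#' HEIDI test: heterogeneity in dependent instruments
#'
#' Tests whether the per-SNP SMR ratios across a cis locus are
#' consistent with a single shared causal variant (homogeneous ratios)
#' or reflect linkage of distinct causal variants (heterogeneous
#' ratios). For each selected non-top SNP i,
#' `d_i = b_gwas_i/b_eqtl_i - b_gwas_top/b_eqtl_top`; the covariance of
#' the `d` vector follows from the delta method with LD-induced
#' correlation of the effect estimates within each study. The observed
#' statistic is the sum of squared standardized `d_i`; its null
#' distribution is estimated by seeded Monte-Carlo draws from the
#' fitted multivariate normal, with an add-one p-value.
#'
#' @param locus A `cis_locus` (needs an `ld` correlation matrix).
#' @param seed RNG seed for the Monte-Carlo null.
#' @param n_draws Monte-Carlo draws (default 20,000).
#' @param eqtl_p_max,r2_min,r2_max,max_snp SNP-selection rule (published
#'   HEIDI defaults).
#' @param min_snp Minimum selected SNPs (incl. top) to run (default 3).
#' @return list: `pval`, `n_snp` (non-top SNPs used), `stat`,
#'   `available` (FALSE with `reason` when the test cannot run).
#' @export
heidi_test <- function(locus, seed = 1, n_draws = 20000,
                       eqtl_p_max = 1.6e-3, r2_min = 0.05, r2_max = 0.9,
                       max_snp = 20, min_snp = 3) {
  z_e_all <- locus$b_eqtl / locus$se_eqtl
  top <- which.max(abs(z_e_all))
  sel <- heidi_select(locus, top, eqtl_p_max, r2_min, r2_max, max_snp)
  if (length(sel) < min_snp) {
    return(list(pval = NA_real_, n_snp = length(sel) - 1L, stat = NA_real_,
                available = FALSE, reason = "too_few_snps"))
  }
  be <- locus$b_eqtl[sel]; se_e <- locus$se_eqtl[sel]
  bg <- locus$b_gwas[sel]; se_g <- locus$se_gwas[sel]
  R <- locus$ld[sel, sel, drop = FALSE]
  k <- length(sel) - 1L          # number of d components
  ratio <- bg / be
  d <- ratio[-1L] - ratio[1L]

  # delta-method covariance of d: gradients wrt (bg, be) per SNP, with
  # cov(bg_i, bg_j) = R_ij se_g_i se_g_j (same for eQTL; studies
  # independent).
  Jg <- matrix(0, k, k + 1L)     # d wrt bg over selected SNPs
  Je <- matrix(0, k, k + 1L)     # d wrt be
  for (i in seq_len(k)) {
    Jg[i, i + 1L] <- 1 / be[i + 1L]
    Jg[i, 1L] <- -1 / be[1L]
    Je[i, i + 1L] <- -bg[i + 1L] / be[i + 1L]^2
    Je[i, 1L] <- bg[1L] / be[1L]^2
  }
  Sg <- R * tcrossprod(se_g)
  Se <- R * tcrossprod(se_e)
  V <- Jg %*% Sg %*% t(Jg) + Je %*% Se %*% t(Je)
  sd_d <- sqrt(diag(V))
  z_d <- d / sd_d
  stat <- sum(z_d^2)
  C <- V / tcrossprod(sd_d)
  Lc <- tryCatch(chol(C + diag(1e-8, k)), error = function(e) NULL)
  if (is.null(Lc)) {
    return(list(pval = NA_real_, n_snp = k, stat = stat,
                available = FALSE, reason = "covariance_not_psd"))
  }
  set.seed(seed)
  Z <- matrix(stats::rnorm(n_draws * k), n_draws, k) %*% Lc
  stat_null <- rowSums(Z^2)
  pval <- (1 + sum(stat_null >= stat)) / (n_draws + 1)
  list(pval = pval, n_snp = k, stat = stat, available = TRUE, reason = "")
}

#' Screen a panel of cis loci with SMR + HEIDI
#'
#' Runs [smr_test()] and [heidi_test()] on every locus and returns the
#' genes with `p_smr < p_smr_max` whose HEIDI p-value is at least
#' `heidi_threshold` (i.e. no evidence that the signal is linkage rather
#' than a shared causal variant), ranked by `p_smr`. The full per-gene
#' table is attached as attribute `all`.
#'
#' @param loci list of `cis_locus` objects.
#' @param p_smr_max SMR significance threshold (default 0.05).
#' @param heidi_threshold Minimum HEIDI p to retain (default 0.01).
#' @param seed Base seed; locus i uses `seed + i` for its HEIDI draws.
#' @param n_draws HEIDI Monte-Carlo draws per locus.
#' @return data.frame of passing genes (columns of [smr_test()] plus
#'   `heidi_pval`, `n_heidi_snp`, `pass`); attributes `all` (every
#'   gene) and `n_pass`.
#' @export
smr_screen <- function(loci, p_smr_max = 0.05, heidi_threshold = 0.01,
                       seed = 1, n_draws = 20000) {
  if (!length(loci)) {
    out <- data.frame()
    attr(out, "all") <- data.frame()
    attr(out, "n_pass") <- 0L
    return(out)
  }
  rows <- lapply(seq_along(loci), function(i) {
    s <- smr_test(loci[[i]])
    h <- if (!s$skipped) heidi_test(loci[[i]], seed = seed + i,
                                    n_draws = n_draws)
         else list(pval = NA_real_, n_snp = 0L)
    s$heidi_pval <- h$pval
    s$n_heidi_snp <- h$n_snp
    s$pass <- !s$skipped && !is.na(s$p_smr) && s$p_smr < p_smr_max &&
      !is.na(h$pval) && h$pval >= heidi_threshold
    s
  })
  all_tab <- do.call(rbind, rows)
  out <- all_tab[all_tab$pass, , drop = FALSE]
  out <- out[order(out$p_smr), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all") <- all_tab
  attr(out, "n_pass") <- nrow(out)
  out
}
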