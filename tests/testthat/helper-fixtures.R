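# Shared fixture builders and independent brute-force oracles.

make_records <- function(snp = paste0("rs", seq_along(beta)),
                         chr = "1", pos = seq_along(beta) * 1000L,
                         ea = "A", oa = "G", eaf = 0.3,
                         beta, se, pval = 2 * pnorm(-abs(beta / se)),
                         n = 1e5) {
  data.frame(snp = snp, chr = chr, pos = pos, ea = ea, oa = oa, eaf = eaf,
             beta = beta, se = se, pval = pval, n = n,
             stringsAsFactors = FALSE)
}

make_hs <- function(beta_exp, se_exp, beta_out, se_out,
                    snp = paste0("rs", seq_along(beta_exp))) {
  hs <- data.frame(snp = snp, chr = "1", pos = seq_along(beta_exp) * 1000L,
                   ea = "A", oa = "G", eaf = 0.3,
                   beta_exp = beta_exp, se_exp = se_exp,
                   pval_exp = 2 * pnorm(-abs(beta_exp / se_exp)),
                   beta_out = beta_out, se_out = se_out,
                   pval_out = 2 * pnorm(-abs(beta_out / se_out)),
                   stringsAsFactors = FALSE)
  class(hs) <- c("harmonized_set", "data.frame")
  hs
}

# Exhaustive nearest-gene scan, independent of the package's routine.
brute_nearest <- function(chrom, pos, genes) {
  g <- genes[genes$chr == chrom, , drop = FALSE]
  if (!nrow(g)) return(NA_character_)
  d <- numeric(nrow(g))
  for (i in seq_len(nrow(g))) {
    lo <- g$start[i] + 1L; hi <- g$end[i]
    d[i] <- if (pos >= lo && pos <= hi) 0 else min(abs(pos - lo), abs(pos - hi))
  }
  cand <- which(d == min(d))
  cand <- cand[order(g$start[cand], g$gene_id[cand])]
  g$gene_id[cand[1]]
}

# Reference clumping: literal restatement of the greedy rule using a
# worklist, independent of the package's vectorised candidate scan.
brute_clump <- function(records, ld, r2_max = 0.001, window_kb = 10000) {
  remaining <- records
  kept <- character()
  while (nrow(remaining)) {
    o <- order(remaining$pval, remaining$pos, remaining$snp)
    idx <- remaining[o[1], ]
    kept <- c(kept, idx$snp)
    drop <- rep(FALSE, nrow(remaining))
    for (i in seq_len(nrow(remaining))) {
      if (remaining$snp[i] == idx$snp) { drop[i] <- TRUE; next }
      if (remaining$chr[i] != idx$chr) next
      if (abs(remaining$pos[i] - idx$pos) > window_kb * 1000) next
      r2 <- medimr::ld_r2(ld, idx$snp, remaining$snp[i])
      if (is.na(r2)) r2 <- 1
      if (r2 >= r2_max) drop[i] <- TRUE
    }
    remaining <- remaining[!drop, , drop = FALSE]
  }
  sort(kept)
}

# Random LD correlation matrix with SNP-id dimnames, PSD by construction.
random_ld <- function(ids, seed) {
  set.seed(seed)
  m <- length(ids)
  A <- matrix(rnorm(m * m), m)
  S <- crossprod(A) + diag(m)
  R <- stats::cov2cor(S)
  dimnames(R) <- list(ids, ids)
  R
}
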