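#' Filter records by association p-value
#'
#' Retains records with p strictly below the threshold (the selection
#' rule is a strict inequality, so `pval == threshold` is rejected).
#'
#' @param records Summary-statistic records.
#' @param threshold Significance threshold (default `5e-6`; a stringent
#'   `5e-8` mode is used for sensitivity analyses).
#' @return The retained rows.
#' @export
filter_pvalue <- function(records, threshold = 5e-6) {
  records[records$pval < threshold, , drop = FALSE]
}

#' Instrument-strength F-statistic
#'
#' Computed as the squared Wald z, `(beta/se)^2`, which for a
#' standardized trait equals the usual single-SNP regression F to first
#' order. The R^2-based form `F = R2 (n - 2) / (1 - R2)` with
#' `R2 = 2 maf (1 - maf) beta^2` is available via `form = "r2"`.
#'
#' @param beta,se Per-SNP effect and standard error (`se > 0`).
#' @param form `"wald"` (default) or `"r2"`.
#' @param maf,n Needed for `form = "r2"`.
#' @return Numeric vector of F-statistics.
#' @export
f_statistic <- function(beta, se, form = c("wald", "r2"), maf = NULL, n = NULL) {
  form <- match.arg(form)
  if (any(se <= 0)) stop("se must be positive")
  if (form == "wald") return((beta / se)^2)
  if (is.null(maf) || is.null(n)) stop("form = 'r2' needs maf and n")
  r2 <- 2 * maf * (1 - maf) * beta^2
  r2 * (n - 2) / (1 - r2)
}

#' Remove weak instruments
#'
#' Excludes SNPs with F-statistic strictly below `min_f` (default 10).
#'
#' @param records Summary-statistic records.
#' @param min_f Exclusion threshold.
#' @return Retained rows with an added `f_stat` column.
#' @export
filter_fstat <- function(records, min_f = 10) {
  f <- f_statistic(records$beta, records$se)
  records$f_stat <- f
  records[f >= min_f, , drop = FALSE]
}

#' Pairwise LD r-squared lookup
#'
#' `ld` is either a square correlation matrix (values are r, dimnames are
#' SNP ids) or a reference genotype matrix (rows individuals, columns
#' SNP-id-named dosages) from which Pearson correlations are computed on
#' the fly. A pair absent from the source yields `NA`.
#'
#' @param ld LD source.
#' @param id1,id2 SNP ids.
#' @return r^2 (squared correlation), or NA when unavailable.
#' @export
ld_r2 <- function(ld, id1, id2) {
  if (is.null(ld)) return(NA_real_)
  if (nrow(ld) == ncol(ld) && !is.null(rownames(ld)) &&
      identical(rownames(ld), colnames(ld))) {
    if (!(id1 %in% rownames(ld)) || !(id2 %in% colnames(ld))) return(NA_real_)
    return(unname(ld[id1, id2]^2))
  }
  if (!(id1 %in% colnames(ld)) || !(id2 %in% colnames(ld))) return(NA_real_)
  suppressWarnings(stats::cor(ld[, id1], ld[, id2])^2)
}

#' Greedy LD clumping of summary statistics
#'
#' Repeatedly takes the lowest-p unclumped SNP as an index SNP and
#' removes every other SNP on the same chromosome within `window_kb` of
#' it whose r^2 with the index is `>= r2_max`. P-value ties are broken by
#' position, then SNP id, so the output is deterministic and independent
#' of input order. A missing LD value for an in-window same-chromosome
#' pair is treated conservatively as r^2 = 1 (removal) and counted in the
#' `n_missing_ld` attribute.
#'
#' @param records Summary-statistic records with `chr`, `pos`, `pval`.
#' @param ld LD source for [ld_r2()] (matrix of r or reference genotypes).
#' @param r2_max Clumping r^2 threshold (default 0.001).
#' @param window_kb Window around the index SNP in kb (default 10,000).
#' @return Index SNPs only, in decreasing significance order, with
#'   attributes `clumped` (data.frame snp, index_snp) and `n_missing_ld`.
#' @export
clump <- function(records, ld = NULL, r2_max = 0.001, window_kb = 10000) {
  if (!nrow(records)) return(records)
  ord <- order(records$pval, records$pos, records$snp)
  x <- records[ord, , drop = FALSE]
  active <- rep(TRUE, nrow(x))
  keep <- logical(nrow(x))
  clumped <- list()
  n_missing <- 0L
  for (i in seq_len(nrow(x))) {
    if (!active[i]) next
    keep[i] <- TRUE
    active[i] <- FALSE
    cand <- which(active & x$chr == x$chr[i] &
                  abs(x$pos - x$pos[i]) <= window_kb * 1000)
    for (j in cand) {
      r2 <- ld_r2(ld, x$snp[i], x$snp[j])
      if (is.na(r2)) { r2 <- 1; n_missing <- n_missing + 1L }
      if (r2 >= r2_max) {
        active[j] <- FALSE
        clumped[[length(clumped) + 1L]] <-
          data.frame(snp = x$snp[j], index_snp = x$snp[i],
                     stringsAsFactors = FALSE)
      }
    }
  }
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "clumped") <- if (length(clumped)) do.call(rbind, clumped) else
    data.frame(snp = character(), index_snp = character())
  attr(out, "n_missing_ld") <- n_missing
  out
}

#' Select instrumental variables
#'
#' Applies, in order: the p-value threshold, greedy LD clumping, and the
#' F-statistic filter. Every input SNP appears exactly once in the audit
#' trail with its fate (`kept` or rejection reason `pval` / `clumped` /
#' `weak`).
#'
#' @param records Summary-statistic records.
#' @param ld LD source for [clump()]; `NULL` skips LD pruning for SNPs
#'   outside each other's windows but removes in-window pairs
#'   conservatively.
#' @param pval,r2,window_kb,min_f Selection thresholds.
#' @return list with `instruments` (retained records incl. `f_stat`) and
#'   `audit` (data.frame snp, action, reason).
#' @export
select_instruments <- function(records, ld = NULL, pval = 5e-6, r2 = 0.001,
                               window_kb = 10000, min_f = 10) {
  fate <- setNames(rep("kept", nrow(records)), records$snp)
  sig <- filter_pvalue(records, pval)
  fate[setdiff(records$snp, sig$snp)] <- "pval"
  cl <- clump(sig, ld = ld, r2_max = r2, window_kb = window_kb)
  fate[setdiff(sig$snp, cl$snp)] <- "clumped"
  strong <- filter_fstat(cl, min_f)
  fate[setdiff(cl$snp, strong$snp)] <- "weak"
  audit <- data.frame(snp = names(fate),
                      action = ifelse(fate == "kept", "kept", "rejected"),
                      reason = unname(fate), stringsAsFactors = FALSE)
  audit$reason[audit$action == "kept"] <- ""
  list(instruments = strong, audit = audit)
}
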