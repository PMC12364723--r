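#' @importFrom data.table fread fwrite as.data.table setDF
#' @importFrom stats pnorm qnorm pchisq setNames
NULL

.VALID_ALLELES <- c("A", "C", "G", "T")

#' Default column mapping for tab-delimited GWAS summary statistics
#'
#' Maps the internal field names to the column names found in a file.
#' Override individual entries via the `dialect` argument of
#' [read_sumstats()], e.g. `dialect = c(snp = "rsid", pval = "p_value")`.
#'
#' @return Named character vector (internal name -> file column name).
#' @export
default_dialect <- function() {
  c(snp = "SNP", chr = "CHR", pos = "POS", ea = "EA", oa = "OA",
    eaf = "EAF", beta = "BETA", se = "SE", pval = "P", n = "N")
}

#' Read GWAS summary statistics
#'
#' Reads a tab-delimited summary-statistics file with a header row and
#' returns validated per-SNP association records. Rows violating the
#' record invariants (non-positive SE, p outside (0, 1], allele codes
#' outside A/C/G/T, identical alleles, allele frequency outside (0, 1),
#' unparsable numerics) are dropped and itemised in the attached report.
#'
#' @param path Path to a tab-delimited file with a header row.
#' @param dialect Named character vector overriding [default_dialect()]
#'   entries; names are internal field names.
#' @param or_scale If `TRUE`, the effect column holds odds ratios and is
#'   stored as `log(OR)`.
#' @param impute_se If `TRUE` (default) and the SE column is absent,
#'   SE is imputed as `|beta| / qnorm(1 - p/2)` and flagged.
#' @return A `data.frame` with columns `snp, chr, pos, ea, oa, eaf, beta,
#'   se, pval, n` (plus `se_imputed` when imputation occurred), carrying
#'   attributes `n_dropped` (count) and `drop_report` (data.frame with
#'   `snp`, `reason`).
#' @export
read_sumstats <- function(path, dialect = NULL, or_scale = FALSE,
                          impute_se = TRUE) {
  if (!file.exists(path)) stop("summary-statistics file not found: ", path)
  map <- default_dialect()
  if (!is.null(dialect)) {
    bad <- setdiff(names(dialect), names(map))
    if (length(bad)) stop("unknown dialect field(s): ", paste(bad, collapse = ", "))
    map[names(dialect)] <- dialect
  }
  dt <- fread(path, sep = "\t", header = TRUE, data.table = TRUE,
              showProgress = FALSE)
  se_absent <- !(map[["se"]] %in% names(dt)) && impute_se
  mandatory <- setdiff(names(map), if (se_absent) "se" else character())
  missing_cols <- map[mandatory][!(map[mandatory] %in% names(dt))]
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(
    snp  = as.character(dt[[map[["snp"]]]]),
    chr  = as.character(dt[[map[["chr"]]]]),
    pos  = suppressWarnings(as.integer(dt[[map[["pos"]]]])),
    ea   = toupper(as.character(dt[[map[["ea"]]]])),
    oa   = toupper(as.character(dt[[map[["oa"]]]])),
    eaf  = suppressWarnings(as.numeric(dt[[map[["eaf"]]]])),
    beta = suppressWarnings(as.numeric(dt[[map[["beta"]]]])),
    se   = if (se_absent) NA_real_ else
             suppressWarnings(as.numeric(dt[[map[["se"]]]])),
    pval = suppressWarnings(as.numeric(dt[[map[["pval"]]]])),
    n    = suppressWarnings(as.numeric(dt[[map[["n"]]]])),
    stringsAsFactors = FALSE
  )
  if (or_scale) out$beta <- log(out$beta)
  if (se_absent) {
    out$se <- abs(out$beta) / qnorm(1 - out$pval / 2)
    out$se_imputed <- TRUE
  }
  validate_sumstats(out)
}

#' Validate summary-statistic records
#'
#' Applies the record invariants and drops failing rows, keeping an
#' itemised report. Used by [read_sumstats()] and usable directly on
#' programmatically built data frames.
#'
#' @param x data.frame with the internal summary-statistics columns.
#' @return The retained rows, with `n_dropped` and `drop_report`
#'   attributes as in [read_sumstats()].
#' @export
validate_sumstats <- function(x) {
  reason <- rep(NA_character_, nrow(x))
  flag <- function(cond, why) {
    cond[is.na(cond)] <- TRUE
    reason[is.na(reason) & cond] <<- why
  }
  flag(is.na(x$beta) | is.na(x$se) | is.na(x$pval) | !is.finite(x$beta),
       "unparsable_numeric")
  flag(!(x$ea %in% .VALID_ALLELES) | !(x$oa %in% .VALID_ALLELES),
       "invalid_allele")
  flag(x$ea == x$oa, "identical_alleles")
  flag(!(x$se > 0) | !is.finite(x$se), "nonpositive_se")
  flag(x$pval <= 0 | x$pval > 1, "pval_out_of_range")
  flag(x$eaf <= 0 | x$eaf >= 1, "eaf_out_of_range")
  keep <- is.na(reason)
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  attr(out, "drop_report") <- data.frame(
    snp = x$snp[!keep], reason = reason[!keep], stringsAsFactors = FALSE)
  out
}

#' Write summary statistics in the package's tab-delimited format
#'
#' @param x data.frame of records (internal column names).
#' @param path Output path.
#' @export
write_sumstats <- function(x, path) {
  out <- data.frame(SNP = x$snp, CHR = x$chr, POS = x$pos, EA = x$ea,
                    OA = x$oa, EAF = x$eaf, BETA = x$beta, SE = x$se,
                    P = x$pval, N = x$n)
  fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

is_palindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
  (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

#' Harmonize exposure, outcome (and optional mediator) summary statistics
#'
#' Aligns all traits to the exposure's effect allele. SNPs present in all
#' supplied traits are retained; palindromic SNPs (A/T or C/G) are removed
#' unconditionally; when the secondary trait's alleles are swapped the
#' sign of its beta is flipped and the allele frequency replaced by
#' `1 - eaf`; strand-complement reconciliation (e.g. A/G vs T/C) is
#' attempted before declaring a SNP irreconcilable. Every removal or flip
#' is recorded in the audit report.
#'
#' @param exposure,outcome data.frames of summary-statistic records.
#' @param mediator Optional third trait, aligned the same way.
#' @return A `harmonized_set`: a data.frame with columns `snp, chr, pos,
#'   ea, oa, beta_exp, se_exp, pval_exp, eaf, beta_out, se_out, pval_out`
#'   (plus `beta_med, se_med, pval_med` when a mediator is supplied) and
#'   logical provenance columns `flipped_out` / `strand_out` (and
#'   mediator analogues); attribute `report` holds the per-SNP audit
#'   (snp, action, reason).
#' @export
harmonize <- function(exposure, outcome, mediator = NULL) {
  ids <- intersect(exposure$snp, outcome$snp)
  if (!is.null(mediator)) ids <- intersect(ids, mediator$snp)
  report <- list()
  note <- function(snp, action, reason) {
    report[[length(report) + 1L]] <<- data.frame(
      snp = snp, action = action, reason = reason, stringsAsFactors = FALSE)
  }
  if (!length(ids)) {
    warning("no SNPs shared across traits; empty harmonized set")
    empty <- empty_harmonized(!is.null(mediator))
    attr(empty, "report") <- data.frame(snp = character(), action = character(),
                                        reason = character())
    return(empty)
  }
  e <- exposure[match(ids, exposure$snp), ]
  o <- outcome[match(ids, outcome$snp), ]
  m <- if (!is.null(mediator)) mediator[match(ids, mediator$snp), ]

  pal <- is_palindromic(e$ea, e$oa)
  if (any(pal)) note(ids[pal], "removed", "palindromic")

  aln_o <- align_alleles(e$ea, e$oa, o$ea, o$oa)
  aln_m <- if (!is.null(m)) align_alleles(e$ea, e$oa, m$ea, m$oa)

  irrec <- is.na(aln_o$mode)
  if (!is.null(m)) irrec <- irrec | is.na(aln_m$mode)
  irrec <- irrec & !pal
  if (any(irrec)) note(ids[irrec], "removed", "irreconcilable_alleles")

  keep <- !pal & !irrec
  flip_o <- aln_o$flip & keep
  if (any(flip_o)) note(ids[flip_o], "flipped", "outcome_allele_swap")
  strand_o <- aln_o$strand & keep
  if (any(strand_o)) note(ids[strand_o], "strand_flip", "outcome_strand")
  if (!is.null(m)) {
    flip_m <- aln_m$flip & keep
    if (any(flip_m)) note(ids[flip_m], "flipped", "mediator_allele_swap")
  }

  hs <- data.frame(
    snp = ids, chr = e$chr, pos = e$pos, ea = e$ea, oa = e$oa,
    beta_exp = e$beta, se_exp = e$se, pval_exp = e$pval, eaf = e$eaf,
    beta_out = ifelse(aln_o$flip, -o$beta, o$beta),
    se_out = o$se, pval_out = o$pval,
    eaf_out = ifelse(aln_o$flip, 1 - o$eaf, o$eaf),
    flipped_out = aln_o$flip, strand_out = aln_o$strand,
    stringsAsFactors = FALSE
  )
  if (!is.null(m)) {
    hs$beta_med <- ifelse(aln_m$flip, -m$beta, m$beta)
    hs$se_med <- m$se
    hs$pval_med <- m$pval
    hs$flipped_med <- aln_m$flip
    hs$strand_med <- aln_m$strand
  }
  hs <- hs[keep, , drop = FALSE]
  rownames(hs) <- NULL
  class(hs) <- c("harmonized_set", "data.frame")
  attr(hs, "report") <- if (length(report)) do.call(rbind, report) else
    data.frame(snp = character(), action = character(), reason = character())
  hs
}

# Per-SNP allele reconciliation: returns mode (same/swap/strand/strand_swap
# or NA), and logical flip / strand vectors.
align_alleles <- function(ea1, oa1, ea2, oa2) {
  cea2 <- unname(.complement[ea2])
  coa2 <- unname(.complement[oa2])
  same        <- ea1 == ea2  & oa1 == oa2
  swap        <- ea1 == oa2  & oa1 == ea2
  strand      <- ea1 == cea2 & oa1 == coa2
  strand_swap <- ea1 == coa2 & oa1 == cea2
  mode <- rep(NA_character_, length(ea1))
  mode[strand_swap] <- "strand_swap"
  mode[strand] <- "strand"
  mode[swap] <- "swap"
  mode[same] <- "same"
  list(mode = mode,
       flip = swap | strand_swap,
       strand = (strand | strand_swap) & !same & !swap)
}

empty_harmonized <- function(with_mediator) {
  hs <- data.frame(snp = character(), chr = character(), pos = integer(),
                   ea = character(), oa = character(), beta_exp = numeric(),
                   se_exp = numeric(), pval_exp = numeric(), eaf = numeric(),
                   beta_out = numeric(), se_out = numeric(),
                   pval_out = numeric(), eaf_out = numeric(),
                   flipped_out = logical(), strand_out = logical())
  if (with_mediator) {
    hs$beta_med <- numeric(); hs$se_med <- numeric()
    hs$pval_med <- numeric(); hs$flipped_med <- logical()
    hs$strand_med <- logical()
  }
  class(hs) <- c("harmonized_set", "data.frame")
  hs
}

#' Write the harmonization / instrument-selection audit trail
#'
#' @param report data.frame with columns `snp`, `action`, `reason` (the
#'   `report` attribute of [harmonize()] or the audit of
#'   [select_instruments()]).
#' @param path Output path (tab-delimited).
#' @export
write_audit <- function(report, path) {
  fwrite(report, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a BED4 gene annotation file
#'
#' BED convention: 0-based half-open intervals, columns chrom, start,
#' end, gene_id, no header.
#'
#' @param path BED4 file path.
#' @return data.frame with columns `gene_id, chr, start, end`.
#' @export
read_bed <- function(path) {
  dt <- fread(path, sep = "\t", header = FALSE, data.table = FALSE,
              showProgress = FALSE)
  if (ncol(dt) < 4) stop("BED4 requires chrom, start, end, name columns")
  out <- data.frame(gene_id = as.character(dt[[4]]), chr = as.character(dt[[1]]),
                    start = as.integer(dt[[2]]), end = as.integer(dt[[3]]),
                    stringsAsFactors = FALSE)
  if (any(out$start >= out$end)) stop("BED intervals must satisfy start < end")
  out
}

#' Map a variant to its nearest gene
#'
#' A 1-based variant position is mapped against 0-based half-open BED
#' gene intervals. A position overlapping a gene body returns that gene
#' with distance 0; otherwise the gene minimising the distance to its
#' nearer boundary wins. Distance is signed: positive downstream of the
#' gene end, negative upstream of the gene start. Ties are broken by
#' smaller start coordinate, then lexicographic gene id.
#'
#' @param chrom Chromosome of the variant.
#' @param pos 1-based position.
#' @param genes Gene annotation data.frame from [read_bed()].
#' @return list with `gene_id` (NA when the chromosome has no
#'   annotation), `distance` (signed; NA when unmapped).
#' @export
nearest_gene <- function(chrom, pos, genes) {
  g <- genes[genes$chr == as.character(chrom), , drop = FALSE]
  if (!nrow(g)) return(list(gene_id = NA_character_, distance = NA_real_))
  # 1-based gene body: (start+1)..end
  lo <- g$start + 1L
  hi <- g$end
  dist <- ifelse(pos >= lo & pos <= hi, 0,
                 ifelse(pos < lo, pos - lo, pos - hi))
  ord <- order(abs(dist), g$start, g$gene_id)
  best <- ord[1L]
  list(gene_id = g$gene_id[best], distance = dist[best])
}

#' Map many variants to their nearest genes
#'
#' @param records Summary-statistic records (needs `snp, chr, pos`).
#' @param genes Gene annotation from [read_bed()].
#' @return data.frame `snp, chr, pos, gene_id, distance`.
#' @export
annotate_nearest_gene <- function(records, genes) {
  hits <- lapply(seq_len(nrow(records)), function(i)
    nearest_gene(records$chr[i], records$pos[i], genes))
  data.frame(snp = records$snp, chr = records$chr, pos = records$pos,
             gene_id = vapply(hits, `[[`, character(1), "gene_id"),
             distance = vapply(hits, `[[`, numeric(1), "distance"),
             stringsAsFactors = FALSE)
}
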