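#' Build a pipeline configuration
#'
#' Accepts either a YAML file path or a named list. Mandatory entries:
#' `exposures` (named list of summary-statistics paths), `outcome`
#' (path), `out_dir`. Optional: `mediators` (named list of paths),
#' `gene_bed` (BED4 annotation), `loci` (list of `cis_locus` objects,
#' programmatic use only), `ld` (square whitespace-delimited r matrix
#' path or matrix), `iv` (pval, r2, window_kb, min_f), `alpha`,
#' `n_sim`, `n_boot`, `seed`.
#'
#' @param config YAML path or list.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  defaults <- list(mediators = list(), gene_bed = NULL, loci = list(),
                   ld = NULL, iv = list(), alpha = 0.05,
                   n_sim = 1000, n_boot = 1000, seed = 1)
  loci <- cfg$loci   # unnamed list; modifyList cannot merge it
  cfg <- utils::modifyList(defaults, cfg)
  if (!is.null(loci)) cfg$loci <- loci
  cfg$iv <- utils::modifyList(list(pval = 5e-6, r2 = 0.001,
                                   window_kb = 10000, min_f = 10), cfg$iv)
  for (p in c(unlist(cfg$exposures), unlist(cfg$mediators), cfg$outcome)) {
    if (is.character(p) && !file.exists(p)) stop("input path not found: ", p)
  }
  if (is.null(cfg$out_dir)) stop("out_dir is required")
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

# Full estimator suite + sensitivity screen for one exposure/outcome pair.
pair_analysis <- function(label_x, x, label_y, y, cfg) {
  iv <- select_instruments(x, ld = cfg$ld, pval = cfg$iv$pval, r2 = cfg$iv$r2,
                           window_kb = cfg$iv$window_kb, min_f = cfg$iv$min_f)
  hs <- harmonize(iv$instruments, y)
  if (!nrow(hs)) stop("no harmonizable instruments for ", label_x)
  rows <- list(mr_ivw(hs))
  if (nrow(hs) >= 3) {
    rows <- c(rows, list(mr_egger(hs),
                         mr_weighted_median(hs, n_boot = cfg$n_boot,
                                            seed = cfg$seed)))
  }
  forest <- do.call(rbind, lapply(rows, function(r) {
    r[setdiff(names(r), c("phi", "se_fixed", "degraded", "intercept",
                          "intercept_se", "intercept_pval", "rss"))]
  }))
  forest <- cbind(data.frame(exposure = label_x, outcome = label_y,
                             stringsAsFactors = FALSE), forest)
  sens <- if (nrow(hs) >= 2) {
    cbind(data.frame(exposure = label_x, outcome = label_y,
                     stringsAsFactors = FALSE),
          pleiotropy_report(hs, n_sim = cfg$n_sim, seed = cfg$seed,
                            alpha = cfg$alpha))
  }
  list(forest = forest, sensitivity = sens, hs = hs, n_snp = nrow(hs))
}

#' Screen a forest table for significant, sensitivity-consistent pairs
#'
#' Retains IVW rows with `pval < alpha` whose pair passes every
#' available sensitivity flag in the pleiotropy report (pairs failing
#' heterogeneity or pleiotropy are excluded). A pure function of its
#' inputs. Benjamini-Hochberg-adjusted p-values are appended for
#' transparency; screening itself uses the nominal level.
#'
#' @param forest Forest-table rows ([run_pipeline()] stage output).
#' @param sensitivity Pleiotropy-report rows keyed by exposure/outcome.
#' @param alpha Nominal significance level (default 0.05).
#' @return Retained IVW rows with `pval_bh` appended.
#' @export
screen_significant <- function(forest, sensitivity, alpha = 0.05) {
  ivw <- forest[forest$method %in% c("ivw_mre", "wald"), , drop = FALSE]
  ivw$pval_bh <- stats::p.adjust(ivw$pval, method = "BH")
  key <- paste(ivw$exposure, ivw$outcome)
  skey <- paste(sensitivity$exposure, sensitivity$outcome)
  ok <- sensitivity$consistent[match(key, skey)]
  ok[is.na(ok)] <- TRUE
  out <- ivw[ivw$pval < alpha & ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full diet -> metabolite -> outcome causal-inference pipeline
#'
#' Stages, in order: (1) exposure -> outcome MR with the full estimator
#' suite and sensitivity screen for every exposure; (2) mediator
#' (metabolite) -> outcome MR likewise; (3) significance screening of
#' both at the nominal level; (4) exposure -> mediator MR and two-step
#' mediation for every screened exposure x mediator pair, with the
#' direction-consistency screen; (5) reverse MR (outcome -> exposure)
#' when the outcome has instruments; (6) multivariable MR over the
#' screened exposures when at least two share instruments; (7) SMR +
#' HEIDI gene screen over supplied cis loci; (8) nearest-gene annotation
#' of mediator instrument SNPs when a BED annotation is supplied. Each
#' stage writes a TSV into `out_dir`; failures are isolated per stage
#' and per trait pair and recorded in the JSON manifest.
#'
#' @param config A [pipeline_config()], a list, or a YAML path.
#' @return Invisibly, the manifest list (also written to
#'   `out_dir/manifest.json`). Stage tables are at
#'   `out_dir/<stage>.tsv`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    pipeline_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = cfg$seed, alpha = cfg$alpha, iv = cfg$iv,
                   stages = list())
  note <- function(stage, status, detail = "") {
    manifest$stages[[stage]] <<- list(status = status, detail = detail)
  }
  emit <- function(tab, name) {
    data.table::fwrite(tab, file.path(cfg$out_dir, paste0(name, ".tsv")),
                       sep = "\t", quote = FALSE)
  }
  load_trait <- function(x) if (is.character(x)) read_sumstats(x) else x

  outcome <- load_trait(cfg$outcome)
  run_block <- function(traits, outcome, label_y) {
    forest <- list(); sens <- list()
    for (nm in names(traits)) {
      res <- tryCatch(pair_analysis(nm, load_trait(traits[[nm]]),
                                    label_y, outcome, cfg),
                      error = function(e) e)
      if (inherits(res, "error")) {
        note(paste0("pair_", nm), "failed", conditionMessage(res))
      } else {
        forest[[nm]] <- res$forest
        sens[[nm]] <- res$sensitivity
      }
    }
    list(forest = do.call(rbind, c(forest, list(NULL))),
         sens = do.call(rbind, c(sens, list(NULL))))
  }

  ## 1-2: forward MR blocks
  exp_block <- run_block(cfg$exposures, outcome, "outcome")
  if (!is.null(exp_block$forest)) {
    emit(exp_block$forest, "exposure_outcome_mr")
    emit(exp_block$sens, "exposure_outcome_sensitivity")
    note("exposure_outcome_mr", "ok")
  } else note("exposure_outcome_mr", "failed", "no exposure pair succeeded")

  med_block <- NULL
  if (length(cfg$mediators)) {
    med_block <- run_block(cfg$mediators, outcome, "outcome")
    if (!is.null(med_block$forest)) {
      emit(med_block$forest, "mediator_outcome_mr")
      emit(med_block$sens, "mediator_outcome_sensitivity")
      note("mediator_outcome_mr", "ok")
    } else note("mediator_outcome_mr", "failed", "no mediator pair succeeded")
  } else note("mediator_outcome_mr", "skipped", "no mediator files supplied")

  ## 3: screening
  sig_exp <- if (!is.null(exp_block$forest)) {
    screen_significant(exp_block$forest, exp_block$sens, cfg$alpha)
  }
  if (!is.null(sig_exp)) emit(sig_exp, "screened_exposures")
  sig_med <- if (!is.null(med_block$forest)) {
    screen_significant(med_block$forest, med_block$sens, cfg$alpha)
  }
  if (!is.null(sig_med)) emit(sig_med, "screened_mediators")
  note("screening", "ok")

  ## 4: mediation over screened pairs
  if (!is.null(sig_exp) && !is.null(sig_med) &&
      nrow(sig_exp) && nrow(sig_med)) {
    med_rows <- list()
    for (ex in sig_exp$exposure) for (md in sig_med$exposure) {
      r <- tryCatch({
        m <- two_step_mediation(load_trait(cfg$exposures[[ex]]),
                                load_trait(cfg$mediators[[md]]),
                                outcome, ld = cfg$ld, iv_config = cfg$iv)
        cbind(data.frame(exposure = ex, mediator = md, outcome = "outcome",
                         stringsAsFactors = FALSE), as.data.frame(m))
      }, error = function(e) e)
      if (inherits(r, "error")) {
        note(paste0("mediation_", ex, "_", md), "failed", conditionMessage(r))
      } else med_rows[[paste(ex, md)]] <- r
    }
    if (length(med_rows)) {
      emit(do.call(rbind, med_rows), "mediation")
      note("mediation", "ok")
    } else note("mediation", "failed", "no mediation pair succeeded")
  } else note("mediation", "skipped", "no screened exposure/mediator pairs")

  ## 5: reverse MR
  rev_rows <- list()
  for (nm in names(cfg$exposures)) {
    r <- tryCatch({
      rr <- reverse_mr(outcome, load_trait(cfg$exposures[[nm]]),
                       ld = cfg$ld, iv_config = cfg$iv, alpha = cfg$alpha)
      cbind(data.frame(exposure = "outcome", outcome = nm,
                       pass = rr$pass, stringsAsFactors = FALSE),
            rr$estimate)
    }, error = function(e) e)
    if (!inherits(r, "error")) rev_rows[[nm]] <- r
  }
  if (length(rev_rows)) {
    emit(do.call(rbind, rev_rows), "reverse_mr")
    note("reverse_mr", "ok")
  } else note("reverse_mr", "skipped", "outcome has no usable instruments")

  ## 6: MVMR over screened exposures sharing instruments
  if (!is.null(sig_exp) && nrow(sig_exp) >= 2) {
    r <- tryCatch({
      ivs <- lapply(sig_exp$exposure, function(nm) {
        select_instruments(load_trait(cfg$exposures[[nm]]), ld = cfg$ld,
                           pval = cfg$iv$pval, r2 = cfg$iv$r2,
                           window_kb = cfg$iv$window_kb,
                           min_f = cfg$iv$min_f)$instruments
      })
      snps <- unique(unlist(lapply(ivs, `[[`, "snp")))
      mats <- lapply(seq_along(sig_exp$exposure), function(k) {
        full <- load_trait(cfg$exposures[[sig_exp$exposure[k]]])
        full$beta[match(snps, full$snp)]
      })
      X <- do.call(cbind, mats)
      colnames(X) <- sig_exp$exposure
      oidx <- match(snps, outcome$snp)
      keep <- stats::complete.cases(X) & !is.na(oidx)
      mr_mvmr(X[keep, , drop = FALSE], outcome$beta[oidx[keep]],
              outcome$se[oidx[keep]])
    }, error = function(e) e)
    if (inherits(r, "error")) note("mvmr", "failed", conditionMessage(r))
    else { emit(r, "mvmr"); note("mvmr", "ok") }
  } else note("mvmr", "skipped", "fewer than two screened exposures")

  ## 7: SMR + HEIDI
  if (length(cfg$loci)) {
    r <- tryCatch(smr_screen(cfg$loci, seed = cfg$seed),
                  error = function(e) e)
    if (inherits(r, "error")) note("smr", "failed", conditionMessage(r))
    else { emit(attr(r, "all"), "smr"); note("smr", "ok") }
  } else note("smr", "skipped", "no cis loci supplied")

  ## 8: nearest-gene mapping of mediator instruments
  if (!is.null(cfg$gene_bed) && length(cfg$mediators)) {
    r <- tryCatch({
      genes <- if (is.character(cfg$gene_bed)) read_bed(cfg$gene_bed) else
        cfg$gene_bed
      ivs <- do.call(rbind, lapply(cfg$mediators, function(p) {
        select_instruments(load_trait(p), ld = cfg$ld,
                           pval = cfg$iv$pval, r2 = cfg$iv$r2,
                           window_kb = cfg$iv$window_kb,
                           min_f = cfg$iv$min_f)$instruments
      }))
      annotate_nearest_gene(ivs, genes)
    }, error = function(e) e)
    if (inherits(r, "error")) note("nearest_gene", "failed",
                                   conditionMessage(r))
    else { emit(r, "nearest_gene"); note("nearest_gene", "ok") }
  } else note("nearest_gene", "skipped", "no gene annotation supplied")

  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
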