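#' Two-step MR mediation with proportion mediated
#'
#' Product-of-coefficients mediation on summary statistics:
#' `beta_total` from exposure -> outcome IVW-MRE using the exposure's
#' instruments; `beta_xm` from exposure -> mediator IVW-MRE using the
#' same instruments; `beta_my` from mediator -> outcome IVW-MRE using
#' the mediator's own instruments (selected on the mediator p-values).
#' The indirect effect is `beta_xm * beta_my`, the proportion mediated
#' `indirect / beta_total`, and the delta-method SE of the indirect
#' effect `sqrt(beta_xm^2 se_my^2 + beta_my^2 se_xm^2)`. The direction
#' screen passes when `sign(indirect) == sign(beta_total)` (an exactly
#' zero indirect effect passes with proportion 0).
#'
#' @param exposure,mediator,outcome Summary-statistic data.frames.
#' @param ld Optional LD source for clumping.
#' @param iv_config list of instrument-selection settings
#'   (`pval`, `r2`, `window_kb`, `min_f`), defaults as in
#'   [select_instruments()].
#' @return One-row data.frame of class `mediation_result`: component
#'   estimates with SEs, `indirect`, `se_indirect`, `proportion`,
#'   `proportion_pct`, `direction_consistent`, instrument counts.
#'   Attribute `components` holds the three full `mr_result` rows.
#' @export
two_step_mediation <- function(exposure, mediator, outcome, ld = NULL,
                               iv_config = list()) {
  cfg <- utils::modifyList(list(pval = 5e-6, r2 = 0.001, window_kb = 10000,
                                min_f = 10), iv_config)
  pick <- function(records, step) {
    iv <- select_instruments(records, ld = ld, pval = cfg$pval, r2 = cfg$r2,
                             window_kb = cfg$window_kb, min_f = cfg$min_f)
    if (!nrow(iv$instruments)) {
      stop("no usable instruments at step: ", step)
    }
    iv$instruments
  }
  est <- function(iv, other, step) {
    hs <- harmonize(iv, other)
    if (!nrow(hs)) stop("no harmonizable SNPs at step: ", step)
    mr_ivw(hs)
  }
  iv_exp <- pick(exposure, "exposure_instruments")
  iv_med <- pick(mediator, "mediator_instruments")
  total <- est(iv_exp, outcome, "exposure_to_outcome")
  xm <- est(iv_exp, mediator, "exposure_to_mediator")
  my <- est(iv_med, outcome, "mediator_to_outcome")

  indirect <- xm$beta * my$beta
  se_indirect <- sqrt(xm$beta^2 * my$se^2 + my$beta^2 * xm$se^2)
  consistent <- if (total$beta == 0) FALSE else
    (indirect == 0) || (sign(indirect) == sign(total$beta))
  proportion <- if (consistent && total$beta != 0) indirect / total$beta else
    indirect / total$beta
  out <- data.frame(
    beta_total = total$beta, se_total = total$se, pval_total = total$pval,
    beta_xm = xm$beta, se_xm = xm$se,
    beta_my = my$beta, se_my = my$se,
    indirect = indirect, se_indirect = se_indirect,
    proportion = proportion, proportion_pct = 100 * proportion,
    direction_consistent = consistent,
    n_snp_exposure = total$n_snp, n_snp_mediator = my$n_snp)
  class(out) <- c("mediation_result", "data.frame")
  attr(out, "components") <- list(total = total, xm = xm, my = my)
  out
}

#' Direction-consistency screen for a mediation result
#'
#' Passes when the indirect effect has the same sign as the total
#' effect; a zero indirect effect passes (proportion 0); a zero total
#' effect fails with a `zero_total` annotation.
#'
#' @param result A `mediation_result` (or any row with `indirect` and
#'   `beta_total`).
#' @return logical flag with attribute `zero_total`.
#' @export
direction_screen <- function(result) {
  if (result$beta_total == 0) {
    return(structure(FALSE, zero_total = TRUE))
  }
  structure(result$indirect == 0 ||
            sign(result$indirect) == sign(result$beta_total),
            zero_total = FALSE)
}

#' Reverse-direction MR screen
#'
#' Runs the IVW analysis with the trait roles swapped (original outcome
#' as exposure), selecting instruments for the original outcome trait.
#' The screen passes (no evidence of reverse causation) when the
#' reverse IVW p-value is at least `alpha`.
#'
#' @param outcome Summary statistics of the original outcome (now the
#'   exposure).
#' @param exposure Summary statistics of the original exposure (now the
#'   outcome).
#' @param ld Optional LD source.
#' @param iv_config Instrument-selection settings as in
#'   [two_step_mediation()].
#' @param alpha Screening level (default 0.05).
#' @return list: `estimate` (one-row `mr_result`), `pass` (logical).
#' @export
reverse_mr <- function(outcome, exposure, ld = NULL, iv_config = list(),
                       alpha = 0.05) {
  cfg <- utils::modifyList(list(pval = 5e-6, r2 = 0.001, window_kb = 10000,
                                min_f = 10), iv_config)
  iv <- select_instruments(outcome, ld = ld, pval = cfg$pval, r2 = cfg$r2,
                           window_kb = cfg$window_kb, min_f = cfg$min_f)
  if (!nrow(iv$instruments)) stop("no usable instruments at step: reverse_instruments")
  hs <- harmonize(iv$instruments, exposure)
  if (!nrow(hs)) stop("no harmonizable SNPs at step: reverse_harmonize")
  est <- mr_ivw(hs)
  list(estimate = est, pass = est$pval >= alpha)
}
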