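#' Simulation configuration for two-sample MR studies
#'
#' Defaults encode the study conditions the package is calibrated
#' against: a large continuous exposure GWAS (n = 400,000), a binary
#' outcome with 10,556 cases and 400,681 controls, a metabolite-scale
#' mediator GWAS (n = 8,299), and a mediation pathway with
#' `theta = 0.1`, `delta = 0.5`, `theta_m = 0.3` so the true total
#' effect is 0.25 and the true proportion mediated 60%.
#'
#' Exposure instruments are drawn with effect alleles oriented
#' exposure-increasing (`|N(0, sigma_gamma^2)|`). Mediator-specific and
#' (optional) outcome-specific instruments get their own, larger effect
#' scales (`sigma_gamma_med`, `sigma_gamma_out`) reflecting the strong
#' cis effects typical of metabolite and disease GWAS; they are the
#' instruments the mediator->outcome and reverse-MR steps select.
#'
#' @param n_snp Exposure-instrument SNPs (default 100).
#' @param n_snp_mediator Mediator-specific SNPs (default `n_snp`).
#' @param n_snp_outcome Outcome-specific SNPs (default 0; enable for
#'   reverse-MR studies).
#' @param n_exposure Exposure GWAS sample size.
#' @param n_mediator Mediator GWAS sample size.
#' @param n_case,n_control Binary-outcome counts.
#' @param theta Direct exposure -> outcome log-odds per SD.
#' @param delta Exposure -> mediator effect (SD per SD).
#' @param theta_m Mediator -> outcome log-odds per SD.
#' @param pi_pleio Fraction of exposure instruments with horizontal
#'   pleiotropy.
#' @param mu_alpha,sigma_alpha Pleiotropy mean/SD (directional when
#'   `mu_alpha != 0`).
#' @param rho_pleio Correlation between pleiotropic effects and
#'   instrument strength (0 = InSIDE holds).
#' @param maf_range Minor-allele-frequency interval within (0, 0.5].
#' @param sigma_gamma SD of true exposure-instrument effects.
#' @param sigma_gamma_med,sigma_gamma_out Effect SD for mediator- and
#'   outcome-specific instruments.
#' @param sigma_eta SD of per-SNP mediator-pathway heterogeneity
#'   (default `sigma_gamma / 2`).
#' @param seed RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_snp = 100, n_snp_mediator = n_snp,
                       n_snp_outcome = 0,
                       n_exposure = 400000, n_mediator = 8299,
                       n_case = 10556, n_control = 400681,
                       theta = 0.1, delta = 0.5, theta_m = 0.3,
                       pi_pleio = 0, mu_alpha = 0, sigma_alpha = 0,
                       rho_pleio = 0,
                       maf_range = c(0.1, 0.4), sigma_gamma = 0.03,
                       sigma_gamma_med = 0.15, sigma_gamma_out = 0.15,
                       sigma_eta = sigma_gamma / 2, seed = 1) {
  stopifnot(pi_pleio >= 0, pi_pleio <= 1, sigma_gamma > 0,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  if (n_exposure <= 0 || n_mediator <= 0 || n_case <= 0 || n_control <= 0) {
    stop("sample sizes must be positive")
  }
  structure(as.list(environment()), class = "sim_config")
}

# SE of a per-allele effect for a continuous trait of size n.
se_continuous <- function(n, maf) 1 / sqrt(2 * n * maf * (1 - maf))

# Log-odds SE under the case/control approximation.
se_binary <- function(n_case, n_control, maf) {
  sqrt((1 / n_case + 1 / n_control) / (2 * maf * (1 - maf)))
}

#' Simulate a two-sample MR study with known ground truth
#'
#' Generates summary statistics for an exposure, a mediator, and a
#' binary outcome over three disjoint instrument sets (exposure-,
#' mediator-, and optionally outcome-specific SNPs; ids `rsE*`, `rsM*`,
#' `rsO*`). For exposure instrument j: true exposure effect
#' `gamma_j = |N(0, sigma_gamma^2)|`; mediator effect
#' `delta * gamma_j + N(0, sigma_eta^2)`; outcome effect
#' `theta * gamma_j + theta_m * gamma_m_j + alpha_j`, where `alpha_j` is
#' nonzero with probability `pi_pleio` (drawn `N(mu_alpha,
#' sigma_alpha^2)`, optionally correlated with `gamma_j` via
#' `rho_pleio`). Mediator-specific SNPs affect the outcome only through
#' the mediator; outcome-specific SNPs affect only the outcome.
#' Observed effects add independent sampling noise with
#' `se = 1/sqrt(2 n maf (1-maf))` for continuous traits and the
#' case/control log-odds approximation for the outcome; p-values are
#' two-sided Wald. SNPs are placed >= 20 Mb apart so they are
#' independent under any clumping window up to 10,000 kb.
#'
#' @param config A [sim_config()].
#' @return list of class `sim_study`: `exposure`, `mediator`, `outcome`
#'   (summary-statistic data.frames over all SNPs), `truth` (theta,
#'   delta, theta_m, theta_total, proportion_mediated, per-SNP alpha and
#'   gamma, instrument-set labels), `config`.
#' @export
simulate_two_sample <- function(config = sim_config()) {
  cfg <- config
  set.seed(cfg$seed)
  n_tot <- cfg$n_snp + cfg$n_snp_mediator + cfg$n_snp_outcome
  set_lab <- rep(c("exposure", "mediator", "outcome"),
                 c(cfg$n_snp, cfg$n_snp_mediator, cfg$n_snp_outcome))
  snp <- paste0(c(paste0("rsE", seq_len(cfg$n_snp)),
                  if (cfg$n_snp_mediator) paste0("rsM", seq_len(cfg$n_snp_mediator)),
                  if (cfg$n_snp_outcome) paste0("rsO", seq_len(cfg$n_snp_outcome))))
  chr <- as.character(rep_len(1:22, n_tot))
  pos <- integer(n_tot)
  for (k in unique(chr)) {
    idx <- which(chr == k)
    pos[idx] <- 2e7L * seq_along(idx)
  }
  maf <- stats::runif(n_tot, cfg$maf_range[1], cfg$maf_range[2])
  alleles <- matrix(c("A", "G"), n_tot, 2, byrow = TRUE)

  gamma <- numeric(n_tot)     # true exposure effects
  gamma_m <- numeric(n_tot)   # true mediator effects
  Gamma <- numeric(n_tot)     # true outcome effects
  alpha <- numeric(n_tot)

  ie <- set_lab == "exposure"
  im <- set_lab == "mediator"
  io <- set_lab == "outcome"

  gamma[ie] <- abs(stats::rnorm(cfg$n_snp, 0, cfg$sigma_gamma))
  eta <- stats::rnorm(cfg$n_snp, 0, cfg$sigma_eta)
  gamma_m[ie] <- cfg$delta * gamma[ie] + eta
  is_pleio <- stats::runif(cfg$n_snp) < cfg$pi_pleio
  a_raw <- stats::rnorm(cfg$n_snp, 0, 1)
  if (cfg$rho_pleio != 0) {
    zg <- (gamma[ie] - mean(gamma[ie])) / stats::sd(gamma[ie])
    a_raw <- cfg$rho_pleio * zg + sqrt(1 - cfg$rho_pleio^2) * a_raw
  }
  alpha[ie] <- ifelse(is_pleio, cfg$mu_alpha + cfg$sigma_alpha * a_raw, 0)
  Gamma[ie] <- cfg$theta * gamma[ie] + cfg$theta_m * gamma_m[ie] + alpha[ie]

  gamma_m[im] <- abs(stats::rnorm(cfg$n_snp_mediator, 0, cfg$sigma_gamma_med))
  Gamma[im] <- cfg$theta_m * gamma_m[im]

  Gamma[io] <- abs(stats::rnorm(cfg$n_snp_outcome, 0, cfg$sigma_gamma_out))

  se_x <- se_continuous(cfg$n_exposure, maf)
  se_m <- se_continuous(cfg$n_mediator, maf)
  se_y <- se_binary(cfg$n_case, cfg$n_control, maf)

  mk <- function(beta_true, se, n) {
    beta <- beta_true + stats::rnorm(n_tot, 0, se)
    data.frame(snp = snp, chr = chr, pos = pos,
               ea = alleles[, 1], oa = alleles[, 2], eaf = maf,
               beta = beta, se = se,
               pval = pmax(2 * pnorm(-abs(beta / se)), .Machine$double.xmin),
               n = n, stringsAsFactors = FALSE)
  }
  theta_total <- cfg$theta + cfg$delta * cfg$theta_m
  structure(list(
    exposure = mk(gamma, se_x, cfg$n_exposure),
    mediator = mk(gamma_m, se_m, cfg$n_mediator),
    outcome = mk(Gamma, se_y, cfg$n_case + cfg$n_control),
    truth = list(theta = cfg$theta, delta = cfg$delta, theta_m = cfg$theta_m,
                 theta_total = theta_total,
                 proportion_mediated = if (theta_total != 0)
                   cfg$delta * cfg$theta_m / theta_total else NA_real_,
                 gamma = gamma, gamma_m = gamma_m, Gamma = Gamma,
                 alpha = alpha, instrument_set = set_lab, snp = snp),
    config = cfg), class = "sim_study")
}

#' Write a simulated study to disk
#'
#' Emits the three trait files in the package's tab-delimited format and
#' the ground-truth record as a JSON sidecar.
#'
#' @param study A `sim_study`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_sim_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(exposure = file.path(dir, "exposure.tsv"),
             mediator = file.path(dir, "mediator.tsv"),
             outcome = file.path(dir, "outcome.tsv"),
             truth = file.path(dir, "truth.json"))
  write_sumstats(study$exposure, paths[["exposure"]])
  write_sumstats(study$mediator, paths[["mediator"]])
  write_sumstats(study$outcome, paths[["outcome"]])
  jsonlite::write_json(study$truth[c("theta", "delta", "theta_m",
                                     "theta_total", "proportion_mediated")],
                       paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

# AR(1) correlation matrix, PSD by construction.
ar1_ld <- function(m, rho) {
  stopifnot(abs(rho) < 1)
  rho^abs(outer(seq_len(m), seq_len(m), `-`))
}

#' Simulate a cis locus for SMR / HEIDI
#'
#' Builds an m-SNP locus with AR(1) LD (parameter `rho`). In
#' `pleiotropy` mode a single causal variant (the centre SNP) drives
#' both the eQTL and GWAS signals, so after LD propagation
#' `b_gwas(true) = beta_smr * b_eqtl(true)` at every SNP. In `linkage`
#' mode two distinct causal variants (eQTL-only at the centre, GWAS-only
#' `sep` positions away, LD `r = rho^sep`) make the per-SNP SMR ratios
#' heterogeneous. In `null` mode there is no GWAS signal. Observed
#' effects add sampling noise with `se = 1/sqrt(2 n maf(1-maf))` per
#' study (case/control approximation on the GWAS side) and LD-induced
#' correlation `cov = D R D`.
#'
#' @param m SNP count (>= 3).
#' @param rho AR(1) LD parameter (|rho| < 1).
#' @param mode `"pleiotropy"`, `"linkage"`, or `"null"`.
#' @param beta_smr True expression -> outcome effect (pleiotropy mode).
#' @param b_qtl Causal cis-eQTL effect (default 0.25 SD per allele, the
#'   scale of strong eQTLGen top signals).
#' @param b_gwas_linkage Causal GWAS effect in linkage mode (default
#'   0.15 log-odds per allele, a strong GWAS locus at this outcome's
#'   sample size, z about 9).
#' @param n_eqtl eQTL study size (default 31,684).
#' @param n_case,n_control GWAS outcome counts.
#' @param maf Shared minor-allele frequency (default 0.3).
#' @param sep Causal-variant separation in linkage mode (default 2).
#' @param gene_id Label carried through to [smr_screen()].
#' @param seed RNG seed.
#' @return list of class `cis_locus`: `snp`, `b_eqtl`, `se_eqtl`,
#'   `b_gwas`, `se_gwas`, `ld` (r matrix), `mode`, `gene_id`, `truth`
#'   (beta_smr_true, causal indices, true effect vectors).
#' @export
simulate_cis_locus <- function(m = 20, rho = 0.9,
                               mode = c("pleiotropy", "linkage", "null"),
                               beta_smr = 0.3, b_qtl = 0.25,
                               b_gwas_linkage = 0.15,
                               n_eqtl = 31684, n_case = 10556,
                               n_control = 400681, maf = 0.3, sep = 2,
                               gene_id = "gene", seed = 1) {
  mode <- match.arg(mode)
  stopifnot(m >= 3)
  set.seed(seed)
  R <- ar1_ld(m, rho)
  c1 <- ceiling(m / 2)
  b_eqtl_true <- b_qtl * R[, c1]
  if (mode == "pleiotropy") {
    b_gwas_true <- beta_smr * b_eqtl_true
    causal <- c(eqtl = c1, gwas = c1)
  } else if (mode == "linkage") {
    c2 <- min(m, c1 + sep)
    b_gwas_true <- b_gwas_linkage * R[, c2]
    causal <- c(eqtl = c1, gwas = c2)
  } else {
    b_gwas_true <- rep(0, m)
    causal <- c(eqtl = c1, gwas = NA)
  }
  se_e <- rep(se_continuous(n_eqtl, maf), m)
  se_g <- rep(se_binary(n_case, n_control, maf), m)
  L <- chol(R + diag(1e-10, m))
  corr_noise <- function(se) se * drop(crossprod(L, stats::rnorm(m)))
  structure(list(
    snp = paste0(gene_id, "_snp", seq_len(m)),
    b_eqtl = b_eqtl_true + corr_noise(se_e), se_eqtl = se_e,
    b_gwas = b_gwas_true + corr_noise(se_g), se_gwas = se_g,
    ld = R, mode = mode, gene_id = gene_id,
    truth = list(beta_smr_true = if (mode == "pleiotropy") beta_smr else NA_real_,
                 causal = causal, b_eqtl_true = b_eqtl_true,
                 b_gwas_true = b_gwas_true)),
    class = "cis_locus")
}
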