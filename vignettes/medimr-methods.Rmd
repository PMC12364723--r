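---
title: "Methods: mediation Mendelian randomization with medimr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mediation Mendelian randomization with medimr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medimr)
```

# The causal model

medimr analyses a two-stage network of causal effects on GWAS summary
statistics: a dietary exposure $X$ (food intake or food liking, SD
units), a plasma-metabolite mediator $M$ (SD units), and a binary
outcome $Y$ (urolithiasis, log-odds). The structural effects are the
direct effect $\theta$ of $X$ on $Y$, the exposure–mediator effect
$\delta$, and the mediator–outcome effect $\theta_m$, so that the total
effect is $\theta_{tot} = \theta + \delta\,\theta_m$ and the proportion
mediated is $\delta\,\theta_m/\theta_{tot}$.

Each effect is estimated by two-sample MR under the instrumental-variable
assumptions: instruments are associated with their trait (enforced by the
p-value and F-statistic filters), independent of confounders (by random
allele assortment), and affect the outcome only through the trait
(probed, not guaranteed, by the pleiotropy diagnostics).

# Instrument selection

Three filters, applied in order:

1. **Association**: retain SNPs with $p$ strictly below the threshold.
   Default $5\times10^{-6}$; a stringent $5\times10^{-8}$ mode exists for
   sensitivity analyses. Both are plain configuration — no analysis
   hard-codes either value.
2. **Independence**: greedy LD clumping. Repeatedly take the lowest-$p$
   unclumped SNP as index and remove same-chromosome SNPs within
   10,000 kb with $r^2 \ge 0.001$ against it. Ties in $p$ break by
   position then SNP id, so output is a pure function of the data. A
   missing LD value for an in-window pair is treated as $r^2 = 1$
   (conservative removal) and logged.
3. **Strength**: F-statistic $(\beta/\sigma)^2 < 10$ excludes the SNP
   (strict). The squared Wald $z$ equals the regression F for a
   standardized trait; the $R^2$-based form
   $F = R^2(n-2)/(1-R^2)$, $R^2 = 2f(1-f)\beta^2$, is available as an
   option.

Harmonization aligns all traits to the exposure's effect allele,
flipping signs (and $1-\mathrm{EAF}$) for swapped alleles, attempting
strand-complement reconciliation before declaring a SNP irreconcilable,
and removing **all** palindromic SNPs. We deliberately do not attempt
frequency-based rescue of palindromic SNPs: with no stated frequency
rule, inferring strand from EAF near 0.5 is error-prone, and removal is
the conservative reading.

# Estimators and their numerical conventions

**IVW with multiplicative random effects** is the primary estimator:
precision-weighted mean of Wald ratios, fixed-effect SE inflated by
$\sqrt{\max(1, Q/(J-1))}$. The floor at 1 never lets heterogeneity
*shrink* an SE. The first-order ratio SE $\sigma_y/|\hat\gamma_x|$ is
used for weights (the dominant convention, adequate under the F
filter); a second-order version is available.

**MR-Egger** orients each SNP so $\hat\gamma_x \ge 0$ (flipping both
coordinates leaves the model invariant), fits WLS with free intercept
and weights $1/\sigma_y^2$, and inflates both SEs by
$\sqrt{\max(1, RSS_w/(J-2))}$. Inference uses normal quantiles for
consistency with the other estimators; this is a documented deviation
knob from t-based Egger inference. At least 3 SNPs are required.

**Weighted median** interpolates the ratio versus the standardized
cumulative weight $p_i = (S_i - w_i/2)/S$ at $p = 0.5$. The SE is the
SD over a seeded parametric bootstrap (each ratio redrawn from
$N(\hat\beta_i, \sigma_i^2)$, default 1000 resamples) — the estimator
has no closed-form SE and the bootstrap convention is ours.

**MVMR** regresses outcome effects on the $K$ exposure-effect columns
without intercept, weights $1/\sigma_y^2$. $K=1$ reduces exactly to
fixed-effect IVW. Fixed-effect SEs are the default (inflation behind a
flag): with instruments pre-screened per exposure, the MVMR residual df
is small and multiplicative inflation is noisy.

P-values are floored at the smallest positive double and never reported
as zero. OR blocks use $\exp(\beta \mp 1.959964\,\sigma)$, and
`p_from_or_ci()` inverts that convention to recover a Wald $p$ from a
published OR and 95% CI.

**MR-PRESSO** computes the weighted RSS around leave-one-out
fixed-effect IVW fits and simulates its null by redrawing both effect
sets from their sampling distributions (default 1000 draws, seeded).
All p-values use the add-one estimator, so they live in
$[1/(n_{sim}+1), 1]$. Outliers are flagged at Bonferroni
$0.05/J$ (the published convention); the distortion test compares the
estimate before/after removal against random pseudo-outlier sets.

# Mediation and screening conventions

The "stepwise" mediation estimator is the two-step product of
coefficients: $\beta_{tot}$ and $\beta_{X\to M}$ from the exposure's
instruments, $\beta_{M\to Y}$ from the *mediator's own* instruments
(univariable IVW; an MVMR-adjusted variant is available behind a flag).
The indirect effect is the product, its SE the delta-method combination
$\sqrt{\beta_{XM}^2\sigma_{MY}^2 + \beta_{MY}^2\sigma_{XM}^2}$, and the
proportion mediated the ratio to the total effect — reported as an
unclipped percentage. Only direction-consistent combinations
(indirect and total effects of equal sign; an exact zero passes with
proportion 0) are reported by the screening layer, and reverse MR
(outcome as exposure) must show no association at the 0.05 level.

A pair survives the sensitivity screen only if the Egger intercept,
Cochran's Q, and the PRESSO global test all have $p \ge 0.05$; the
pipeline screens at the nominal 0.05 (to surface as many candidate
mediation signals as possible) while also emitting Benjamini–Hochberg
adjusted columns for transparency.

# SMR and HEIDI

At the top cis-eQTL SNP (largest $|z_{eQTL}|$, gated at
$z^2 \ge 10$ in parallel with the F rule), the SMR estimate is
$\hat\beta_{SMR} = \hat b_{GWAS}/\hat b_{eQTL}$ and the test statistic
$t = z^2_{GWAS} z^2_{eQTL}/(z^2_{GWAS}+z^2_{eQTL}) \sim \chi^2_1$.
HEIDI asks whether the per-SNP SMR ratios across the locus are
consistent with one shared causal variant: for each selected non-top
SNP, $d_i = \hat\beta_{SMR,i} - \hat\beta_{SMR,top}$, with the
covariance of $d$ from the delta method and the LD-induced correlation
of effect estimates within each study. SNP selection follows the
published tool defaults (eQTL $p < 1.6\times10^{-3}$, $r^2$ with the
top SNP in $[0.05, 0.9]$, top-20 by $|z_{eQTL}|$) — imported
conventions, configurable. The null of $\sum z_{d_i}^2$ is evaluated by
seeded Monte-Carlo from the fitted multivariate normal (default 20,000
draws; exact in the limit, and the add-one p at the 0.01 decision
threshold is resolved with ample margin at this size). A non-PSD
covariance after jitter marks HEIDI unavailable for that gene — never
silently passed. Genes pass the screen with SMR $p < 0.05$ and HEIDI
$p \ge 0.01$.

# The synthetic-data generator

`simulate_two_sample()` emulates the study conditions the package is
built for: a large continuous exposure GWAS ($n = 400{,}000$), a
metabolite-scale mediator GWAS ($n = 8{,}299$), and a binary outcome
with 10,556 cases / 400,681 controls. Sampling SEs follow
$1/\sqrt{2n f(1-f)}$ for continuous traits and the case/control
log-odds approximation
$\sqrt{(1/n_{ca}+1/n_{co})/(2f(1-f))}$; MAF is uniform on
$[0.1, 0.4]$. Defaults for the pathway are $\theta = 0.1$,
$\delta = 0.5$, $\theta_m = 0.3$: total effect 0.25, proportion
mediated 60%.

Design choices worth stating:

- **Disjoint instrument sets.** Exposure-specific SNPs
  ($|\gamma| \sim |N(0, 0.03^2)|$, a plausible per-SNP scale for
  behavioural traits at biobank power) carry the mediation pathway;
  mediator-specific SNPs get the larger effects ($SD = 0.15$) typical
  of metabolite cis loci. Because the mediator GWAS is small, exposure
  SNPs essentially never reach $p < 5\times10^{-6}$ on the mediator, so
  p-value selection cleanly assigns each step its own instruments —
  mirroring how food-liking and metabolite instruments separate in
  practice. Optional outcome-specific SNPs enable reverse-MR studies.
- **Effect-allele orientation.** Effect alleles are oriented
  exposure-increasing, so directional pleiotropy
  ($\mu_\alpha \ne 0$) is identifiable by the Egger intercept in
  simulation, as in standard MR simulation designs.
- **Mediator-pathway heterogeneity** ($\sigma_\eta = \sigma_\gamma/2$)
  makes per-SNP mediator effects imperfectly proportional to exposure
  effects — genuine balanced heterogeneity that the MRE SE is designed
  to absorb.
- **Placement**: SNPs sit ≥ 20 Mb apart, independent under any clumping
  window up to 10,000 kb, so LD handling can be tested separately via
  explicit LD matrices.
- **InSIDE**: pleiotropic effects are drawn independently of instrument
  strength by default; `rho_pleio` correlates them to stress-test
  Egger.

`simulate_cis_locus()` builds AR(1)-correlated loci
($R_{ij} = \rho^{|i-j|}$, PSD by construction, one parameter). In
pleiotropy mode one causal variant (eQTL effect 0.25, the scale of
strong eQTLGen top signals) drives both traits, so every SNP's true SMR
ratio equals $\beta_{SMR}$. In linkage mode distinct eQTL and GWAS
causal variants sit two positions apart; the GWAS causal effect
defaults to 0.15 log-odds ($z \approx 9$ at this outcome's sample
size) — a strong GWAS locus, which is the regime where HEIDI is
expected to have power. Observed effects add noise with covariance
$D R D$ (LD-propagated sampling correlation).

What the generator does *not* emulate: realistic human LD maps, sample
overlap between studies, allele-frequency mismatch between cohorts,
population stratification, or winner's-curse-free discovery (instrument
selection and estimation use the same exposure scan, as in the real
single-discovery setting). Calibration results on synthetic data
therefore demonstrate internal statistical correctness, not robustness
to those data pathologies.

# Calibration scale and known limitations

The shipped calibration suites use 500 replicates for IVW
bias/coverage/size and the SMR/HEIDI operating characteristics, 200 for
Egger intercept recovery, mediation recovery, and PRESSO null
uniformity, and 100 for PRESSO outlier detection — sizes at which
binomial Monte-Carlo error is a percentage point or two, comfortable
for the bands being checked.

Two properties deserve explicit statement:

- **IVW size with the MRE floor.** Because $\max(1, Q/(J-1))$ only ever
  inflates, the IVW test is mildly conservative under the exact null
  (measured type-I error near 4% at the 5% level).
- **Proportion-mediated ratio bias.** The per-replicate proportion
  $\widehat{ind}/\widehat{tot}$ is median-unbiased, but its *mean*
  across replicates is inflated by roughly
  $\mathrm{CV}(\widehat{tot})^2$ (Jensen's inequality on the noisy
  denominator) — about +3 points at the default conditions, where the
  total effect has CV ≈ 24%. Recovery checks therefore summarise by the
  pooled components (ratio of replicate-mean legs) and the median, and
  users averaging reported proportions across weak total effects should
  expect the same upward drift.

Degenerate inputs are handled explicitly rather than silently: one
ratio degrades IVW to a flagged Wald estimate; fewer than 3 (Egger,
weighted median) or 4 (PRESSO) SNPs refuse with an informative error;
an empty harmonization intersection warns and returns an empty set;
zero usable instruments at any mediation step fails with the step
label; a HEIDI covariance that is not PSD after jitter is reported
unavailable.

# Pipeline

`run_pipeline()` executes the stages in study order — exposure→outcome
MR, metabolite→outcome MR, nominal-significance screening with the
sensitivity consistency rule, exposure→metabolite MR plus mediation for
screened pairs, reverse MR, MVMR over screened exposures, SMR+HEIDI
over supplied cis loci, nearest-gene annotation — writing one TSV per
stage plus a JSON manifest recording seeds, thresholds, and per-stage
status. Failures isolate: a failing trait pair or stage is recorded in
the manifest and the rest of the run proceeds. Reruns with the same
config and seeds are byte-identical. The package is driven from R (or
`Rscript -e`); `scripts/acceptance.R` is a worked example of scripting
it end to end.
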