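---
title: "Kin-cohort survival GWAS of parental lifespan: models and methods"
author: "kinspan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kin-cohort survival GWAS of parental lifespan: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinspan)
```

## The kin-cohort design

Human lifespan cannot be measured on genotyped subjects who are still
alive, but most genotyped adults can report how long their parents lived.
The kin-cohort design exploits this: subject genotypes are tested for
association with *parental* survival. Because a parent transmits exactly
one of two alleles to the offspring, the offspring's dosage carries half
of the per-allele effect present in the parent who lived (or died) — the
squared correlation between offspring dosage and either parent's genotype
is 0.25 under Mendelian transmission. Effects estimated on offspring
dosage are therefore doubled to recover the effect in the allele carrier
themselves.

The survival model is a Cox proportional-hazards model for parent age at
death $x$,

$$h(x) = h_0(x)\, e^{\beta X + \gamma_1 Z_1 + \dots + \gamma_k Z_k},$$

with $X$ the offspring dosage (0–2) and $Z$ the covariates. Rather than
fitting one Cox model per SNP — infeasible at millions of markers — the
pipeline fits a covariates-only Cox model once per parent sex, extracts
the Martingale residuals (event indicator minus fitted cumulative
hazard), and divides them by the proportion of parents dead, $c$. The
scaled residual is an approximately hazard-ratio-scaled trait: the OLS
slope of this trait on dosage estimates the per-allele log hazard ratio.
All reported effects are negated to the **log protection ratio** (lnPR)
scale, on which positive values mean longer life, and converted to years
of life by the actuarial rule of thumb $\text{years} = 10 \times
\text{lnPR}$.

Estimates and standard errors are doubled exactly once, at single-parent
record creation (`gwasSingleParent`). The combined-parent trait
(`combineCES`) regresses the *sum* of father and mother residuals on
dosage: under a common effect in both parents this slope is already on
the carrier scale, and its standard error automatically absorbs the
covariance between the two parents' traits, so it is never doubled again.
A unit test enforces this single-doubling rule, which is the classic
pitfall of the design.

Two combined analyses are available:

* **CES** (common effect sizes): the summed-residual regression above;
  one beta per SNP.
* **SSE** (sex-specific effect sizes): the father and mother Z statistics
  are combined into the 2-df bivariate Wald statistic
  $z' R^{-1} z$ with $R$ the trait correlation matrix (off-diagonal
  $r \approx 0.1$, measured directly from the residuals). This tests
  whether *either* parental effect is nonzero and produces no single
  beta.

Because both scans run on the same markers, the genome-wide significance
constant is Bonferroni-halved to $2.5 \times 10^{-8}$
(`genomewideThreshold`).

When only summary statistics are available per parent (no individual
residuals), `metaCesCorrelated` pools them by inverse-variance weighting
and inflates the pooled standard error by $\sqrt{1 + r}$; for two
estimates the exact variance factor
$1 + 2 r s_1 s_2 / (s_1^2 + s_2^2)$ is also exposed. The
$\sqrt{1+r}$ form is conservative, with equality when $s_1 = s_2$.

## The synthetic cohort generator

No individual-level biobank data can ship with a package, so every
downstream stage is exercised on cohorts drawn by `simulateCohort`. The
generator reproduces the statistical features the analysis relies on:

* **Baseline mortality** is Gompertz, $h_0(x) = a e^{bx}$, with defaults
  $a = 2\times10^{-5}$/yr and $b = 0.1$/yr, putting the modal age at
  death in the mid-80s. The analysis of real data is semi-parametric and
  assumes no baseline; Gompertz is chosen here because it yields closed
  forms — the conditional survival and quantile functions
  (`gompertzConditionalSurvival`, `gompertzConditionalQuantile`) are the
  oracles the tests compare against.
* **Left truncation at 40**: death ages are drawn by inverse transform
  from the Gompertz survival conditioned on reaching age 40, mirroring
  the exclusion of parents dying at 40 or younger. No resampling is
  needed; truncation is exact by construction.
* **Genotype effects** enter the parent's own log hazard as
  $-\beta_{\text{lnPR}}$ per effect allele (additive) or only for effect
  homozygotes (recessive mode, used to exercise the recessive-to-additive
  conversion).
* **Parent-pair correlation**: the two parents of a subject share a
  Gaussian log-frailty. Its standard deviation (`rho`, default 0.45) was
  calibrated once, numerically, so that the father–mother
  Martingale-residual correlation is approximately 0.1 — the value
  measured on the real parental traits. The observed phenomenon is the
  correlation, not its mechanism; shared frailty is the simplest
  generator of it.
* **Censoring**: parents alive at a censoring age drawn Uniform(70, 100)
  years are recorded alive at that age (capped at 120). This window was
  chosen so that about 60% of simulated parents are deceased, the
  proportion reported for the 1,012,240 analysed parental lifespans; the
  censoring-age distribution of real biobank parents is not published,
  so only this one moment is matched. Note that mild violation of
  proportional hazards across the whole age range is *intended*: marginal
  hazards under shared frailty are not exactly proportional, just as
  real covariate-adjusted hazards are not.
* **Covariates**: subject sex and two standard-normal nuisance
  covariates (stand-ins for genotyping-array and principal-component
  covariates, independent of genotype by construction, so they guard the
  code paths rather than inject confounding).
* **Determinism**: every stochastic function takes an explicit seed, uses
  a private RNG scope, and restores the caller's RNG stream.

What the generator deliberately does **not** emulate: linkage
disequilibrium (pruning and clumping are tested against explicit LD
matrices instead), population stratification, genotyping error or
imputation uncertainty, secular trends in mortality, and non-random
reporting of parental ages. Green tests therefore demonstrate the
correctness of the estimators under the model's own assumptions, not
robustness to those real-data complications.

## Scale conversions

External studies report effects on scales that must be aligned before
replication analysis:

* `martingaleRescale`: effects estimated on rank-normalised Martingale
  residuals are returned to the lnHR scale via
  $\sqrt{c} \times 1/c = 1/\sqrt{c}$, optionally doubled to the carrier.
* `recessiveToAdditive`: a purely recessive homozygote effect observed
  through imputed parental genotypes appears under an additive fit as
  $\beta_{\text{hom}}\, q^2/(q^2 + 2pq)$ on the carrier scale — the
  probability that the transmitting parent is homozygous given
  transmission. At $q = 0.269$ the frequency factor is 0.155.
* `longevityCalibration`: longevity case–control log odds ratios are
  mapped to lnHR empirically through an anchor variant measured on both
  scales; the direction of the stored factor is explicit because
  published constants use both orientations.
* `equivalentSampleSize`: the power dilution of the design — trait
  heritability $\times$ kin $r^2$ (0.25) $\times$ proportion dead —
  expressed as an equivalent directly-measured-trait sample size.

## Replication machinery

Collective replication against external longevity studies pools the
per-SNP ratio $\alpha = \beta_{\text{rep}}/\beta_{\text{disc}}$ by
inverse variance (`alphaRatio`, `metaAlpha`), with the first-order
delta-method standard error
$\sqrt{SE_\text{rep}^2/\beta_\text{disc}^2 + \beta_\text{rep}^2
SE_\text{disc}^2/\beta_\text{disc}^4}$. The first-order form is kept
exactly as published; a parametric bootstrap in the test suite documents
that it is accurate at high discovery signal-to-noise and biased when
$|\beta_\text{disc}|/SE_\text{disc}$ is small. One-sided p-values test
$\alpha = 0$ against the alternative that replication shares the
discovery sign; since $\alpha$ is sign-relative to discovery by
construction, this is $\Phi(-\hat\alpha/SE_\alpha)$ for protective and
deleterious discovery alleles alike. Sample overlap between studies is
handled by estimating the error correlation among null SNPs
($|Z| < 1$ in both studies, `estimateNullOverlap`) and adding
$2\sum_{n<m} w_n w_m \mathrm{Cov}_{nm}$ to the pooled variance
(`metaOverlapAdjusted`). Overlap adjustment is applied on the converted
(lnPR) scale; the alternative order is not distinguishable from
published information. Note that conditioning on $|Z|<1$ attenuates the
estimated correlation by roughly $\mathrm{Var}(Z \mid |Z|<1) \approx
0.29$; at the tiny overlaps this estimator is used for
($r \sim 0.01$) the attenuation is immaterial, and the estimate is used
as-is, matching the published procedure.

## Risk-factor-informed GWAS (iGWAS)

The Bayesian scan combines each SNP's observed association Z with a prior
built from the SNP's effects on mortality risk factors:

1. `fitMultivariateMR`: weighted multivariate regression (through the
   origin) of lifespan effects on the factor-effect matrix over
   instruments off the focal chromosome; factors chosen by AIC stepwise
   search. AIC is retained knowingly: it admits a superfluous factor with
   asymptotic probability $P(\chi^2_1 > 2) \approx 0.16$, and the tests
   assert the selection rate AIC actually implies.
2. `buildPriors`: prior mean $\mu = \sum_k \theta_k b_k$; prior variance
   is the first-order propagation of that sum **plus one**, the unit
   accounting for priors being built from observed (noisy) Z-scores.
   Several variance conventions exist for such priors; the delta-method
   propagation used here is isolated in this one function so an
   alternative can be swapped in.
3. `bayesFactor`: the normal–normal marginal likelihood ratio
   $\log N(z;\mu,\sigma^2) - \log N(z;0,1)$, zero for the null prior
   $(\mu = 0, \sigma^2 = 1)$.
4. `permutationPvalues`: observed Z values are permuted across SNPs
   against the fixed priors; all null log-BFs are pooled and the
   empirical p is $(1 + \#\{\text{null} \ge \text{obs}\})/(1 + N)$,
   floored at $1/(1+N)$ with floor-limited SNPs flagged; BH q-values
   follow. The desk-scale default ($10^3$–$10^4$ SNPs $\times$
   $10^2$–$10^3$ permutations) is the same computation as the published
   billions-scale run, smaller only in size.

## Stratified effects and disease attribution

`stratifySurvival` re-fits the Cox model on age-band-truncated data
(default decades 40–90 plus 90–120): parents dying before a band are
excluded, parents surviving past it are censored at its end. The band
estimates have independent errors across bands, so
`moderatorRegression` fits
$\beta(\text{band, sex}) = \beta_0 + \beta_1 \cdot \text{age} +
\beta_2 \cdot \text{male}$ by weighted least squares with *known*
variances — standard errors come from $(X'WX)^{-1}$ without residual
rescaling. Age is coded as the band midpoint in years (so slopes have
per-year units) and sex as male = 1 against a female reference.

Disease attribution uses an independent panel of disease-associated
SNPs: `pruneLoci` (greedy by p-value, 500 kb / $r^2 < 0.1$; distance-only
when no LD matrix is available, a documented divergence from analyses
with genotype LD at hand), lifespan variance explained
$\text{LVE} = 2pqa^2$ in years², the one-false-positive FDR rule
(BH threshold $1/n$, truncated to 3 decimals — reproducing both
published thresholds, 0.022 at $n=45$ and 0.016 at $n=60$), the
double-Z rule marking a SNP secondary when another disease's |Z| is at
least twice the nominal disease's (boundary inclusive), and a Fisher's
exact test harness for age-related-expression enrichment. The FDR family
is a parameter, since published analyses use differently scoped
families.

## Polygenic survival scores

`buildPRS` clumps (250 kb / $r^2 < 0.1$) and thresholds summary
statistics (default $p \le 1$: all independent markers, the
configuration found most informative for lifespan); training cohort
labels are recorded and scoring a training cohort is refused.
`scorePRS` standardises on the scored sample; `associateSurvival` fits
the Cox association per score SD, doubled for parent phenotypes only;
`decileContrast` reports Kaplan–Meier median-survival differences
between top and bottom score deciles (deciles by sample quantiles with
stable first-rank tie-breaking; unreached medians are reported as
censoring-time lower bounds and flagged — the source analyses are
silent on both choices). `diseaseAssociations` regresses *not* carrying
each disease on the score (so positive = protective), doubles
first-degree-relative estimates, meta-analyses across kin, and inflates
pooled SEs by $\sqrt{1+r}$ per kin correlation; the literal $(1+r)$
variant is available behind a switch because the published text and its
displayed equation disagree, and neither is endorsed here.

## Numerical choices

* Cox fits: Breslow tie handling, convergence tolerance $10^{-9}$,
  at most 50 Newton iterations; non-convergence is an error, not a
  warning.
* The residual-on-dosage OLS re-includes the Cox covariates. Residuals
  are orthogonal to the covariates only up to Cox-model nonlinearity, so
  re-inclusion guards against residual confounding and is harmless when
  orthogonal.
* Missing dosages are mean-imputed per SNP; monomorphic SNPs return NA
  with a warning rather than failing the scan. The MAF filter default is
  0.005.
* Strand-ambiguous A/T and C/G SNPs are dropped during harmonisation
  when the allele frequency is in [0.4, 0.6].
* Empirical p-values use the add-one rule and are floored at
  $1/(1+N_{\text{null}})$.

## Problem sizes used by the test suite

The suite exercises the estimators at sizes chosen to make sampling
error small relative to the tested tolerances while keeping a laptop run
short: parameter-recovery cohorts of 8,000–20,000 subjects with up to 50
SNPs; a 3,000-subject, 5,000-SNP all-null cohort for calibration (KS
uniformity and genomic-inflation checks); 50 paired replicates of 1,000
SNPs for the prior-informed power comparison; 1,000 simulated
replication pairs for delta-method CI coverage. The published analyses
are the same computations at biobank scale.

## Known limitations

* The Martingale-residual trait is a first-order approximation to the
  per-SNP Cox fit; agreement is verified against the partial-likelihood
  oracle at realistic effect sizes (|lnPR| ≤ 0.3) and will degrade for
  very large effects.
* Headline discoveries of the original biobank analyses (specific loci,
  heritability) require the real data and are out of reach of any
  synthetic check; what the suite verifies is the machinery, its
  calibration, and every self-contained arithmetic result.
* No mixed-model relatedness adjustment is provided: under the
  kin-cohort model the usual GRM covariance is mis-specified for
  parental phenotypes, and exclusion of relatives is the supported
  approach.
* No X-chromosome dosage model, no real genotype formats (VCF/PLINK) in
  this version.
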