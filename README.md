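# kinspan

Kin-cohort survival GWAS of parental lifespan, as an R package.

Human lifespan is hard to study genetically: genotyped subjects are
mostly still alive. The kin-cohort design sidesteps this by associating
**subject genotypes with parental survival** — each parent transmitted
one of two alleles to the subject, so the offspring dosage carries half
the per-allele effect in the parent, and estimates are doubled back to
the carrier scale. `kinspan` implements the full analytical pipeline of
a biobank-scale parental-lifespan GWAS, together with a synthetic cohort
generator so that every stage runs and is tested without access to any
real biobank.

## What it implements

* **Residualised Cox phenotype** — a covariates-only Cox proportional
  hazards fit per parent sex; Martingale residuals divided by the
  proportion dead give a hazard-ratio-scaled trait for fast linear GWAS
  (`residualPhenotype`, `gwasSingleParent`). Effects are reported as
  log protection ratios (lnPR; positive = longer life), with
  years of life per allele = 10 × lnPR.
* **Parent-trait combination** — common effect sizes via the summed
  parent residual (`combineCES`), sex-specific effects via the 2-df
  bivariate MANOVA statistic z′R⁻¹z (`combineSSE`), and
  correlation-adjusted inverse-variance meta-analysis with the
  √(1+r) standard-error inflation (`metaCesCorrelated`). Genome-wide
  significance for the two-test scan is 2.5e-8 (`genomewideThreshold`).
* **Scale conversions** — rank-normalised Martingale residual → lnHR
  (`martingaleRescale`), recessive homozygote effect → expected additive
  carrier effect q²/(q²+2pq) (`recessiveToAdditive`), longevity log-OR ↔
  lnHR anchor calibration (`longevityCalibration`), equivalent sample
  size of the diluted design (`equivalentSampleSize`).
* **Collective replication** — per-SNP replication/discovery ratios with
  delta-method SEs (`alphaRatio`), inverse-variance pooling with anchor
  exclusion (`metaAlpha`), and sample-overlap adjustment from null-SNP
  covariance (`estimateNullOverlap`, `metaOverlapAdjusted`).
* **Risk-factor-informed GWAS (iGWAS)** — priors from multivariate MR
  causal estimates (`fitMultivariateMR`, `buildPriors`), normal-normal
  Bayes factors (`bayesFactor`), permutation p-values and BH q-values
  (`permutationPvalues`, `igwas`).
* **Stratified effects** — age-band × sex Cox estimates on truncated
  data (`stratifySurvival`) and fixed-effects known-variance moderator
  meta-regression (`moderatorRegression`).
* **Disease attribution** — greedy locus pruning (`pruneLoci`), lifespan
  variance explained 2pqa² (`lifespanVarianceExplained`), the
  one-false-positive FDR rule (`fdrOneFalsePositive`), the double-Z
  pleiotropy classifier (`classifyPleiotropy`), category LVE totals
  (`sumLveByCategory`) and a Fisher enrichment harness
  (`fisherEnrichment`).
* **Polygenic survival scores** — clump+threshold models with a
  training/test leakage guard (`buildPRS`, `scorePRS`), Cox association
  per score SD (`associateSurvival`, `scoreAndAssociate`), decile
  Kaplan-Meier contrasts (`decileContrast`) and kin-correlation-adjusted
  disease associations (`diseaseAssociations`).
* **Synthetic cohorts** — Gompertz baseline mortality left-truncated at
  40, per-allele proportional hazard effects, shared parent-pair
  frailty calibrated to a residual correlation of 0.1, censoring tuned
  to ~60% of parents deceased, and risk-factor summary statistics with
  known causal structure (`simulateCohort`, `simulateGenotypes`,
  `simulateLifespans`, `simulateRiskFactorStats`).

The central data object, `LifespanCohort`, extends
`SummarizedExperiment`: a SNP × subject dosage assay, the SNP manifest
as `rowData`, and subject covariates plus both parents' survival records
in `colData`.

## Worked example

```r
library(kinspan)

snps <- snpSpec(id = c("rs_apoe", "rs_chrna", "rs_null"),
                maf  = c(0.15, 0.35, 0.25),
                beta = c(0.106, 0.044, 0))   # carrier lnPR per allele
cohort <- simulateCohort(20000, snps, cohortId = "demo", seed = 1)
cohort
#> LifespanCohort 'demo': 20000 subjects, 3 SNPs
#>   parent lives: 40000 (23943 deaths, 59.9% dead)
#>   covariates: sex, pc1, pc2

ces <- combineCES(cohort)
print(ces, digits = 3)
#>             snpid a1 a0 freq1     beta     se      z      p n_lives n_deaths
#> rs_apoe   rs_apoe  A  G 0.151  0.05646 0.0270  2.093 0.0363   40000    23943
#> rs_chrna rs_chrna  A  G 0.346  0.04342 0.0202  2.150 0.0315   40000    23943
#> rs_null   rs_null  A  G 0.248 -0.00261 0.0223 -0.117 0.9068   40000    23943

f <- gwasSingleParent(cohort, "father")
m <- gwasSingleParent(cohort, "mother")
print(combineSSE(f, m, r = 0.1), digits = 3)
#>      snpid chisq df      p
#> 1  rs_apoe 4.455  2 0.1078
#> 2 rs_chrna 5.144  2 0.0764
#> 3  rs_null 0.339  2 0.8439

round(yearsFromLnpr(ces$beta), 2)
#> [1]  0.56  0.43 -0.03
```

The CES `beta` column is the carrier-scale lnPR per effect allele: the
two causal SNPs are recovered near their simulated effects (0.106 and
0.044; a 20,000-subject cohort leaves visible sampling noise around the
weaker one) while the null SNP sits at zero, and the last line converts
the estimates to years of life per allele. A simulated cohort can also
be written/read as TSV (`writeCohortTable`, `readCohortTable`) or
generated from the shell with `inst/scripts/simcohort.R`.

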