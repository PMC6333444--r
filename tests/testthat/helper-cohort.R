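# small fixtures built in code, shared across test files

nullSnps <- function(m, maf = 0.3) {
  snpSpec(id = sprintf("rs%04d", seq_len(m)), maf = maf, beta = 0)
}

# cohort with no genetic effects and no covariates beyond the defaults
nullCohort <- function(n, m = 1, seed = 101, ...) {
  simulateCohort(n, nullSnps(m), seed = seed, ...)
}

# direct Cox fit of one parent's lifespan on offspring dosage: the
# partial-likelihood oracle for the residual-method estimates
coxOracle <- function(cohort, parent, snp) {
  rec <- parentRecords(cohort, parent)
  x <- t(dosages(cohort))[, snp]
  fit <- survival::coxph(survival::Surv(rec$age, rec$dead) ~ x)
  c(lnPR = -2 * unname(coef(fit)[1]),
    se = 2 * sqrt(stats::vcov(fit)[1, 1]))
}
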