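test_that("transmission model gives the kin-cohort genotype dilution", {
  g <- simulateGenotypes(50000, snpSpec("rs1", maf = 0.5), seed = 11)
  r2f <- cor(g$dosage[, 1], g$father[, 1])^2
  r2m <- cor(g$dosage[, 1], g$mother[, 1])^2
  expect_gt(r2f, 0.22); expect_lt(r2f, 0.28)
  expect_gt(r2m, 0.22); expect_lt(r2m, 0.28)
})

test_that("dosages follow the binomial expectation and MAF is validated", {
  g <- simulateGenotypes(100000, snpSpec("rs1", maf = 0.2), seed = 12)
  expect_gt(mean(g$dosage), 0.39)
  expect_lt(mean(g$dosage), 0.41)
  expect_error(snpSpec("rs1", maf = 1e-9), "maf")
  expect_error(simulateGenotypes(10, data.frame(id = "a", maf = NaN),
                                 seed = 1), "maf")
})

test_that("null lifespans match the conditional Gompertz closed form", {
  snps <- nullSnps(1)
  g <- simulateGenotypes(20000, snps, seed = 13)
  # censor at the age cap so essentially every parent dies
  ls <- simulateLifespans(g, snps, rho = 0, censorRange = c(119.9, 120),
                          seed = 14)
  medTheory <- gompertzConditionalQuantile(0.5)
  expect_lt(abs(median(ls$father$age[ls$father$dead]) - medTheory), 0.5)
  expect_lt(abs(median(ls$mother$age[ls$mother$dead]) - medTheory), 0.5)
})

test_that("Kaplan-Meier curve of a null cohort tracks the Gompertz model", {
  coh <- nullCohort(10000, seed = 15, rho = 0)
  rec <- parentRecords(coh, "father")
  fit <- survival::survfit(survival::Surv(rec$age, rec$dead) ~ 1,
                           conf.int = 0.99)
  # 99% pointwise Greenwood bands: five correlated ages are checked
  for (age in c(50, 60, 70, 80, 90)) {
    i <- max(which(fit$time <= age))
    s <- gompertzConditionalSurvival(age)
    expect_gt(s, fit$lower[i])
    expect_lt(s, fit$upper[i])
  }
})

test_that("defaults give ~60% of parents deceased and residual cor ~0.1", {
  coh <- nullCohort(20000, seed = 16)
  dead <- c(parentRecords(coh, "father")$dead,
            parentRecords(coh, "mother")$dead)
  expect_gt(mean(dead), 0.55)
  expect_lt(mean(dead), 0.65)
  rf <- residualPhenotype(coh, "father")@residuals
  rm_ <- residualPhenotype(coh, "mother")@residuals
  expect_gt(cor(rf, rm_), 0.05)
  expect_lt(cor(rf, rm_), 0.15)
})

test_that("realised parental lnHR is twice the offspring-dosage effect", {
  snps <- snpSpec(paste0("rs", 1:3), maf = 0.3, beta = c(0, 0.1, 0.3))
  coh <- simulateCohort(15000, snps, rho = 0, seed = 17)
  rec <- parentRecords(coh, "father")
  geno <- t(SummarizedExperiment::assay(coh, "fatherGeno"))
  dose <- t(dosages(coh))
  for (j in 1:3) {
    fitG <- survival::coxph(survival::Surv(rec$age, rec$dead) ~ geno[, j])
    fitD <- survival::coxph(survival::Surv(rec$age, rec$dead) ~ dose[, j])
    se <- sqrt(stats::vcov(fitG)[1, 1] + 4 * stats::vcov(fitD)[1, 1])
    expect_lt(abs(coef(fitG)[1] - 2 * coef(fitD)[1]), 1.96 * se)
    # and the carrier effect realised in parents is the specified lnPR
    expect_lt(abs(-coef(fitG)[1] - snps$beta[j]),
              1.96 * sqrt(stats::vcov(fitG)[1, 1]))
  }
})

test_that("simulation is reproducible by seed and varies across seeds", {
  a <- simulateCohort(200, nullSnps(3), seed = 18)
  b <- simulateCohort(200, nullSnps(3), seed = 18)
  c <- simulateCohort(200, nullSnps(3), seed = 19)
  expect_identical(dosages(a), dosages(b))
  expect_identical(parentRecords(a, "father"), parentRecords(b, "father"))
  expect_false(identical(dosages(a), dosages(c)))
  # and the caller's RNG stream is untouched
  set.seed(1); x1 <- rnorm(1)
  set.seed(1); invisible(simulateCohort(50, nullSnps(1), seed = 20))
  expect_identical(rnorm(1), x1)
})

test_that("recessive SNPs shift hazard only in effect homozygotes", {
  snps <- snpSpec("rs1", maf = 0.4, beta = 0.8, mode = "recessive")
  g <- simulateGenotypes(40000, snps, seed = 21)
  ls <- simulateLifespans(g, snps, rho = 0, censorRange = c(119.9, 120),
                          seed = 22)
  byGeno <- tapply(ls$father$age, g$father[, 1], median)
  expect_lt(abs(byGeno["1"] - byGeno["0"]), 0.5)  # het = ref
  expect_gt(byGeno["2"] - byGeno["0"], 2)         # homozygotes live longer
})

test_that("risk-factor summary statistics embed the causal structure", {
  snps <- nullSnps(500)
  causal <- c(0.5, -0.3, 0.2)
  rf <- simulateRiskFactorStats(snps, causal, noiseSe = 0.05, seed = 23)
  B <- sapply(rf$factorTables, `[[`, "beta")
  fit <- lm(rf$trueBeta ~ B - 1)
  est <- coef(summary(fit))
  expect_true(all(abs(est[, 1] - causal) < 2 * est[, 2]))
  expect_error(simulateRiskFactorStats(snps, causal, noiseSe = -1,
                                       seed = 1), "noiseSe")
  # all-zero causal effects give a null prior construction
  rf0 <- simulateRiskFactorStats(snps, c(0, 0, 0), noiseSe = 0,
                                 seed = 24)
  expect_true(all(rf0$trueBeta == 0))
})

test_that("cohort tables round-trip through the TSV writer", {
  coh <- simulateCohort(50, nullSnps(2), seed = 25)
  tf <- tempfile(fileext = ".tsv"); mf <- tempfile(fileext = ".tsv")
  writeCohortTable(coh, tf)
  writeSnpManifest(coh, mf)
  back <- readCohortTable(tf, mf, cohortId = cohortId(coh))
  expect_equal(unname(dosages(back)), unname(dosages(coh)))
  expect_equal(parentRecords(back, "mother")$age,
               parentRecords(coh, "mother")$age)
  expect_equal(covariates(back), covariates(coh))
})

test_that("cohort validity rejects malformed records", {
  coh <- simulateCohort(30, nullSnps(1), seed = 26)
  expect_error(LifespanCohort(
    dosage = matrix(3, 1, 2), snps = nullSnps(1),
    father = data.frame(age = c(80, 80), dead = FALSE),
    mother = data.frame(age = c(80, 80), dead = FALSE)), "0, 2")
  expect_error(LifespanCohort(
    dosage = matrix(1, 1, 2), snps = nullSnps(1),
    father = data.frame(age = c(39, 80), dead = c(TRUE, FALSE)),
    mother = data.frame(age = c(80, 80), dead = FALSE)), "40")
  expect_error(simulateLifespans(list(), nullSnps(1), rho = 0.9,
                                 seed = 1), "rho")
  expect_error(gompertzParams(a = 0.5, b = 0.1, entryAge = 40),
               "degenerate")
})
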