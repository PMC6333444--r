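mkSumstats <- function(m, seed = 81) {
  withr::with_seed(seed, {
    data.frame(snpid = sprintf("rs%04d", 1:m), chrom = "1",
               pos = seq(1e6, by = 6e5, length.out = m), a1 = "A",
               a0 = "G", beta1 = rnorm(m, 0, 0.05), p = runif(m))
  })
}

test_that("score models threshold, clump and refuse empty weight lists", {
  ss <- mkSumstats(20)
  full <- buildPRS(ss, trainingCohorts = "train")
  tight <- buildPRS(ss, pThreshold = 0.2, trainingCohorts = "train")
  # nested thresholds give nested SNP sets
  expect_true(all(tight@weights$snpid %in% full@weights$snpid))
  # 600 kb spacing beats the default 250 kb clump window: all kept
  expect_equal(nrow(full@weights), 20)
  expect_error(buildPRS(ss, pThreshold = 0), "empty")
})

test_that("training cohorts cannot be scored (leakage guard)", {
  coh <- simulateCohort(300, nullSnps(5), cohortId = "ukb-train",
                        seed = 82)
  ss <- data.frame(snpid = snpInfo(coh)$id, chrom = "1",
                   pos = seq(1e6, by = 6e5, length.out = 5), a1 = "A",
                   a0 = "G", beta1 = 0.1, p = 0.01)
  model <- buildPRS(ss, trainingCohorts = "ukb-train")
  expect_error(scorePRS(model, coh), "refusing")
  test <- simulateCohort(300, nullSnps(5), cohortId = "estonia",
                         seed = 83)
  expect_silent(scorePRS(model, test))
})

test_that("scores are standardised and alleles aligned", {
  coh <- simulateCohort(500, nullSnps(3), cohortId = "test", seed = 84)
  ss <- data.frame(snpid = snpInfo(coh)$id, chrom = "1",
                   pos = c(1e6, 2e6, 3e6), a1 = c("A", "G", "A"),
                   a0 = c("G", "A", "G"), beta1 = c(0.1, -0.2, 0.05),
                   p = 0.5)
  sc <- scorePRS(buildPRS(ss, clumpKb = 100), coh)
  expect_equal(mean(sc), 0, tolerance = 1e-12)
  expect_equal(sd(sc), 1, tolerance = 1e-12)
  # flipping the coded allele leaves the standardised score identical
  ssFlip <- transform(ss, a1 = a0, a0 = a1, beta1 = -beta1)
  scF <- scorePRS(buildPRS(ssFlip, clumpKb = 100), coh)
  expect_equal(sc, scF, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("oracle-weight scores recover the construction effect", {
  snps <- snpSpec(sprintf("rs%02d", 1:20), maf = 0.3,
                  beta = seq(0.02, 0.1, length.out = 20))
  coh <- simulateCohort(8000, snps, rho = 0, cohortId = "test",
                        seed = 85)
  ss <- data.frame(snpid = snps$id, chrom = snps$chrom, pos = snps$pos,
                   a1 = snps$a1, a0 = snps$a0, beta1 = snps$beta,
                   p = 1e-9)
  model <- buildPRS(ss, clumpKb = 100)
  res <- scoreAndAssociate(model, coh)
  # true per-SD carrier effect: sd of the raw genetic score
  d <- t(dosages(coh))
  trueSd <- sd(drop(d %*% snps$beta))
  for (p in c("father", "mother")) {
    row <- res$association[res$association$parent == p, ]
    expect_lt(abs(row$beta - trueSd), 1.96 * row$se)
    expect_equal(row$years, 10 * row$beta)
  }
  # a random score shows no association
  rnd <- withr::with_seed(86, rnorm(ncol(coh)))
  rec <- parentRecords(coh, "father")
  null <- associateSurvival(rnd, rec$age, rec$dead, covariates(coh),
                            "parent")
  expect_lt(abs(null$beta), 1.96 * null$se * 2.6)
})

test_that("parent-doubled and self associations agree internally", {
  snps <- snpSpec(sprintf("rs%02d", 1:10), maf = 0.3, beta = 0.08)
  coh <- simulateCohort(8000, snps, rho = 0, cohortId = "test",
                        seed = 87)
  ss <- data.frame(snpid = snps$id, chrom = snps$chrom, pos = snps$pos,
                   a1 = snps$a1, a0 = snps$a0, beta1 = snps$beta, p = 1e-9)
  sc <- scorePRS(buildPRS(ss, clumpKb = 100), coh)
  rec <- parentRecords(coh, "father")
  parent <- associateSurvival(sc, rec$age, rec$dead, kin = "parent")
  # the father's own genotype score is the "self" phenotype oracle
  gF <- t(SummarizedExperiment::assay(coh, "fatherGeno"))
  scSelf <- drop(scale(gF %*% snps$beta))
  self <- associateSurvival(scSelf, rec$age, rec$dead, kin = "self")
  # per-SD effects differ by the score-sd ratio; compare on years/allele
  ratio <- sd(drop(gF %*% snps$beta)) /
    sd(drop(t(dosages(coh)) %*% snps$beta))
  expect_lt(abs(parent$beta * ratio - self$beta),
            1.96 * sqrt((parent$se * ratio)^2 + self$se^2))
})

test_that("decile contrasts are zero under exchangeability, exact on fixtures", {
  withr::with_seed(88, {
    rec <- data.frame(age = sample(c(60, 70, 80, 90), 400, TRUE),
                      dead = TRUE)
    sc <- rnorm(400)
    dc <- decileContrast(sc, rec, doubled = FALSE)
    expect_lt(abs(dc$contrast), 15)  # medians move in 10-year steps
    # identical survival in all deciles: contrast exactly zero
    recC <- data.frame(age = rep(75, 400), dead = TRUE)
    dc0 <- decileContrast(sc, recC, doubled = TRUE)
    expect_equal(dc0$contrast, 0)
    expect_equal(dc0$contrastDoubled, 0)
  })
  # brute-force KM median by step-function inversion on a small fixture
  sc <- seq_len(40) / 40
  rec <- data.frame(age = c(rep(60, 4), rep(c(65, 75), 16),
                            rep(90, 4)), dead = TRUE)
  rec$age[37:40] <- 90; rec$age[1:4] <- 60
  dc <- decileContrast(sc, rec, doubled = FALSE)
  expect_equal(dc$medianBottom, 60)
  expect_equal(dc$medianTop, 90)
  expect_equal(dc$contrast, 30)
  # ties in the score are broken deterministically
  tied <- rep(1:10, each = 4)
  d1 <- decileContrast(tied, rec, doubled = FALSE)
  d2 <- decileContrast(tied, rec, doubled = FALSE)
  expect_identical(d1, d2)
})

test_that("unreached KM medians are reported as flagged lower bounds", {
  rec <- data.frame(age = rep(85, 40), dead = FALSE)
  dc <- decileContrast(seq_len(40), rec, doubled = FALSE)
  expect_true(dc$lowerBound)
  expect_equal(dc$medianTop, 85)
})

test_that("disease associations protect, double and meta-analyse", {
  withr::with_seed(89, {
    n <- 3000
    sc <- rnorm(n)
    liability <- -0.4 * sc + rnorm(n)
    disease <- cbind(cvd = as.integer(liability > 0.8),
                     diabetes = as.integer(rnorm(n) > 1))
    scores <- list(parent = sc, self = sc)
    diseases <- list(parent = disease, self = disease)
    res <- diseaseAssociations(scores, diseases,
                               firstDegree = c(parent = TRUE,
                                               self = FALSE))
    cvd <- res$meta[res$meta$disease == "cvd", ]
    expect_gt(cvd$beta, 0)  # protective score
    expect_lt(cvd$p, 0.05)
    null <- res$meta[res$meta$disease == "diabetes", ]
    expect_gt(null$p, 0.001)
    # parent rows are doubled relative to self
    pk <- res$perKin
    expect_gt(abs(pk$beta[pk$kin == "parent" & pk$disease == "cvd"]),
              abs(pk$beta[pk$kin == "self" & pk$disease == "cvd"]))
    # zero kin correlation leaves the meta SE unadjusted
    r0 <- diseaseAssociations(scores, diseases,
                              firstDegree = c(parent = TRUE,
                                              self = FALSE),
                              kinCor = c(self = 0))
    expect_equal(r0$meta$se, res$meta$se)
    rAdj <- diseaseAssociations(scores, diseases,
                                firstDegree = c(parent = TRUE,
                                                self = FALSE),
                                kinCor = c(self = 0.1))
    expect_equal(rAdj$meta$se, res$meta$se * sqrt(1.1))
    rLin <- diseaseAssociations(scores, diseases,
                                firstDegree = c(parent = TRUE,
                                                self = FALSE),
                                kinCor = c(self = 0.1),
                                seAdjust = "linear")
    expect_equal(rLin$meta$se, res$meta$se * 1.1)
  })
})
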