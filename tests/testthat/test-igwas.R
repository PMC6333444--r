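test_that("multivariate MR recovers constructed causal effects", {
  # one factor, no noise: exact regression
  b <- seq(-1, 1, length.out = 20)
  fit <- suppressWarnings(
    fitMultivariateMR(0.7 * b, cbind(f1 = b), stepwise = FALSE))
  expect_equal(fit$estimates$estimate, 0.7, tolerance = 1e-12)
  # three factors with noise: recovery within 2 SE each
  snps <- nullSnps(500)
  causal <- c(0.5, -0.3, 0.2)
  rf <- simulateRiskFactorStats(snps, causal, noiseSe = 0.05,
                                lifespanNoiseSd = 0.2, seed = 51)
  B <- sapply(rf$factorTables, `[[`, "beta")
  est <- fitMultivariateMR(rf$trueBeta, B, stepwise = FALSE)$estimates
  expect_true(all(abs(est$estimate - causal) < 2 * est$se))
})

test_that("stepwise AIC drops a null factor at the AIC-implied rate", {
  # AIC retains a superfluous 1-df term with asymptotic probability
  # P(chi2_1 > 2) ~ 0.157, so the expected exclusion rate is ~84%;
  # true factors must always be retained
  excluded <- 0L
  for (i in 1:100) {
    snps <- nullSnps(400)
    rf <- simulateRiskFactorStats(snps, c(0.6, -0.4), noiseSe = 0.02,
                                  lifespanNoiseSd = 1, seed = 500 + i)
    B <- cbind(sapply(rf$factorTables, `[[`, "beta"),
               nullfac = withr::with_seed(900 + i, rnorm(400)))
    sel <- fitMultivariateMR(rf$trueBeta, B)$estimates
    expect_true(all(sel$selected[sel$factor != "nullfac"]))
    if (!sel$selected[sel$factor == "nullfac"]) excluded <- excluded + 1L
  }
  expect_gte(excluded, 70L)
})

test_that("rank-deficient factor matrices are refused with names", {
  b <- rnorm(30)
  expect_error(fitMultivariateMR(b, cbind(f1 = b, f2 = 2 * b)),
               "collinear")
})

test_that("prior construction propagates uncertainty and adds the unit", {
  tabs <- list(f1 = data.frame(snpid = "s1", beta = 2, se = 0.2))
  causal <- data.frame(factor = "f1", estimate = 0.5, se = 0.1)
  pr <- buildPriors(causal, tabs)
  expect_equal(pr$mu, 1)
  expect_equal(pr$sigma2, 1 + (0.5 * 0.2)^2 + (2 * 0.1)^2)  # 1.05
  # noiseless single factor: mu exact, variance collapses to the unit
  pr0 <- buildPriors(data.frame(factor = "f1", estimate = 0.5, se = 0),
                     list(f1 = data.frame(snpid = "s1", beta = 2,
                                          se = 0)))
  expect_equal(pr0$mu, 1)
  expect_equal(pr0$sigma2, 1)
  # null causal effects: null prior
  prN <- buildPriors(data.frame(factor = "f1", estimate = 0, se = 0),
                     tabs["f1"])
  expect_equal(prN$mu, 0)
  # missing SNP contributes zero and is flagged
  prM <- buildPriors(causal, tabs, snpids = c("s1", "s2"))
  expect_equal(prM$mu[2], 0)
  expect_true(prM$flagged[2])
  expect_false(prM$flagged[1])
})

test_that("log Bayes factors match the normal-normal closed forms", {
  expect_equal(bayesFactor(c(-2, 0, 3), mu = 0, sigma2 = 1), c(0, 0, 0))
  expect_equal(bayesFactor(3, mu = 3, sigma2 = 1), 4.5)
  expect_equal(bayesFactor(0, mu = 5, sigma2 = 1), -12.5)
  expect_error(bayesFactor(1, mu = 0, sigma2 = 0.5), "sigma2")
})

test_that("permutation p-values are valid under an exchangeable null", {
  withr::with_seed(52, {
    m <- 1000
    z <- rnorm(m)
    priors <- data.frame(snpid = sprintf("s%04d", 1:m),
                         mu = rnorm(m, 0, 2), sigma2 = 1 + rexp(m))
    perm <- permutationPvalues(z, priors, nPermutations = 200, seed = 53)
    ks <- suppressWarnings(ks.test(perm$empiricalP, "punif"))
    expect_gt(ks$p.value, 0.01)
    # p is floored at 1/(1 + N_null) and the floor is flagged
    floorP <- 1 / (1 + m * 200)
    expect_true(all(perm$empiricalP >= floorP))
    expect_identical(perm$atFloor, perm$empiricalP <= floorP)
    # BH q is monotone non-decreasing in p
    o <- order(perm$empiricalP)
    expect_true(all(diff(perm$q[o]) >= -1e-12))
  })
  expect_error(permutationPvalues(rnorm(5),
                                  data.frame(snpid = letters[1:5],
                                             mu = 0, sigma2 = 1),
                                  nPermutations = 0, seed = 1),
               "nPermutations")
})

test_that("permutation p is invariant to monotone transforms of the BF", {
  # ranks alone determine the empirical p: recomputing the counts from a
  # monotone transform of the same null pool reproduces them exactly
  withr::with_seed(54, {
    m <- 200
    z <- rnorm(m)
    priors <- data.frame(snpid = sprintf("s%03d", 1:m), mu = rnorm(m),
                         sigma2 = 1 + rexp(m))
    perm <- permutationPvalues(z, priors, nPermutations = 50, seed = 55)
    obs <- bayesFactor(z, priors$mu, priors$sigma2)
    nulls <- withr::with_seed(55, {
      unlist(lapply(1:50, function(b)
        bayesFactor(z[sample.int(m)], priors$mu, priors$sigma2)))
    })
    mono <- function(x) tanh(x / 10)  # strictly increasing
    pT <- vapply(mono(obs), function(o)
      (1 + sum(mono(nulls) >= o)) / (1 + length(nulls)), numeric(1))
    expect_equal(perm$empiricalP, pT)
  })
})

test_that("the iGWAS wrapper produces the published table shape", {
  withr::with_seed(56, {
    snps <- nullSnps(300)
    rf <- simulateRiskFactorStats(snps, c(1, -0.5), noiseSe = 0.05,
                                  seed = 57)
    z <- rf$trueBeta + rnorm(300)
    lifespan <- data.frame(snpid = snps$id, beta1 = z, se = 1)
    causal <- data.frame(factor = names(rf$factorTables),
                         estimate = c(1, -0.5), se = c(0.02, 0.02))
    res <- igwas(lifespan, rf$factorTables, causal,
                 nPermutations = 50, seed = 58)
    expect_named(res, c("snpid", "beta", "se", "p", "prior_mean",
                        "prior_se", "logBF", "p_bf", "q", "atFloor"))
    expect_true(all(res$q >= res$p_bf - 1e-12))
  })
})
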