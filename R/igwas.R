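#' Multivariate Mendelian-randomisation causal estimates for the prior
#'
#' Weighted multivariate regression (through the origin) of lifespan SNP
#' effects on the matrix of SNP effects on candidate risk factors, over
#' instruments not on the masked chromosome. The fitted coefficients are
#' the causal effects of each standardised factor on standardised
#' lifespan; factor selection uses AIC-based stepwise search, mirroring
#' how risk factors are chosen before prior construction.
#'
#' @param lifespanBeta per-instrument lifespan effect (Z or beta scale,
#'   consistent with \code{factorBeta}).
#' @param factorBeta numeric matrix, instruments x factors, of SNP effects
#'   on each risk factor; column names identify the factors.
#' @param lifespanSe optional per-instrument SEs; weights are 1/se^2.
#' @param chrom optional per-instrument chromosome labels.
#' @param maskChrom chromosome to mask (instruments dropped), or NULL.
#' @param stepwise run AIC stepwise selection (default TRUE).
#' @return list: \code{estimates} (data.frame factor, estimate, se, p,
#'   selected) and \code{fit} (the final \code{lm}).
#' @export
fitMultivariateMR <- function(lifespanBeta, factorBeta,
                              lifespanSe = NULL, chrom = NULL,
                              maskChrom = NULL, stepwise = TRUE) {
  factorBeta <- as.matrix(factorBeta)
  if (is.null(colnames(factorBeta)))
    colnames(factorBeta) <- paste0("factor", seq_len(ncol(factorBeta)))
  keep <- rep(TRUE, length(lifespanBeta))
  if (!is.null(maskChrom) && !is.null(chrom))
    keep <- !(chrom %in% maskChrom)
  y <- lifespanBeta[keep]
  B <- factorBeta[keep, , drop = FALSE]
  if (nrow(B) < ncol(B) + 1)
    stop("need at least factors + 1 instruments")
  if (qr(B)$rank < ncol(B)) {
    qrB <- qr(B)
    bad <- colnames(B)[qrB$pivot[seq(qrB$rank + 1, ncol(B))]]
    stop("rank-deficient factor matrix; collinear factors: ",
         paste(bad, collapse = ", "))
  }
  w <- if (is.null(lifespanSe)) NULL else 1 / lifespanSe[keep]^2
  dat <- data.frame(y = y, B, check.names = TRUE)
  colnames(dat)[-1] <- make.names(colnames(B))
  full <- lm(y ~ . - 1, data = dat, weights = w)
  fit <- if (stepwise && ncol(B) > 1)
    step(full, direction = "both", trace = 0,
         scope = list(lower = y ~ -1)) else full
  co <- summary(fit)$coefficients
  nm <- make.names(colnames(B))
  sel <- nm %in% rownames(co)
  est <- data.frame(factor = colnames(B),
                    estimate = ifelse(sel, co[nm[sel], 1][match(nm, nm[sel])], 0),
                    se = ifelse(sel, co[nm[sel], 2][match(nm, nm[sel])], NA),
                    p = ifelse(sel, co[nm[sel], 4][match(nm, nm[sel])], NA),
                    selected = sel, stringsAsFactors = FALSE)
  list(estimates = est, fit = fit)
}

#' Assemble per-SNP Bayesian priors from risk-factor effects
#'
#' The prior mean for a SNP's standardised lifespan effect is the sum over
#' selected risk factors of (causal effect of factor on lifespan) x
#' (effect of the SNP on that factor). The prior variance is the
#' first-order error propagation of that product sum, plus one: the added
#' unit accounts for priors being built from observed Z-scores, which
#' carry unit sampling noise around the true Z (Zobs ~ N(Ztrue, 1)).
#' A SNP missing from a factor table contributes zero to the mean for
#' that factor, its variance term is dropped, and the SNP is flagged.
#'
#' @param causal data.frame with columns \code{factor}, \code{estimate},
#'   \code{se} (and optionally \code{selected}), as from
#'   [fitMultivariateMR()].
#' @param factorTables named list of summary-statistics data.frames
#'   (\code{snpid}, \code{beta}, \code{se}), one per factor, on the same
#'   standardised scale as the causal estimates.
#' @param snpids SNPs to build priors for (default: union of tables).
#' @return data.frame: \code{snpid}, \code{mu} (prior mean), \code{sigma2}
#'   (prior variance including the added unit), \code{flagged}.
#' @export
buildPriors <- function(causal, factorTables, snpids = NULL) {
  if (!is.null(causal$selected))
    causal <- causal[causal$selected, , drop = FALSE]
  stopifnot(all(causal$factor %in% names(factorTables)))
  if (is.null(snpids))
    snpids <- unique(unlist(lapply(factorTables, `[[`, "snpid")))
  mu <- numeric(length(snpids))
  v <- numeric(length(snpids))
  flagged <- logical(length(snpids))
  for (i in seq_len(nrow(causal))) {
    tab <- factorTables[[causal$factor[i]]]
    idx <- match(snpids, tab$snpid)
    miss <- is.na(idx)
    flagged <- flagged | miss
    b <- ifelse(miss, 0, tab$beta[idx])
    sb <- ifelse(miss, 0, tab$se[idx])
    th <- causal$estimate[i]
    sth <- if (is.na(causal$se[i])) 0 else causal$se[i]
    mu <- mu + th * b
    v <- v + ifelse(miss, 0, (th * sb)^2 + (b * sth)^2)
  }
  data.frame(snpid = snpids, mu = mu, sigma2 = v + 1, flagged = flagged,
             stringsAsFactors = FALSE)
}

#' Normal-normal log Bayes factors for prior-informed association
#'
#' Compares the marginal likelihood of an observed association Z statistic
#' under the risk-factor-informed prior, N(mu, sigma2), with the null
#' N(0, 1): logBF = log N(z; mu, sigma2) - log N(z; 0, 1). \code{sigma2}
#' is the full prior variance from [buildPriors()], which already includes
#' the unit observation noise, so a null prior (mu = 0, sigma2 = 1) gives
#' logBF = 0 for every z, and a mismatched confident prior actively
#' penalises.
#'
#' @param z observed association Z statistic(s).
#' @param mu prior mean(s).
#' @param sigma2 full prior variance(s), >= 1.
#' @return log Bayes factor(s).
#' @examples
#' bayesFactor(3, mu = 3, sigma2 = 1)  # 4.5
#' bayesFactor(0, mu = 5, sigma2 = 1)  # -12.5
#' @export
bayesFactor <- function(z, mu = 0, sigma2 = 1) {
  if (any(!is.finite(z)) || any(!is.finite(mu)) || any(!is.finite(sigma2)))
    stop("inputs must be finite")
  if (any(sigma2 < 1))
    stop("sigma2 must be >= 1 (it includes the unit observation noise)")
  dnorm(z, mu, sqrt(sigma2), log = TRUE) - dnorm(z, 0, 1, log = TRUE)
}

#' Permutation p-values and BH correction for Bayes factors
#'
#' The null distribution of the log Bayes factor is generated by
#' permuting the observed Z statistics across SNPs (breaking the Z-prior
#' pairing) while keeping the priors fixed, recomputing Bayes factors for
#' each permutation, and pooling all null values. The empirical p-value
#' for each SNP is (1 + number of null logBF >= observed) /
#' (1 + total null count); it is floored at 1/(1 + N_null), and SNPs at
#' the floor are flagged since their significance is limited by the
#' number of permutations. Benjamini-Hochberg q-values are computed across
#' SNPs.
#'
#' @param z observed Z statistics (one per SNP).
#' @param priors data.frame from [buildPriors()] aligned to \code{z}.
#' @param nPermutations number of permutations (>= 1).
#' @param seed integer seed.
#' @return data.frame: \code{snpid}, \code{logBF}, \code{empiricalP},
#'   \code{q}, \code{atFloor}.
#' @export
permutationPvalues <- function(z, priors, nPermutations = 1000, seed) {
  if (nPermutations < 1) stop("nPermutations must be >= 1")
  m <- length(z)
  stopifnot(nrow(priors) == m)
  obs <- bayesFactor(z, priors$mu, priors$sigma2)
  nulls <- withSeed(seed, {
    out <- numeric(m * nPermutations)
    for (b in seq_len(nPermutations)) {
      zp <- z[sample.int(m)]
      out[((b - 1) * m + 1):(b * m)] <-
        bayesFactor(zp, priors$mu, priors$sigma2)
    }
    out
  })
  sortedNulls <- sort(nulls)
  nNull <- length(sortedNulls)
  # count of nulls >= obs via position in the sorted null vector
  nGreater <- nNull - findInterval(obs, sortedNulls,
                                   left.open = TRUE)
  p <- (1 + nGreater) / (1 + nNull)
  data.frame(snpid = priors$snpid, logBF = obs, empiricalP = p,
             q = p.adjust(p, method = "BH"),
             atFloor = p <= 1 / (1 + nNull), stringsAsFactors = FALSE)
}

#' Risk-factor-informed GWAS (iGWAS) pipeline
#'
#' End-to-end prior-informed scan: builds per-SNP priors from risk-factor
#' summary statistics weighted by multivariate MR causal estimates,
#' computes normal-normal Bayes factors against the observed lifespan Z
#' statistics, and assigns permutation p-values with BH correction.
#'
#' @param lifespan summary-statistics data.frame (\code{snpid},
#'   \code{beta1}, \code{se}, optionally \code{p}).
#' @param factorTables named list of per-factor summary statistics
#'   (\code{snpid}, \code{beta}, \code{se}), on the Z scale.
#' @param causal causal-estimate data.frame (see [buildPriors()]).
#' @param nPermutations,seed passed to [permutationPvalues()].
#' @return data.frame shaped like the published per-SNP iGWAS table:
#'   \code{snpid, beta, se, p, prior_mean, prior_se, logBF, p_bf, q}.
#' @export
igwas <- function(lifespan, factorTables, causal, nPermutations = 1000,
                  seed) {
  z <- lifespan$beta1 / lifespan$se
  priors <- buildPriors(causal, factorTables, snpids = lifespan$snpid)
  priors <- priors[match(lifespan$snpid, priors$snpid), ]
  perm <- permutationPvalues(z, priors, nPermutations, seed)
  data.frame(snpid = lifespan$snpid, beta = lifespan$beta1,
             se = lifespan$se,
             p = if (!is.null(lifespan$p)) lifespan$p
                 else 2 * pnorm(-abs(z)),
             prior_mean = priors$mu, prior_se = sqrt(priors$sigma2),
             logBF = perm$logBF, p_bf = perm$empiricalP, q = perm$q,
             atFloor = perm$atFloor, stringsAsFactors = FALSE)
}
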