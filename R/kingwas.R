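#' Residualised Cox phenotype for kin-cohort GWAS
#'
#' Fits a covariates-only Cox proportional-hazards partial likelihood
#' (Breslow ties) to one parent's survival, extracts the Martingale
#' residuals (event indicator minus fitted cumulative hazard at exit) and
#' divides them by the proportion dead. The resulting trait is suitable
#' for linear GWAS: the slope of a regression of this trait on genotype
#' estimates the log hazard ratio per allele, which is negated downstream
#' to the log protection ratio (lnPR) scale, on which positive values
#' extend life. Because offspring dosage carries half the effect in the
#' parent, downstream per-parent effect estimates (and SEs) are doubled to
#' the carrier scale.
#'
#' @param age age at death or censoring (years).
#' @param dead logical event indicator.
#' @param covariates numeric matrix (may be NULL for a null model).
#' @param parentSex label stored with the result.
#' @param x a [LifespanCohort-class] (for the method).
#' @param parent \code{"father"} or \code{"mother"}.
#' @param ... passed through to \code{fitResidualPhenotype}.
#' @return A \code{ResidualPhenotype} object: slots \code{residuals}
#'   (scaled residual per subject), \code{propDead}, \code{variance}
#'   (sample variance of the scaled trait), \code{parentSex},
#'   \code{nDeaths}.
#' @examples
#' coh <- simulateCohort(300, snpSpec("rs1", 0.3), seed = 3)
#' rp <- residualPhenotype(coh, "father")
#' rp@propDead
#' @export
fitResidualPhenotype <- function(age, dead, covariates = NULL,
                                 parentSex = NA_character_) {
  dead <- as.logical(dead)
  nd <- sum(dead)
  if (nd < 2) stop("need at least 2 deaths to fit the Cox model")
  propDead <- mean(dead)
  if (is.null(covariates) || NCOL(covariates) == 0) {
    fit <- coxph(Surv(age, dead) ~ 1)
  } else {
    covariates <- as.matrix(covariates)
    if (qr(cbind(1, covariates))$rank < ncol(covariates) + 1L)
      stop("covariate matrix is rank deficient")
    fit <- coxph(Surv(age, dead) ~ covariates, ties = "breslow",
                 control = survival::coxph.control(eps = 1e-9,
                                                   iter.max = 50))
    if (!is.null(fit$info) && grepl("did not converge", fit$info %||% ""))
      stop("Cox fit did not converge: ", fit$info)
  }
  res <- residuals(fit, type = "martingale") / propDead
  new("ResidualPhenotype", residuals = as.numeric(res),
      propDead = propDead, variance = var(as.numeric(res)),
      parentSex = parentSex, nDeaths = as.integer(nd))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname fitResidualPhenotype
#' @export
setClass("ResidualPhenotype",
         representation(residuals = "numeric", propDead = "numeric",
                        variance = "numeric", parentSex = "character",
                        nDeaths = "integer"))

setValidity("ResidualPhenotype", function(object) {
  if (object@propDead <= 0 || object@propDead > 1)
    return("propDead must lie in (0, 1]")
  TRUE
})

setMethod("show", "ResidualPhenotype", function(object) {
  cat("ResidualPhenotype (", object@parentSex, "): ",
      length(object@residuals), " subjects, ", object@nDeaths,
      " deaths (prop dead ", sprintf("%.3f", object@propDead),
      "), variance ", sprintf("%.3f", object@variance), "\n", sep = "")
})

#' @rdname fitResidualPhenotype
#' @export
setMethod("residualPhenotype", "LifespanCohort", function(x, parent, ...) {
  rec <- parentRecords(x, parent)
  fitResidualPhenotype(rec$age, rec$dead, covariates = covariates(x),
                       parentSex = match.arg(parent,
                                             c("father", "mother")), ...)
})

# residualise y and every dosage column on [1 | covs], then per-SNP OLS.
# returns slope, se, df on the raw (offspring, lnHR-signed) scale.
fastOLS <- function(y, dosage, covariates = NULL) {
  n <- length(y)
  X0 <- if (is.null(covariates) || NCOL(covariates) == 0)
    matrix(1, n, 1) else cbind(1, as.matrix(covariates))
  qrX <- qr(X0)
  yr <- qr.resid(qrX, y)
  xr <- qr.resid(qrX, dosage)
  sxx <- colSums(xr^2)
  sxy <- colSums(xr * yr)
  syy <- sum(yr^2)
  df <- n - ncol(X0) - 1L
  slope <- sxy / sxx
  rss <- pmax(syy - slope^2 * sxx, 0)
  se <- sqrt(rss / df / sxx)
  bad <- sxx < .Machine$double.eps * n
  slope[bad] <- NA_real_; se[bad] <- NA_real_
  list(slope = slope, se = se, df = df, monomorphic = bad)
}

assocRecord <- function(snps, beta, se, freq1, nLives, nDeaths) {
  z <- beta / se
  data.frame(snpid = snps$id, a1 = snps$a1, a0 = snps$a0,
             freq1 = freq1, beta = beta, se = se, z = z,
             p = 2 * pnorm(-abs(z)), n_lives = nLives,
             n_deaths = nDeaths, stringsAsFactors = FALSE)
}

meanImpute <- function(d) {
  if (!anyNA(d)) return(d)
  mu <- colMeans(d, na.rm = TRUE)
  idx <- which(is.na(d), arr.ind = TRUE)
  d[idx] <- mu[idx[, 2]]
  d
}

#' Single-parent kin-cohort association scan
#'
#' Per SNP, ordinary least squares of the scaled Martingale-residual trait
#' on offspring dosage plus the Cox covariates. The slope estimates half
#' the parental log hazard ratio, so effect sizes and standard errors are
#' doubled, and the sign is flipped to the log protection ratio (lnPR)
#' scale. Missing dosages are mean-imputed per SNP; monomorphic SNPs yield
#' NA statistics with a warning.
#'
#' @param cohort a [LifespanCohort-class].
#' @param parent \code{"father"} or \code{"mother"}.
#' @param phenotype optional precomputed \code{ResidualPhenotype}.
#' @param mafFilter minimum effect-allele frequency (SNPs below are
#'   dropped); default 0.005.
#' @return data.frame of association records: \code{snpid, a1, a0, freq1,
#'   beta, se, z, p, n_lives, n_deaths}, with \code{beta} the carrier-scale
#'   lnPR per allele.
#' @examples
#' coh <- simulateCohort(400, snpSpec("rs1", 0.3, 0.2), seed = 11)
#' gwasSingleParent(coh, "father")
#' @export
gwasSingleParent <- function(cohort, parent, phenotype = NULL,
                             mafFilter = 0.005) {
  if (is.null(phenotype))
    phenotype <- residualPhenotype(cohort, parent)
  snps <- snpInfo(cohort)
  d <- meanImpute(t(dosages(cohort)))
  freq1 <- colMeans(d) / 2
  keep <- pmin(freq1, 1 - freq1) >= mafFilter | snps$beta != 0
  keep[is.na(keep)] <- TRUE
  fit <- fastOLS(phenotype@residuals, d, covariates(cohort))
  if (any(fit$monomorphic))
    warning(sum(fit$monomorphic), " monomorphic SNP(s) returned NA")
  rec <- assocRecord(snps, beta = -2 * fit$slope, se = 2 * fit$se,
                     freq1 = freq1, nLives = nrow(d),
                     nDeaths = phenotype@nDeaths)
  rec[keep, , drop = FALSE]
}

#' Combined-parent association under common effect sizes (CES)
#'
#' Regresses the total parent residual (father + mother scaled Martingale
#' residuals) on offspring dosage plus covariates. Under a common effect
#' in both parents, the combined trait's slope is already the carrier-scale
#' effect (twice the single-parent slope), so no further doubling is
#' applied, and its standard error automatically reflects the covariance
#' between the parents' traits. The sign is flipped to lnPR.
#'
#' @inheritParams gwasSingleParent
#' @param phenotypeFather,phenotypeMother optional precomputed
#'   \code{ResidualPhenotype} objects.
#' @return data.frame of association records as in [gwasSingleParent()];
#'   \code{n_lives} counts both parents.
#' @export
combineCES <- function(cohort, phenotypeFather = NULL,
                       phenotypeMother = NULL, mafFilter = 0.005) {
  if (is.null(phenotypeFather))
    phenotypeFather <- residualPhenotype(cohort, "father")
  if (is.null(phenotypeMother))
    phenotypeMother <- residualPhenotype(cohort, "mother")
  if (length(phenotypeFather@residuals) != length(phenotypeMother@residuals))
    stop("father and mother phenotypes cover different subject sets")
  y <- phenotypeFather@residuals + phenotypeMother@residuals
  snps <- snpInfo(cohort)
  d <- meanImpute(t(dosages(cohort)))
  freq1 <- colMeans(d) / 2
  keep <- pmin(freq1, 1 - freq1) >= mafFilter | snps$beta != 0
  fit <- fastOLS(y, d, covariates(cohort))
  if (any(fit$monomorphic))
    warning(sum(fit$monomorphic), " monomorphic SNP(s) returned NA")
  rec <- assocRecord(snps, beta = -fit$slope, se = fit$se, freq1 = freq1,
                     nLives = 2L * nrow(d),
                     nDeaths = phenotypeFather@nDeaths +
                       phenotypeMother@nDeaths)
  rec[keep, , drop = FALSE]
}

#' Sex-specific effects (SSE) test by bivariate MANOVA
#'
#' Combines father and mother association Z statistics into a 2-df Wald
#' statistic z' R^-1 z, where R is the 2x2 correlation matrix of the two
#' parent traits (off-diagonal \code{r}, the residual-trait correlation,
#' measured directly in the sample; ~0.1 for parental lifespans). Tests
#' the null that both parental effects are zero without assuming they are
#' equal; no single combined beta is produced.
#'
#' @param father,mother association record data.frames (same SNPs, same
#'   allele coding) as from [gwasSingleParent()].
#' @param r inter-trait correlation, in (-1, 1).
#' @return data.frame: \code{snpid, chisq, df, p}.
#' @export
combineSSE <- function(father, mother, r = 0.1) {
  if (!is.finite(r) || abs(r) >= 1) stop("r must lie in (-1, 1)")
  m <- merge(father[, c("snpid", "a1", "a0", "z")],
             mother[, c("snpid", "a1", "a0", "z")],
             by = "snpid", suffixes = c(".f", ".m"))
  if (!all(m$a1.f == m$a1.m & m$a0.f == m$a0.m))
    stop("allele coding differs between parents; harmonise first")
  chisq <- (m$z.f^2 + m$z.m^2 - 2 * r * m$z.f * m$z.m) / (1 - r^2)
  data.frame(snpid = m$snpid, chisq = chisq, df = 2,
             p = pchisq(chisq, df = 2, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Correlation-adjusted inverse-variance meta-analysis
#'
#' Inverse-variance-weighted combination of two or more estimates per SNP
#' whose errors are positively correlated (correlated parent traits on
#' overlapping samples). The pooled SE is inflated to SE0 * sqrt(1 + r),
#' where SE0 is the naive IVW standard error. For exactly two estimates
#' the exact variance Var0 * (1 + 2 r s1 s2 / (s1^2 + s2^2)) is also
#' returned; the sqrt(1 + r) inflation is always at least as large
#' (conservative), with equality when s1 = s2.
#'
#' @param beta matrix (SNPs x estimates) of effect sizes, or a vector for
#'   a single SNP.
#' @param se matching matrix/vector of standard errors (> 0).
#' @param r assumed correlation between the estimates' errors, in
#'   \[-1, 1\].
#' @return data.frame: \code{beta} (IVW pooled), \code{se} (adjusted),
#'   \code{se0} (naive), \code{z}, \code{p}, and for two estimates
#'   \code{seExact} per the exact two-estimate variance.
#' @examples
#' metaCesCorrelated(c(0.1, 0.14), c(0.02, 0.02), r = 0.1)
#' @export
metaCesCorrelated <- function(beta, se, r = 0.1) {
  if (!is.finite(r) || r < -1 || r > 1) stop("r must lie in [-1, 1]")
  if (is.null(dim(beta))) beta <- matrix(beta, nrow = 1)
  if (is.null(dim(se))) se <- matrix(se, nrow = 1)
  stopifnot(all(dim(beta) == dim(se)), ncol(beta) >= 2, all(se > 0))
  w <- 1 / se^2
  pooled <- rowSums(beta * w) / rowSums(w)
  var0 <- 1 / rowSums(w)
  se0 <- sqrt(var0)
  seAdj <- se0 * sqrt(1 + r)
  out <- data.frame(beta = pooled, se = seAdj, se0 = se0,
                    z = pooled / seAdj,
                    p = 2 * pnorm(-abs(pooled / seAdj)))
  if (ncol(beta) == 2) {
    s1 <- se[, 1]; s2 <- se[, 2]
    out$seExact <- se0 * sqrt(1 + 2 * r * s1 * s2 / (s1^2 + s2^2))
  }
  out
}
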