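#' Estimate sample-overlap correlation from null SNPs
#'
#' When two studies share subjects, their effect-size errors are
#' correlated. Among SNPs that are null in both studies (|Z| < 1), the
#' correlation of Z statistics estimates that error correlation, which
#' can then be fed to [metaOverlapAdjusted()].
#'
#' @param x,y summary-statistics data.frames with \code{snpid} and either
#'   \code{z} or \code{beta1}/\code{se}.
#' @param zMax null-set threshold on |Z| (default 1).
#' @param minShared minimum number of shared null SNPs (default 100).
#' @return Pearson correlation of null-SNP Z statistics (single number).
#' @export
estimateNullOverlap <- function(x, y, zMax = 1, minShared = 100) {
  zcol <- function(t) if (!is.null(t$z)) t$z else t$beta1 / t$se
  xz <- data.frame(snpid = x$snpid, z = zcol(x))
  yz <- data.frame(snpid = y$snpid, z = zcol(y))
  m <- merge(xz, yz, by = "snpid")
  m <- m[abs(m$z.x) < zMax & abs(m$z.y) < zMax, , drop = FALSE]
  if (nrow(m) < minShared)
    stop("only ", nrow(m), " shared null SNPs (need >= ", minShared, ")")
  cor(m$z.x, m$z.y)
}

#' Overlap-adjusted inverse-variance meta-analysis
#'
#' Fixed-effects IVW pooling of study estimates whose errors covary
#' because of shared subjects. The pooled variance is the naive IVW
#' variance plus 2 * sum_{n<m} w_n w_m Cov(beta_n, beta_m), with w the
#' normalised inverse-variance weights and Cov the between-study null-SNP
#' covariance of the estimates.
#'
#' @param beta vector of study effect estimates for one SNP.
#' @param se vector of their standard errors (> 0).
#' @param cov between-study covariance matrix of the estimates (diagonal
#'   ignored), or a single correlation applied to every pair, scaled by
#'   the corresponding SE products.
#' @param covIsCorrelation if TRUE (default when \code{cov} is scalar),
#'   treat \code{cov} entries as correlations and scale by se_n * se_m.
#' @return list: \code{beta} (pooled), \code{se} (adjusted), \code{se0}
#'   (naive), \code{z}, \code{p}.
#' @examples
#' metaOverlapAdjusted(c(0.1, 0.2), c(1, 1), cov = 0.01,
#'                     covIsCorrelation = FALSE)
#' @export
metaOverlapAdjusted <- function(beta, se, cov = 0,
                                covIsCorrelation = length(cov) == 1) {
  k <- length(beta)
  stopifnot(length(se) == k, all(se > 0), k >= 2)
  if (length(cov) == 1)
    cov <- matrix(cov, k, k)
  cov <- as.matrix(cov)
  if (!isSymmetric(unname(cov), tol = 1e-8))
    stop("covariance matrix must be symmetric")
  if (covIsCorrelation)
    cov <- cov * tcrossprod(se)
  w <- (1 / se^2) / sum(1 / se^2)
  var0 <- 1 / sum(1 / se^2)
  extra <- 0
  for (n in seq_len(k - 1))
    for (m in seq(n + 1, k))
      extra <- extra + w[n] * w[m] * cov[n, m]
  v <- var0 + 2 * extra
  pooled <- sum(w * beta)
  list(beta = pooled, se = sqrt(v), se0 = sqrt(var0),
       z = pooled / sqrt(v), p = 2 * pnorm(-abs(pooled / sqrt(v))))
}

#' Replication-to-discovery effect-size ratio (alpha)
#'
#' alpha = beta_rep / beta_disc compares a replication estimate with its
#' discovery estimate on a common scale; alpha = 1 means full replication,
#' 0 means no effect. The standard error comes from the first-order Taylor
#' (delta-method) expansion:
#' SE^2 = SE_rep^2 / beta_disc^2 + beta_rep^2 SE_disc^2 / beta_disc^4.
#' The one-sided p-value tests alpha = 0 against the alternative that the
#' replication effect shares the discovery sign (i.e. alpha > 0, since
#' alpha is sign-relative to discovery by construction).
#'
#' @param betaDisc,seDisc discovery effect and SE (betaDisc != 0).
#' @param betaRep,seRep replication effect and SE.
#' @param snpid optional identifier carried through.
#' @return data.frame: \code{snpid, alpha, se, oneSidedP}.
#' @examples
#' alphaRatio(0.2, 0.02, 0.1, 0.05)
#' @export
alphaRatio <- function(betaDisc, seDisc, betaRep, seRep,
                       snpid = NA_character_) {
  if (any(betaDisc == 0)) stop("betaDisc must be nonzero")
  alpha <- betaRep / betaDisc
  se <- sqrt(seRep^2 / betaDisc^2 + betaRep^2 * seDisc^2 / betaDisc^4)
  data.frame(snpid = snpid, alpha = alpha, se = se,
             oneSidedP = pnorm(-alpha / se), stringsAsFactors = FALSE)
}

#' Inverse-variance meta-analysis of per-SNP alpha ratios
#'
#' Pools alpha across SNPs as collective evidence that discovery loci
#' influence the replication trait; the pooled alpha is reported with a
#' Wald 95\% CI and a two-sided p-value for alpha = 0. High-leverage
#' anchor SNPs (e.g. the variant used to calibrate the scale conversion)
#' can be excluded by id.
#'
#' @param alphas data.frame from [alphaRatio()] (columns \code{snpid},
#'   \code{alpha}, \code{se}).
#' @param exclude character vector of snpids to drop before pooling.
#' @return list: \code{alpha}, \code{se}, \code{ciLow}, \code{ciHigh},
#'   \code{p}, \code{nSnps}.
#' @export
metaAlpha <- function(alphas, exclude = character()) {
  keep <- !(alphas$snpid %in% exclude)
  a <- alphas[keep & is.finite(alphas$alpha) & alphas$se > 0, ,
              drop = FALSE]
  if (nrow(a) == 0) stop("no alpha estimates left after exclusion")
  w <- 1 / a$se^2
  pooled <- sum(w * a$alpha) / sum(w)
  se <- sqrt(1 / sum(w))
  list(alpha = pooled, se = se,
       ciLow = pooled - qnorm(0.975) * se,
       ciHigh = pooled + qnorm(0.975) * se,
       p = 2 * pnorm(-abs(pooled / se)), nSnps = nrow(a))
}
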