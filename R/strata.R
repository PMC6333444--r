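#' Default age bands for stratified hazard estimation
#'
#' Decades of age from 40 to 90 and a wider terminal band 90-120.
#'
#' @return A two-column matrix of band limits (lo, hi) in years.
#' @export
defaultAgeBands <- function() {
  cbind(lo = c(40, 50, 60, 70, 80, 90),
        hi = c(50, 60, 70, 80, 90, 120))
}

#' Age-band and sex-stratified kin-cohort hazard ratios
#'
#' For each parent sex and age band, fits a Cox model to the
#' band-truncated data: parents who died before the band are excluded,
#' parents surviving beyond the band are censored alive at its end, and
#' events are deaths within the band. A parent dying at 65 therefore
#' contributes to the 40-50, 50-60 and 60-70 bands only. Band estimates
#' are doubled to the carrier scale and sign-flipped to lnPR, giving
#' independent per-period effect estimates suitable for moderator
#' meta-regression.
#'
#' @param cohort a [LifespanCohort-class].
#' @param bands two-column matrix of non-overlapping ordered (lo, hi)
#'   limits; default [defaultAgeBands()].
#' @param snpids SNPs to analyse (default all).
#' @return data.frame of stratum estimates: \code{snpid, parent, age_lo,
#'   age_hi, n, deaths, beta, se, z, p}; bands with no deaths are omitted
#'   with a warning.
#' @export
stratifySurvival <- function(cohort, bands = defaultAgeBands(),
                             snpids = NULL) {
  bands <- as.matrix(bands)
  stopifnot(ncol(bands) == 2, all(bands[, 1] < bands[, 2]))
  if (any(bands[-1, 1] < bands[-nrow(bands), 2] - 1e-9))
    stop("bands must be non-overlapping and ordered")
  snps <- snpInfo(cohort)
  if (is.null(snpids)) snpids <- snps$id
  d <- meanImpute(t(dosages(cohort)))
  covs <- covariates(cohort)
  out <- list()
  for (parent in c("father", "mother")) {
    rec <- parentRecords(cohort, parent)
    for (b in seq_len(nrow(bands))) {
      lo <- bands[b, 1]; hi <- bands[b, 2]
      inBand <- rec$age > lo & !(rec$dead & rec$age <= lo)
      exit <- pmin(rec$age[inBand], hi)
      event <- rec$dead[inBand] & rec$age[inBand] <= hi
      if (sum(event) == 0) {
        warning("no deaths for ", parent, " in band ", lo, "-", hi,
                "; stratum omitted")
        next
      }
      cv <- if (ncol(covs)) covs[inBand, , drop = FALSE] else NULL
      for (s in snpids) {
        x <- d[inBand, s]
        fit <- tryCatch(
          suppressWarnings(coxph(Surv(exit, event) ~ cbind(x, cv),
                                 ties = "breslow")),
          error = function(e) NULL)
        est <- if (is.null(fit)) NA_real_ else coef(fit)[1]
        se <- if (is.null(fit)) NA_real_ else sqrt(vcov(fit)[1, 1])
        out[[length(out) + 1L]] <- data.frame(
          snpid = s, parent = parent, age_lo = lo, age_hi = hi,
          n = sum(inBand), deaths = sum(event),
          beta = -2 * est, se = 2 * se, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  res$z <- res$beta / res$se
  res$p <- 2 * pnorm(-abs(res$z))
  rownames(res) <- NULL
  res
}

#' Fixed-effects moderator meta-regression of stratum estimates
#'
#' Weighted least squares of the stratum lnPR estimates on the band's
#' mean age (midpoint, years) and a male indicator, with weights equal to
#' the inverse of the known per-stratum variances. Because the variances
#' are known, coefficient standard errors come directly from
#' (X' W X)^(-1) without rescaling by the residual mean square — the
#' fixed-effects "known variance" meta-regression model. Wald p-values
#' are reported per moderator and BH q-values across the whole SNP x
#' moderator family.
#'
#' @param strata data.frame from [stratifySurvival()] (columns
#'   \code{snpid, parent, age_lo, age_hi, beta, se}).
#' @param moderators subset of \code{c("age", "sex")}.
#' @return data.frame, one row per SNP x moderator: \code{snpid,
#'   moderator, estimate, se, p, q}, plus \code{intercept} rows
#'   (q = NA for the intercept).
#' @export
moderatorRegression <- function(strata, moderators = c("age", "sex")) {
  moderators <- match.arg(moderators, c("age", "sex"), several.ok = TRUE)
  out <- list()
  for (s in unique(strata$snpid)) {
    d <- strata[strata$snpid == s, , drop = FALSE]
    X <- matrix(1, nrow(d), 1, dimnames = list(NULL, "intercept"))
    if ("age" %in% moderators)
      X <- cbind(X, age = (d$age_lo + d$age_hi) / 2)
    if ("sex" %in% moderators)
      X <- cbind(X, sex = as.numeric(d$parent == "father"))
    if (nrow(d) < ncol(X) || qr(X)$rank < ncol(X))
      stop("singular moderator design for SNP ", s)
    W <- 1 / d$se^2
    XtW <- t(X * W)
    V <- solve(XtW %*% X)
    b <- drop(V %*% XtW %*% d$beta)
    se <- sqrt(diag(V))
    out[[s]] <- data.frame(snpid = s, moderator = colnames(X),
                           estimate = b, se = se,
                           p = 2 * pnorm(-abs(b / se)),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$q <- NA_real_
  fam <- res$moderator != "intercept"
  res$q[fam] <- p.adjust(res$p[fam], method = "BH")
  res
}
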