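#' Rescale rank-normalised Martingale-residual effect sizes to lnHR
#'
#' Effect sizes estimated on rank-normalised (unit-variance) Martingale
#' residuals depend on the study's proportion dead c: the residual
#' distribution has standard deviation approximately sqrt(c), and the
#' untransformed residual must be divided by c to estimate the hazard
#' ratio. Converting back therefore multiplies by sqrt(c) (to the raw
#' residual scale) and then by 1/c (to the lnHR scale), i.e. by 1/sqrt(c)
#' overall; a further factor 2 converts a subject-on-parent effect to an
#' effect in the carrier themselves.
#'
#' @param beta effect size on the rank-normalised residual scale.
#' @param c proportion dead in the originating study, in (0, 1\].
#' @param toSelf if TRUE, also double to the carrier (self) scale.
#' @param invert if TRUE, apply the inverse transformation.
#' @return Rescaled effect size(s).
#' @examples
#' martingaleRescale(1, c = 0.25, toSelf = TRUE)   # factor 4
#' # the published mother/father constants arise from c ~ 0.598 / 0.765
#' martingaleRescale(1, c = (2 / 2.5863)^2, toSelf = TRUE)
#' @export
martingaleRescale <- function(beta, c, toSelf = FALSE, invert = FALSE) {
  if (!is.finite(c) || c <= 0 || c > 1) stop("c must lie in (0, 1]")
  factor <- (if (toSelf) 2 else 1) / sqrt(c)
  if (invert) beta / factor else beta * factor
}

#' Expected additive-model effect of a recessive allele
#'
#' Under a purely recessive effect (only effect-allele homozygotes are
#' affected) observed through imputed parental genotypes, a parent who
#' transmitted the effect allele is homozygous with probability
#' q^2 / (q^2 + 2 p q), with q the effect-allele frequency and p = 1 - q.
#' The expected per-subject-allele effect on the parent trait is half the
#' homozygote effect times this factor, and doubling to the carrier scale
#' gives betaHom * q^2 / (q^2 + 2 p q).
#'
#' @param betaHom effect size in effect-allele homozygotes.
#' @param q effect-allele frequency in (0, 1).
#' @return list: \code{frequencyFactor} = q^2/(q^2 + 2pq),
#'   \code{betaCarrier} = betaHom * factor (additive carrier scale),
#'   \code{betaSubjectAllele} = betaCarrier / 2.
#' @examples
#' recessiveToAdditive(10, q = 0.269)$frequencyFactor  # ~ 0.155
#' @export
recessiveToAdditive <- function(betaHom, q) {
  if (!is.finite(q) || q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  p <- 1 - q
  f <- q^2 / (q^2 + 2 * p * q)
  list(frequencyFactor = f, betaCarrier = betaHom * f,
       betaSubjectAllele = betaHom * f / 2)
}

#' Empirical calibration between longevity log odds and log hazard ratios
#'
#' Longevity case-control studies report log odds ratios of surviving to
#' extreme age; lifespan GWAS report log hazard ratios. The two scales are
#' related empirically through an anchor variant measured on both (the
#' most powered variant available, typically at APOE): the conversion
#' factor is the ratio of the anchor's magnitudes. Published conversion
#' constants use both orientations, so the direction is explicit: the
#' returned \code{factor} converts FROM the odds-ratio scale TO the
#' hazard-ratio (lnPR) scale by division, or equivalently multiply by
#' \code{reciprocal}. Magnitudes are stored; apply signs via the lnPR
#' convention (positive = protective).
#'
#' @param logOR anchor log odds ratio (nonzero; magnitude used).
#' @param lnHR anchor log hazard ratio (nonzero; magnitude used).
#' @return list: \code{factor} = |logOR| / |lnHR| (OR units per HR unit),
#'   \code{reciprocal} = |lnHR| / |logOR|, and \code{convert(beta)}
#'   mapping OR-scale estimates to the lnPR scale.
#' @examples
#' longevityCalibration(logOR = 0.33, lnHR = 0.086)$factor      # ~ 3.84
#' longevityCalibration(logOR = 0.20, lnHR = 0.087)$reciprocal  # ~ 0.435
#' @export
longevityCalibration <- function(logOR, lnHR) {
  if (!is.finite(logOR) || logOR == 0) stop("zero/invalid logOR anchor")
  if (!is.finite(lnHR) || lnHR == 0) stop("zero/invalid lnHR anchor")
  factor <- abs(logOR) / abs(lnHR)
  list(factor = factor, reciprocal = 1 / factor,
       convert = function(beta) beta / factor)
}

#' Years of life per allele from the log protection ratio
#'
#' The actuarial rule of thumb for human mortality: one unit of log
#' protection ratio corresponds to roughly ten years of life, so
#' years = 10 * lnPR.
#'
#' @param beta effect size on the lnPR scale.
#' @param years effect size in years of life.
#' @return Numeric vector.
#' @examples
#' yearsFromLnpr(0.10561)  # ~ 1.06 years
#' lnprFromYears(1.0561)
#' @export
yearsFromLnpr <- function(beta) {
  stopifnot(all(is.finite(beta)))
  10 * beta
}

#' @rdname yearsFromLnpr
#' @export
lnprFromYears <- function(years) {
  stopifnot(all(is.finite(years)))
  years / 10
}

#' Equivalent sample size of a kin-cohort lifespan GWAS
#'
#' The power of a kin-cohort survival GWAS is diluted relative to a fully
#' heritable, directly measured trait by the trait heritability, the
#' r-squared of offspring dosage on parent genotype (0.25 under Mendelian
#' transmission) and the proportion of parents dead. The effective sample
#' size is the product of the raw count with those three fractions; it can
#' then be expressed as an equivalent sample size for a reference trait by
#' dividing by that trait's heritability.
#'
#' @param nLives number of parental lifespans analysed.
#' @param heritability lifespan heritability, in (0, 1\].
#' @param r2Kin offspring-to-parent genotype r-squared, in (0, 1\].
#' @param propDead proportion of parents deceased, in (0, 1\].
#' @param h2Reference heritability of the reference trait, in (0, 1\].
#' @return list: \code{nEffective} and \code{nReference} (both rounded to
#'   the nearest integer).
#' @examples
#' equivalentSampleSize(1012240, 0.122, 0.25, 0.602, h2Reference = 0.8)
#' @export
equivalentSampleSize <- function(nLives, heritability, r2Kin = 0.25,
                                 propDead, h2Reference = 1) {
  frac <- c(heritability, r2Kin, propDead, h2Reference)
  if (any(!is.finite(frac)) || any(frac <= 0) || any(frac > 1))
    stop("all fractions must lie in (0, 1]")
  nEff <- nLives * heritability * r2Kin * propDead
  list(nEffective = round(nEff),
       nReference = round(nEff / h2Reference))
}

#' Mean successive percentage increase of an ordered series
#'
#' Arithmetic mean of the step-to-step percentage increases
#' 100 * (v[i+1]/v[i] - 1) of an ordered positive series, e.g. annuity
#' prices across quinquennial purchase ages.
#'
#' @param values ordered numeric vector (>= 2 positive values).
#' @return Mean percentage increase (a single number).
#' @examples
#' meanSuccessiveIncrease(c(4158, 4680, 5476, 6075, 7105))  # ~ 14
#' @export
meanSuccessiveIncrease <- function(values) {
  if (length(values) < 2 || any(!is.finite(values)) || any(values <= 0))
    stop("need >= 2 positive values")
  mean(100 * (values[-1] / values[-length(values)] - 1))
}
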