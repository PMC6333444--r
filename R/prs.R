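#' Clump-and-threshold polygenic survival score model
#'
#' Builds a polygenic score weight list from lifespan summary statistics:
#' SNPs are pruned into independent loci (distance window, optional LD
#' threshold — the clumping step) and filtered at a p-value threshold.
#' The default threshold p <= 1 keeps all independent markers, the
#' configuration found most informative for lifespan. The training cohort
#' labels are recorded so that scoring a cohort used for training is
#' refused (leakage guard).
#'
#' @param sumstats data.frame with \code{snpid, chrom, pos, a1, beta1, p}.
#' @param pThreshold p-value threshold (default 1).
#' @param clumpKb clumping window in kb (default 250).
#' @param clumpR2 clumping r-squared threshold (default 0.1, used when
#'   \code{ld} is supplied).
#' @param ld optional LD r-squared matrix.
#' @param trainingCohorts character vector of cohort ids the summary
#'   statistics were estimated on.
#' @return A \code{PRSModel} object.
#' @examples
#' ss <- data.frame(snpid = c("rs1", "rs2"), chrom = "1",
#'                  pos = c(1e6, 5e6), a1 = "A", beta1 = c(0.1, -0.2),
#'                  p = c(1e-6, 0.03))
#' buildPRS(ss, trainingCohorts = "train")
#' @export
buildPRS <- function(sumstats, pThreshold = 1, clumpKb = 250,
                     clumpR2 = 0.1, ld = NULL,
                     trainingCohorts = character()) {
  stopifnot(all(c("snpid", "chrom", "pos", "a1", "beta1", "p") %in%
                  colnames(sumstats)))
  kept <- pruneLoci(sumstats, distanceKb = clumpKb, r2Max = clumpR2,
                    ld = ld)
  kept <- kept[kept$p <= pThreshold, , drop = FALSE]
  if (nrow(kept) == 0)
    stop("no SNPs pass the p-value threshold: empty score model")
  new("PRSModel",
      weights = data.frame(snpid = kept$snpid, a1 = kept$a1,
                           beta = kept$beta1, stringsAsFactors = FALSE),
      pThreshold = pThreshold, clumpKb = clumpKb, clumpR2 = clumpR2,
      trainingCohorts = as.character(trainingCohorts))
}

#' @rdname buildPRS
#' @export
setClass("PRSModel",
         representation(weights = "data.frame", pThreshold = "numeric",
                        clumpKb = "numeric", clumpR2 = "numeric",
                        trainingCohorts = "character"))

setValidity("PRSModel", function(object) {
  if (nrow(object@weights) == 0) return("empty weight list")
  TRUE
})

setMethod("show", "PRSModel", function(object) {
  cat("PRSModel: ", nrow(object@weights), " SNPs, p <= ",
      object@pThreshold, ", clump ", object@clumpKb, " kb / r2 ",
      object@clumpR2, "\n", sep = "")
})

#' Score a cohort with a polygenic survival model
#'
#' Computes sum(dosage x weight) over the model SNPs present in the
#' cohort (effect alleles aligned via the manifest; SNPs coded on the
#' other allele have their dosage reflected) and standardises the score
#' to mean 0, SD 1 on the scored sample, so downstream effects are per
#' score standard deviation. Refuses to score a cohort whose id is among
#' the model's training cohorts.
#'
#' @param model a \code{PRSModel}.
#' @param cohort a [LifespanCohort-class].
#' @return Standardised numeric score per subject, with attributes
#'   \code{mean} and \code{sd} (raw-scale standardisation constants) and
#'   \code{nSnps}.
#' @export
scorePRS <- function(model, cohort) {
  if (cohortId(cohort) %in% model@trainingCohorts)
    stop("cohort '", cohortId(cohort),
         "' was used to train this score: refusing to score it")
  snps <- snpInfo(cohort)
  idx <- match(model@weights$snpid, snps$id)
  use <- !is.na(idx)
  if (!any(use)) stop("no model SNPs present in cohort")
  w <- model@weights[use, , drop = FALSE]
  d <- meanImpute(t(dosages(cohort)))[, idx[use], drop = FALSE]
  flip <- w$a1 != snps$a1[idx[use]]
  d[, flip] <- 2 - d[, flip]
  raw <- drop(d %*% w$beta)
  s <- sd(raw)
  if (s <= 0) stop("degenerate score: zero variance")
  structure((raw - mean(raw)) / s, mean = mean(raw), sd = s,
            nSnps = nrow(w))
}

#' Survival association of a standardised polygenic score
#'
#' Cox proportional-hazards fit of survival on the standardised score
#' plus covariates. For parent phenotypes the estimate and SE are doubled
#' to the carrier (self) scale; for subject phenotypes they are not. The
#' sign is flipped to lnPR per score SD, and years of life per SD is
#' 10 x beta.
#'
#' @param score standardised score (one per subject).
#' @param age,dead survival record aligned to \code{score}.
#' @param covariates optional covariate matrix.
#' @param kin \code{"parent"} (doubled) or \code{"self"}.
#' @return data.frame row: \code{kin, n, deaths, beta, se, z, p, years}.
#' @export
associateSurvival <- function(score, age, dead, covariates = NULL,
                              kin = c("parent", "self")) {
  kin <- match.arg(kin)
  mult <- if (kin == "parent") 2 else 1
  X <- if (is.null(covariates) || NCOL(covariates) == 0) score
       else cbind(score, as.matrix(covariates))
  fit <- coxph(Surv(age, as.logical(dead)) ~ X, ties = "breslow")
  est <- coef(fit)[1]; se <- sqrt(vcov(fit)[1, 1])
  beta <- -mult * est; seAdj <- mult * se
  data.frame(kin = kin, n = sum(!is.na(age)),
             deaths = sum(dead, na.rm = TRUE), beta = beta, se = seAdj,
             z = beta / seAdj, p = 2 * pnorm(-abs(beta / seAdj)),
             years = 10 * beta, stringsAsFactors = FALSE)
}

#' Score a cohort and associate it with parental survival
#'
#' Convenience wrapper: scores the cohort, fits the doubled Cox
#' association against each parent's survival, and computes the decile
#' survival contrast.
#'
#' @inheritParams scorePRS
#' @return list: \code{score}, \code{association} (father and mother
#'   rows), \code{decileContrast}.
#' @export
scoreAndAssociate <- function(model, cohort) {
  score <- scorePRS(model, cohort)
  covs <- covariates(cohort)
  assoc <- do.call(rbind, lapply(c("father", "mother"), function(p) {
    rec <- parentRecords(cohort, p)
    r <- associateSurvival(score, rec$age, rec$dead, covs, "parent")
    cbind(parent = p, r)
  }))
  list(score = score, association = assoc,
       decileContrast = decileContrast(score,
                                       parentRecords(cohort, "father"),
                                       parentRecords(cohort, "mother")))
}

kmMedian <- function(age, dead) {
  fit <- survfit(Surv(age, dead) ~ 1)
  med <- unname(summary(fit)$table["median"])
  if (is.na(med))
    list(median = max(age), lowerBound = TRUE)
  else list(median = med, lowerBound = FALSE)
}

#' Kaplan-Meier survival contrast between top and bottom score deciles
#'
#' Assigns subjects to score deciles (stable tie-breaking by first-rank,
#' so a tied score is deterministically allocated) and contrasts the
#' Kaplan-Meier median survival of parents of top-decile subjects against
#' bottom-decile subjects, per parent. The parent-based contrast is
#' doubled to the carrier scale. Where a decile's survival curve does not
#' reach 0.5, the largest observed age is reported as a lower bound and
#' flagged.
#'
#' @param score numeric score per subject.
#' @param father,mother parent record data.frames (\code{age},
#'   \code{dead}).
#' @param doubled double the observed contrast (TRUE for parent records).
#' @return data.frame per parent: \code{medianTop, medianBottom,
#'   contrast, contrastDoubled, lowerBound}.
#' @export
decileContrast <- function(score, father, mother = NULL,
                           doubled = TRUE) {
  n <- length(score)
  if (n < 20) stop("too few subjects for decile contrast")
  dec <- ceiling(10 * rank(score, ties.method = "first") / n)
  parents <- list(father = father)
  if (!is.null(mother)) parents$mother <- mother
  out <- lapply(names(parents), function(p) {
    rec <- parents[[p]]
    top <- kmMedian(rec$age[dec == 10], rec$dead[dec == 10])
    bot <- kmMedian(rec$age[dec == 1], rec$dead[dec == 1])
    ctr <- top$median - bot$median
    data.frame(parent = p, medianTop = top$median,
               medianBottom = bot$median, contrast = ctr,
               contrastDoubled = if (doubled) 2 * ctr else ctr,
               lowerBound = top$lowerBound | bot$lowerBound,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Disease associations of a polygenic survival score across kin
#'
#' Per kin type and disease, logistic regression of NOT carrying the
#' disease on the standardised score plus covariates, so a positive
#' estimate means the score protects from disease. First-degree-relative
#' estimates and SEs are doubled to the carrier scale. Per disease, kin
#' estimates are combined by inverse-variance meta-analysis; the pooled
#' SE is inflated for phenotypic correlation between family members by
#' sqrt(1 + r) per correlated kin (or linearly by (1 + r) with
#' \code{seAdjust = "linear"}). BH q-values are computed across diseases.
#'
#' @param scores named list of numeric score vectors, one per kin type.
#' @param diseases named list (same names) of 0/1 disease matrices,
#'   subjects x diseases, with common column names.
#' @param firstDegree named logical: is the kin a first-degree relative
#'   of the score carrier (estimates doubled)?
#' @param kinCor named numeric: correlation of each non-reference kin's
#'   phenotype with the reference (first) kin; default 0.
#' @param covariatesList optional named list of covariate matrices.
#' @param seAdjust \code{"sqrt"} for sqrt(1+r) (default) or
#'   \code{"linear"} for (1+r).
#' @return list: \code{perKin} (one row per kin x disease) and
#'   \code{meta} (per disease: pooled beta, se, z, p, q).
#' @export
diseaseAssociations <- function(scores, diseases, firstDegree,
                                kinCor = NULL, covariatesList = NULL,
                                seAdjust = c("sqrt", "linear")) {
  seAdjust <- match.arg(seAdjust)
  kins <- names(scores)
  stopifnot(!is.null(kins), identical(sort(kins), sort(names(diseases))))
  perKin <- list()
  for (k in kins) {
    sc <- scores[[k]]
    dis <- as.matrix(diseases[[k]])
    cv <- if (!is.null(covariatesList)) covariatesList[[k]] else NULL
    dat <- if (is.null(cv) || NCOL(cv) == 0) data.frame(score = sc)
           else data.frame(score = sc, as.matrix(cv))
    mult <- if (isTRUE(firstDegree[[k]])) 2 else 1
    for (dname in colnames(dis)) {
      dat$.y <- 1 - dis[, dname]
      fit <- stats::glm(.y ~ ., data = dat, family = stats::binomial())
      est <- coef(fit)["score"]
      se <- sqrt(vcov(fit)["score", "score"])
      perKin[[length(perKin) + 1L]] <- data.frame(
        kin = k, disease = dname, beta = mult * est, se = mult * se,
        stringsAsFactors = FALSE)
    }
  }
  perKin <- do.call(rbind, perKin)
  rownames(perKin) <- NULL
  infl <- 1
  if (!is.null(kinCor) && length(kinCor)) {
    f <- if (seAdjust == "sqrt") sqrt(1 + kinCor) else (1 + kinCor)
    infl <- prod(f)
  }
  meta <- do.call(rbind, lapply(unique(perKin$disease), function(dname) {
    d <- perKin[perKin$disease == dname, ]
    w <- 1 / d$se^2
    b <- sum(w * d$beta) / sum(w)
    se <- sqrt(1 / sum(w)) * infl
    data.frame(disease = dname, beta = b, se = se, z = b / se,
               p = 2 * pnorm(-abs(b / se)), stringsAsFactors = FALSE)
  }))
  meta$q <- p.adjust(meta$p, method = "BH")
  list(perKin = perKin, meta = meta)
}
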