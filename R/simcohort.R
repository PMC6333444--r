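#' SNP specification table for simulation
#'
#' Builds and validates the manifest of biallelic SNPs used by the cohort
#' simulator. \code{beta} is the per-allele log protection ratio (lnPR) in
#' the allele carrier: positive values extend life. Under
#' \code{mode = "recessive"}, \code{beta} is the lnPR of effect-allele
#' homozygotes and heterozygotes are unaffected (used to exercise the
#' recessive-to-additive conversion).
#'
#' @param id character SNP identifiers (unique).
#' @param maf effect-allele frequency, in (0.005, 0.5\].
#' @param beta per-allele (or homozygote, if recessive) lnPR; finite.
#' @param mode "additive" or "recessive", recycled.
#' @param chrom,pos chromosome label and 1-based position; defaults place
#'   SNPs 1 Mb apart on chromosome 1.
#' @param a1,a0 effect and reference allele labels.
#' @return data.frame with columns id, chrom, pos, a1, a0, maf, beta, mode.
#' @examples
#' snpSpec(id = c("rs1", "rs2"), maf = c(0.3, 0.02), beta = c(0.1, 0))
#' @export
snpSpec <- function(id, maf, beta = 0, mode = "additive",
                    chrom = "1", pos = NULL,
                    a1 = "A", a0 = "G") {
  m <- length(id)
  if (anyDuplicated(id)) stop("duplicate SNP ids")
  maf <- rep_len(maf, m); beta <- rep_len(beta, m)
  mode <- rep_len(mode, m)
  if (any(!is.finite(maf)) || any(maf <= 0.005) || any(maf > 0.5))
    stop("maf must lie in (0.005, 0.5]")
  if (any(!is.finite(beta))) stop("beta must be finite")
  if (!all(mode %in% c("additive", "recessive")))
    stop("mode must be 'additive' or 'recessive'")
  if (is.null(pos)) pos <- seq_len(m) * 1e6
  data.frame(id = as.character(id), chrom = rep_len(chrom, m),
             pos = as.numeric(pos), a1 = rep_len(a1, m),
             a0 = rep_len(a0, m), maf = maf, beta = beta, mode = mode,
             stringsAsFactors = FALSE)
}

#' Simulate parental genotypes and transmitted offspring dosages
#'
#' Parents are drawn from Hardy-Weinberg proportions at each SNP; the
#' offspring dosage is the sum of one allele transmitted from each parent.
#' This transmission model gives the kin-cohort dilution the analysis
#' corrects for: the squared correlation between offspring dosage and
#' either parent's genotype is 0.25 in expectation, so effects observed on
#' offspring dosage are half the effect in the parent who carries the
#' allele.
#'
#' @param nSubjects number of subjects (>= 1).
#' @param snps a [snpSpec()] manifest.
#' @param seed integer seed; all simulator randomness is local to the call.
#' @return list with integer matrices \code{father}, \code{mother}
#'   (subjects x SNPs, values 0/1/2) and \code{dosage} (offspring).
#' @examples
#' g <- simulateGenotypes(500, snpSpec("rs1", 0.3), seed = 1)
#' cor(g$dosage[, 1], g$father[, 1])^2  # ~ 0.25
#' @export
simulateGenotypes <- function(nSubjects, snps, seed) {
  stopifnot(nSubjects >= 1)
  snps <- validateSnps(snps)
  m <- nrow(snps)
  withSeed(seed, {
    father <- matrix(rbinom(nSubjects * m, 2L,
                            rep(snps$maf, each = nSubjects)),
                     nrow = nSubjects, ncol = m)
    mother <- matrix(rbinom(nSubjects * m, 2L,
                            rep(snps$maf, each = nSubjects)),
                     nrow = nSubjects, ncol = m)
    tf <- matrix(rbinom(nSubjects * m, 1L, father / 2),
                 nrow = nSubjects)
    tm <- matrix(rbinom(nSubjects * m, 1L, mother / 2),
                 nrow = nSubjects)
    dosage <- tf + tm
    colnames(father) <- colnames(mother) <- colnames(dosage) <- snps$id
    list(father = father, mother = mother, dosage = dosage)
  })
}

validateSnps <- function(snps) {
  stopifnot(is.data.frame(snps), all(c("id", "maf") %in% colnames(snps)))
  if (!"beta" %in% colnames(snps)) snps$beta <- 0
  if (!"mode" %in% colnames(snps)) snps$mode <- "additive"
  if (any(!is.finite(snps$maf)) || any(snps$maf <= 0.005) ||
      any(snps$maf > 0.5))
    stop("maf must lie in (0.005, 0.5]")
  if (any(!is.finite(snps$beta))) stop("beta must be finite")
  snps
}

# per-parent log hazard shift from own genotype: -beta per effect allele
# (additive) or -beta for effect homozygotes (recessive)
genotypeLogHazard <- function(geno, snps) {
  add <- snps$mode == "additive"
  eta <- numeric(nrow(geno))
  if (any(add))
    eta <- eta - geno[, add, drop = FALSE] %*% snps$beta[add]
  if (any(!add))
    eta <- eta - (geno[, !add, drop = FALSE] == 2L) %*% snps$beta[!add]
  drop(eta)
}

#' Simulate parental lifespans under a Gompertz proportional-hazards model
#'
#' Death ages are drawn by inverse transform from the Gompertz survival
#' function conditioned on survival to the entry age (40 by default), with
#' each parent's log hazard shifted by their own genotype (minus the
#' carrier lnPR per effect allele) and by a Gaussian log-frailty shared by
#' the two parents of a subject, which induces the father-mother lifespan
#' correlation. Parents alive at a drawn censoring age are censored there;
#' ages are capped at 120. The default frailty scale \code{rho = 0.45} is
#' calibrated so the father-mother Martingale-residual correlation is
#' about 0.1, and the default censoring window Uniform(70, 100) yields
#' about 60\% of parents deceased.
#'
#' @param parents list with \code{father} and \code{mother} genotype
#'   matrices, as returned by [simulateGenotypes()].
#' @param snps the [snpSpec()] manifest.
#' @param gp a [gompertzParams()] object.
#' @param rho standard deviation of the shared Gaussian log-frailty, in
#'   \[0, 0.5\]; 0 gives independent parents.
#' @param censorRange two ages (years); censoring ages are drawn uniformly
#'   between them.
#' @param seed integer seed.
#' @return list of two data.frames (\code{father}, \code{mother}) with
#'   columns \code{age} and \code{dead}.
#' @export
simulateLifespans <- function(parents, snps, gp = gompertzParams(),
                              rho = 0.45, censorRange = c(70, 100),
                              seed) {
  snps <- validateSnps(snps)
  if (!is.finite(rho) || rho < 0 || rho > 0.5)
    stop("rho must lie in [0, 0.5]")
  stopifnot(inherits(gp, "GompertzParams"), length(censorRange) == 2,
            censorRange[1] < censorRange[2])
  n <- nrow(parents$father)
  etaF <- genotypeLogHazard(parents$father, snps)
  etaM <- genotypeLogHazard(parents$mother, snps)
  withSeed(seed, {
    frail <- rnorm(n, 0, rho)
    one <- function(eta) {
      t <- gompertzConditionalQuantile(runif(n), gp, eta + frail)
      cens <- pmin(runif(n, censorRange[1], censorRange[2]), 120)
      data.frame(age = pmin(t, cens, 120), dead = t <= cens)
    }
    list(father = one(etaF), mother = one(etaM))
  })
}

#' Simulate a complete kin-cohort sample
#'
#' Convenience wrapper tying [simulateGenotypes()] and
#' [simulateLifespans()] into a [LifespanCohort-class] object, with
#' subject sex and two standard-normal nuisance covariates (stand-ins for
#' genetic principal components, independent of genotype by construction).
#'
#' @inheritParams simulateGenotypes
#' @inheritParams simulateLifespans
#' @param cohortId label stored in the object's metadata.
#' @return A [LifespanCohort-class]; latent parental genotypes are kept as
#'   assays \code{fatherGeno}/\code{motherGeno} for oracle checks.
#' @examples
#' coh <- simulateCohort(500, snpSpec("rs1", 0.3, 0.1), seed = 7)
#' mean(parentRecords(coh, "father")$dead)
#' @export
simulateCohort <- function(nSubjects, snps, gp = gompertzParams(),
                           rho = 0.45, censorRange = c(70, 100),
                           cohortId = "sim1", seed) {
  snps <- validateSnps(snps)
  g <- simulateGenotypes(nSubjects, snps, seed = seed)
  ls <- simulateLifespans(g, snps, gp = gp, rho = rho,
                          censorRange = censorRange, seed = seed + 1L)
  covs <- withSeed(seed + 2L, cbind(sex = rbinom(nSubjects, 1, 0.5),
                                    pc1 = rnorm(nSubjects),
                                    pc2 = rnorm(nSubjects)))
  LifespanCohort(dosage = t(g$dosage), snps = snps,
                 father = ls$father, mother = ls$mother,
                 covariates = covs, cohortId = cohortId,
                 fatherGeno = t(g$father), motherGeno = t(g$mother))
}

#' Simulate risk-factor GWAS summary statistics with known causal structure
#'
#' Generates per-SNP effects on \code{length(causalEffects)} risk factors
#' and a true lifespan effect equal to the causal combination
#' sum_k causal_k * factorEffect_k (plus optional residual noise), the
#' structure assumed by the risk-factor-informed GWAS prior. Observed
#' factor estimates are the true factor effects plus Gaussian noise with
#' standard error \code{noiseSe}.
#'
#' @param snps a [snpSpec()] manifest.
#' @param causalEffects numeric vector: causal effect of each standardised
#'   factor on standardised lifespan.
#' @param noiseSe per-factor standard error of the observed factor effect
#'   estimates (vector or scalar, >= 0).
#' @param lifespanNoiseSd SD of lifespan effects not mediated by the
#'   factors (default 0: fully mediated).
#' @param factorEffectSd SD of the true per-SNP factor effects.
#' @param seed integer seed.
#' @return list: \code{factorTables} (one summary-statistics data.frame
#'   per factor: snpid, a1, a0, beta, se), \code{trueBeta} (true lifespan
#'   effect per SNP), \code{causalEffects}.
#' @export
simulateRiskFactorStats <- function(snps, causalEffects, noiseSe = 0.02,
                                    lifespanNoiseSd = 0,
                                    factorEffectSd = 1, seed) {
  snps <- validateSnps(snps)
  k <- length(causalEffects)
  noiseSe <- rep_len(noiseSe, k)
  if (any(noiseSe < 0)) stop("noiseSe must be non-negative")
  m <- nrow(snps)
  withSeed(seed, {
    b <- matrix(rnorm(m * k, 0, factorEffectSd), m, k)
    trueBeta <- drop(b %*% causalEffects) + rnorm(m, 0, lifespanNoiseSd)
    tables <- lapply(seq_len(k), function(j) {
      data.frame(snpid = snps$id, a1 = snps$a1, a0 = snps$a0,
                 beta = b[, j] + rnorm(m, 0, noiseSe[j]),
                 se = rep(noiseSe[j], m), stringsAsFactors = FALSE)
    })
    names(tables) <- paste0("factor", seq_len(k))
    list(factorTables = tables, trueBeta = trueBeta,
         causalEffects = causalEffects)
  })
}

#' Read and write cohort tables and SNP manifests
#'
#' Tab-delimited plain-text interchange for simulated cohorts: one row per
#' subject with id, per-SNP dosage columns (named by SNP id), covariates,
#' and the four parent survival fields; the SNP manifest as a companion
#' TSV (positions 1-based).
#'
#' @param cohort a [LifespanCohort-class].
#' @param file,manifestFile paths.
#' @return \code{readCohortTable} returns a [LifespanCohort-class];
#'   writers return the path invisibly.
#' @export
writeCohortTable <- function(cohort, file) {
  d <- t(dosages(cohort))
  covs <- covariates(cohort)
  out <- data.frame(subject_id = colnames(cohort), d, covs,
                    father_age = colData(cohort)$father_age,
                    father_dead = as.integer(colData(cohort)$father_dead),
                    mother_age = colData(cohort)$mother_age,
                    mother_dead = as.integer(colData(cohort)$mother_dead),
                    check.names = FALSE)
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeCohortTable
#' @export
writeSnpManifest <- function(cohort, file) {
  write.table(snpInfo(cohort), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' @rdname writeCohortTable
#' @param cohortId label for the object read back.
#' @export
readCohortTable <- function(file, manifestFile, cohortId = "cohort1") {
  tab <- read.delim(file, check.names = FALSE)
  snps <- read.delim(manifestFile, colClasses = c(id = "character"))
  stopifnot(all(snps$id %in% colnames(tab)))
  d <- as.matrix(tab[, snps$id, drop = FALSE])
  fixed <- c("subject_id", snps$id, .parentCols)
  covNames <- setdiff(colnames(tab), fixed)
  LifespanCohort(
    dosage = t(d), snps = snps,
    father = data.frame(age = tab$father_age,
                        dead = tab$father_dead == 1),
    mother = data.frame(age = tab$mother_age,
                        dead = tab$mother_dead == 1),
    covariates = if (length(covNames))
      as.matrix(tab[, covNames, drop = FALSE]) else NULL,
    cohortId = cohortId, subjectIds = as.character(tab$subject_id))
}
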