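#' LifespanCohort: subjects, genotype dosages and parental survival
#'
#' An S4 container for a kin-cohort sample, extending
#' \linkS4class{SummarizedExperiment}. Rows are SNPs, columns are subjects.
#' The \code{"dosage"} assay holds allelic dosages in \[0, 2\] (effect-allele
#' counts, possibly fractional for imputed genotypes). \code{rowData} is the
#' SNP manifest (\code{id}, \code{chrom}, \code{pos}, \code{a1}, \code{a0},
#' \code{maf}, \code{beta}, \code{mode}). \code{colData} carries the subject
#' covariates together with the two parental survival records
#' (\code{father_age}, \code{father_dead}, \code{mother_age},
#' \code{mother_dead}): age at death or at last observation, and a
#' dead/alive flag. Parents dying at or before age 40 are excluded upstream
#' (the analysis conditions on parental survival to 40).
#'
#' Simulated cohorts additionally carry \code{"fatherGeno"} and
#' \code{"motherGeno"} assays with the latent parental genotypes, used only
#' by oracle checks.
#'
#' @param dosage numeric matrix of dosages, SNPs x subjects, values in
#'   \[0, 2\] (NA allowed).
#' @param snps data.frame SNP manifest, one row per row of \code{dosage};
#'   must contain at least \code{id}; see [snpSpec()].
#' @param father,mother data.frames with columns \code{age} (years) and
#'   \code{dead} (logical), one row per subject.
#' @param covariates numeric matrix or data.frame of subject covariates
#'   (may have zero columns).
#' @param cohortId single character label for the cohort.
#' @param subjectIds character vector of unique subject identifiers.
#' @param ... further assays (e.g. latent parent genotypes).
#' @param x a \code{LifespanCohort}.
#' @param parent \code{"father"} or \code{"mother"}.
#'
#' @return \code{LifespanCohort()} returns a validated object.
#'   \code{dosages()} the dosage matrix; \code{snpInfo()} the manifest as a
#'   data.frame; \code{covariates()} the covariate matrix;
#'   \code{parentRecords()} a data.frame with \code{age} and \code{dead};
#'   \code{cohortId()} the label.
#'
#' @examples
#' snps <- snpSpec(id = c("rs1", "rs2"), maf = c(0.3, 0.1),
#'                 beta = c(0.1, 0))
#' coh <- simulateCohort(200, snps, seed = 1)
#' coh
#' dim(dosages(coh))
#' head(parentRecords(coh, "father"))
#'
#' @aliases dosages snpInfo covariates parentRecords cohortId
#' @export
setClass("LifespanCohort", contains = "SummarizedExperiment")

.parentCols <- c("father_age", "father_dead", "mother_age", "mother_dead")

setValidity("LifespanCohort", function(object) {
  msg <- character()
  if (!"dosage" %in% assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- assay(object, "dosage")
    if (any(d < 0 | d > 2, na.rm = TRUE))
      msg <- c(msg, "dosages must lie in [0, 2]")
  }
  cd <- colData(object)
  miss <- setdiff(.parentCols, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste("colData lacks parent columns:",
                        paste(miss, collapse = ", ")))
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate subject ids")
  if (!length(miss)) {
    for (p in c("father", "mother")) {
      age <- cd[[paste0(p, "_age")]]
      dead <- cd[[paste0(p, "_dead")]]
      if (any(age > 120, na.rm = TRUE))
        msg <- c(msg, paste(p, "ages exceed 120"))
      if (any(dead & age <= 40, na.rm = TRUE))
        msg <- c(msg, paste(p, "deaths at or before age 40 must be excluded"))
    }
  }
  if (is.null(metadata(object)$cohortId))
    msg <- c(msg, "metadata 'cohortId' is required")
  if (length(msg)) msg else TRUE
})

#' @rdname LifespanCohort-class
#' @export
LifespanCohort <- function(dosage, snps, father, mother,
                           covariates = NULL, cohortId = "cohort1",
                           subjectIds = NULL, ...) {
  dosage <- as.matrix(dosage)
  n <- ncol(dosage)
  if (is.null(subjectIds))
    subjectIds <- if (!is.null(colnames(dosage))) colnames(dosage)
                  else sprintf("S%05d", seq_len(n))
  if (is.null(covariates))
    covariates <- matrix(numeric(0), nrow = n, ncol = 0)
  covariates <- as.matrix(covariates)
  if (ncol(covariates) > 0 && is.null(colnames(covariates)))
    colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
  stopifnot(nrow(snps) == nrow(dosage), nrow(father) == n,
            nrow(mother) == n, nrow(covariates) == n)
  cd <- DataFrame(covariates,
                  father_age = father$age,
                  father_dead = as.logical(father$dead),
                  mother_age = mother$age,
                  mother_dead = as.logical(mother$dead),
                  row.names = subjectIds)
  se <- SummarizedExperiment(
    assays = c(list(dosage = dosage), list(...)),
    rowData = DataFrame(snps, row.names = snps$id),
    colData = cd)
  metadata(se)$cohortId <- cohortId
  metadata(se)$covariateNames <- colnames(covariates)
  new("LifespanCohort", se)
}

#' @rdname LifespanCohort-class
#' @export
setMethod("dosages", "LifespanCohort", function(x, ...)
  assay(x, "dosage"))

#' @rdname LifespanCohort-class
#' @export
setMethod("snpInfo", "LifespanCohort", function(x, ...)
  as.data.frame(rowData(x)))

#' @rdname LifespanCohort-class
#' @export
setMethod("covariates", "LifespanCohort", function(x, ...) {
  nm <- metadata(x)$covariateNames
  if (is.null(nm) || length(nm) == 0)
    return(matrix(numeric(0), nrow = ncol(x), ncol = 0))
  as.matrix(as.data.frame(colData(x)[, nm, drop = FALSE]))
})

#' @rdname LifespanCohort-class
#' @export
setMethod("parentRecords", "LifespanCohort", function(x, parent, ...) {
  parent <- match.arg(parent, c("father", "mother"))
  data.frame(age = colData(x)[[paste0(parent, "_age")]],
             dead = colData(x)[[paste0(parent, "_dead")]],
             row.names = colnames(x))
})

#' @rdname LifespanCohort-class
#' @export
setMethod("cohortId", "LifespanCohort", function(x)
  metadata(x)$cohortId)

setMethod("show", "LifespanCohort", function(object) {
  cd <- colData(object)
  nd <- sum(cd$father_dead) + sum(cd$mother_dead)
  cat("LifespanCohort '", metadata(object)$cohortId, "': ",
      ncol(object), " subjects, ", nrow(object), " SNPs\n", sep = "")
  cat("  parent lives: ", 2L * ncol(object), " (", nd, " deaths, ",
      sprintf("%.1f%%", 50 * nd / ncol(object)), " dead)\n", sep = "")
  nm <- metadata(object)$covariateNames
  cat("  covariates: ",
      if (length(nm)) paste(nm, collapse = ", ") else "(none)", "\n",
      sep = "")
})
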