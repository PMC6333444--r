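#' @rdname LifespanCohort-class
#' @export
setGeneric("dosages", function(x, ...) standardGeneric("dosages"))

#' @rdname LifespanCohort-class
#' @export
setGeneric("snpInfo", function(x, ...) standardGeneric("snpInfo"))

#' @rdname LifespanCohort-class
#' @export
setGeneric("covariates", function(x, ...) standardGeneric("covariates"))

#' @rdname LifespanCohort-class
#' @export
setGeneric("parentRecords", function(x, parent, ...)
  standardGeneric("parentRecords"))

#' @rdname LifespanCohort-class
#' @export
setGeneric("cohortId", function(x) standardGeneric("cohortId"))

#' @rdname residualPhenotype
#' @export
setGeneric("residualPhenotype", function(x, parent, ...)
  standardGeneric("residualPhenotype"))
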