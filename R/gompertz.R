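#' Gompertz baseline hazard parameters
#'
#' The simulator's baseline mortality is Gompertz, h0(x) = a * exp(b * x),
#' left-truncated at \code{entryAge}: all simulated parents are conditioned
#' on survival to that age, mirroring an analysis that excludes parental
#' deaths at 40 or younger. The defaults (a = 2e-5 per year, b = 0.1 per
#' year) put the modal age at death in the mid-80s, a realistic shape for
#' European cohorts born in the early 20th century.
#'
#' @param a baseline hazard at age 0, per year (> 0).
#' @param b log-hazard slope, per year (> 0).
#' @param entryAge left-truncation age in years (>= 0).
#' @return An object of class \code{"GompertzParams"} (a validated list).
#' @examples
#' gp <- gompertzParams()
#' gompertzConditionalSurvival(80, gp)
#' @export
gompertzParams <- function(a = 2e-5, b = 0.1, entryAge = 40) {
  stopifnot(is.finite(a), is.finite(b), is.finite(entryAge),
            a > 0, b > 0, entryAge >= 0)
  if (a * exp(b * entryAge) >= 1)
    stop("degenerate hazard: a*exp(b*entryAge) >= 1 per year")
  structure(list(a = a, b = b, entryAge = entryAge),
            class = "GompertzParams")
}

#' Conditional Gompertz survival and quantile functions
#'
#' Survival and inverse survival of a Gompertz lifetime with proportional
#' hazard multiplier \code{exp(eta)}, conditioned on survival to the entry
#' age: S(x | entry) = exp(-exp(eta) * a/b * (exp(b x) - exp(b entry))).
#' \code{gompertzConditionalQuantile} inverts the conditional survival at
#' probability \code{u} (so \code{u = 0.5} gives the conditional median);
#' it is the inverse-transform sampler used by [simulateLifespans()].
#'
#' @param x age in years (vector).
#' @param gp a [gompertzParams()] object.
#' @param eta log hazard-ratio shift (vector or scalar).
#' @param u survival probability in (0, 1) (vector).
#' @return Numeric vector of survival probabilities, or of ages.
#' @export
gompertzConditionalSurvival <- function(x, gp = gompertzParams(), eta = 0) {
  stopifnot(inherits(gp, "GompertzParams"))
  ifelse(x < gp$entryAge, 1,
         exp(-exp(eta) * gp$a / gp$b *
               (exp(gp$b * x) - exp(gp$b * gp$entryAge))))
}

#' @rdname gompertzConditionalSurvival
#' @export
gompertzConditionalQuantile <- function(u, gp = gompertzParams(), eta = 0) {
  stopifnot(inherits(gp, "GompertzParams"), all(u > 0 & u < 1))
  (1 / gp$b) * log(exp(gp$b * gp$entryAge) -
                     gp$b * log(u) / (gp$a * exp(eta)))
}
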