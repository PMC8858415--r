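## Quantile-matched two-piece (split) normal sampler.  Published cohort
## tables report only Me [Q1; Q3]; a split normal with piecewise scales
## fitted to the quartiles is the minimal model that reproduces all three
## printed quantiles exactly and accommodates the strong skew of entries
## such as 6 [6; 8].

# upper quartile of the standard normal; the divisor mapping (Me - Q1) and
# (Q3 - Me) to the piecewise scales
split_normal_z <- qnorm(0.75)

#' Quartile specification of a variable
#'
#' @param me median
#' @param q1,q3 lower and upper quartiles; `q1 <= me <= q3`
#' @param lower,upper optional clamps applied after sampling
#' @param integer_valued round samples to integers (scores and grades)
#' @return object of class `quartile_spec`
#' @export
quartile_spec <- function(me, q1, q3, lower = -Inf, upper = Inf,
                          integer_valued = FALSE) {
  if (is.na(lower)) lower <- -Inf
  if (is.na(upper)) upper <- Inf
  if (!(q1 <= me && me <= q3))
    stop("quartiles must satisfy q1 <= me <= q3")
  if (!(lower <= q1 && q3 <= upper))
    stop("clamps must contain [q1, q3]")
  structure(list(me = me, q1 = q1, q3 = q3, lower = lower, upper = upper,
                 integer_valued = isTRUE(integer_valued)),
            class = "quartile_spec")
}

#' Fit the two-piece normal to a quartile specification
#'
#' The split normal shares its location `me` between two half-normals with
#' scales `sigma_low = (me - q1) / qnorm(0.75)` and
#' `sigma_high = (q3 - me) / qnorm(0.75)`, so its quantile function
#' reproduces (q1, me, q3) exactly; a zero scale degenerates to a point
#' mass on that side.
#'
#' @param spec a [quartile_spec()]
#' @return object of class `two_piece`: list with `me`, `sigma_low`,
#'   `sigma_high` and the originating `spec`
#' @export
#' @examples
#' fit_two_piece(quartile_spec(6, 6, 8))   # sigma_low 0, sigma_high ~2.97
fit_two_piece <- function(spec) {
  stopifnot(inherits(spec, "quartile_spec"))
  structure(list(me = spec$me,
                 sigma_low = (spec$me - spec$q1) / split_normal_z,
                 sigma_high = (spec$q3 - spec$me) / split_normal_z,
                 spec = spec),
            class = "two_piece")
}

#' Quantile function of a fitted two-piece normal
#'
#' Closed form, before clamping or rounding: `me + sigma_low * qnorm(p)` for
#' `p < 0.5`, `me + sigma_high * qnorm(p)` otherwise.
#'
#' @param params a [fit_two_piece()] fit
#' @param p probabilities in (0, 1)
#' @return quantiles
#' @export
two_piece_quantile <- function(params, p) {
  stopifnot(inherits(params, "two_piece"), all(p > 0 & p < 1))
  z <- qnorm(p)
  ifelse(p < 0.5, params$me + params$sigma_low * z,
         params$me + params$sigma_high * z)
}

#' Sample from a fitted two-piece normal
#'
#' Inverse-transform sampling through [two_piece_quantile()], then clamping
#' to the spec's bounds and, for integer-valued variables, rounding
#' (rounding happens before the final clamp so extreme scores stay on the
#' scale).
#'
#' @param params a [fit_two_piece()] fit
#' @param n number of draws
#' @param seed optional integer; when given, draws are reproducible and the
#'   caller's RNG state is untouched
#' @return numeric vector of length `n`
#' @export
sample_continuous <- function(params, n, seed = NULL) {
  stopifnot(inherits(params, "two_piece"), n >= 1)
  draw <- function() {
    u <- runif(n)
    x <- two_piece_quantile(params, u)
    if (params$spec$integer_valued) x <- round(x)
    pmin(params$spec$upper, pmax(params$spec$lower, x))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Sample ordinal grades from a quartile specification
#'
#' Grades are sampled on their numeric axis with the two-piece model, then
#' rounded to the nearest integer and clamped to the scale, so that the
#' large-sample median reproduces the spec's median grade.
#'
#' @param spec a [quartile_spec()] whose me/q1/q3 are grade numbers and whose
#'   `lower`/`upper` are the scale limits
#' @param n number of draws
#' @param seed optional integer seed
#' @return integer vector of grades
#' @export
sample_ordinal <- function(spec, n, seed = NULL) {
  stopifnot(is.finite(spec$lower), is.finite(spec$upper))
  spec$integer_valued <- TRUE
  as.integer(sample_continuous(fit_two_piece(spec), n, seed = seed))
}

#' Sample facet tropism from a printed symbol
#'
#' The cohort tables report tropism only as "+", "-", or "+/-" per stratum.
#' The documented mapping draws tropism present with probability 0.9, 0.1
#' and 0.5 respectively.
#'
#' @param symbol one of "+", "-", "+/-"
#' @param n number of draws
#' @param seed optional integer seed
#' @return logical vector
#' @export
sample_tropism <- function(symbol, n, seed = NULL) {
  p <- switch(symbol, "+" = 0.9, "-" = 0.1, "+/-" = 0.5,
              stop(sprintf("unknown tropism symbol '%s'", symbol)))
  draw <- function() runif(n) < p
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
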