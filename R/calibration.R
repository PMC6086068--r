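#' Population conversion rate from mean sister-species age
#'
#' Under protracted speciation the reciprocal of the conversion rate is the
#' expected duration of speciation, so the mean divergence time `t` of extant
#' sister species gives a conversion rate of `1 / (2 t)`: on average a sister
#' pair split `t` Myr ago and each member spent half its history as an
#' incipient lineage.
#'
#' @param sister_age Mean sister-species divergence time, in Myr. Must be
#'   strictly positive.
#' @return Conversion rate (chi), per lineage per Myr.
#' @examples
#' chi_from_sister_age(1)    # 0.5  (temperate birds)
#' chi_from_sister_age(3.4)  # 0.147 (tropical birds)
#' @export
chi_from_sister_age <- function(sister_age) {
  stopifnot(is.numeric(sister_age), is.finite(sister_age))
  if (any(sister_age <= 0))
    stop("'sister_age' must be strictly positive", call. = FALSE)
  1 / (2 * sister_age)
}

#' Population splitting rate from a macro-level speciation rate
#'
#' The macro-level speciation rate lambda is the product of the population
#' splitting rate lambda' and the conversion rate chi, so lambda' = lambda/chi.
#'
#' @param speciation_rate Macro-level speciation rate (lambda), per Myr.
#' @param conversion_rate Population conversion rate (chi), per Myr; > 0.
#' @return Population splitting rate (lambda'), per Myr.
#' @examples
#' splitting_rate_from_speciation(0.58, 0.5)   # 1.16
#' splitting_rate_from_speciation(0.17, 0.15)  # 1.133...
#' @export
splitting_rate_from_speciation <- function(speciation_rate, conversion_rate) {
  stopifnot(is.numeric(speciation_rate), is.numeric(conversion_rate),
            is.finite(speciation_rate), is.finite(conversion_rate),
            speciation_rate >= 0)
  if (any(conversion_rate <= 0))
    stop("'conversion_rate' must be strictly positive", call. = FALSE)
  speciation_rate / conversion_rate
}

# shared exponent: expected number of still-intraspecific populations after
# `horizon` Myr, exp(lambda' * horizon) * (1 - chi)
bd_pop_exponent <- function(splitting_rate, conversion_rate, horizon) {
  stopifnot(is.finite(splitting_rate), splitting_rate >= 0,
            is.finite(conversion_rate), conversion_rate >= 0,
            is.finite(horizon), horizon > 0)
  if (conversion_rate >= 1)
    stop("'conversion_rate' must be < 1: the expected count of ",
         "non-converted populations, exp(lambda' t) (1 - chi), must be ",
         "positive for the extinction/extirpation map to be invertible",
         call. = FALSE)
  exp(splitting_rate * horizon) * (1 - conversion_rate)
}

#' Macro-level species extinction rate implied by a population extirpation rate
#'
#' A species goes extinct only when all of its within-species populations are
#' extirpated. With `exp(lambda' t)` populations expected after `t` Myr, of
#' which a fraction `(1 - chi)` remain intraspecific, the species extinction
#' rate is the extirpation rate raised to that expected population count:
#' `mu = mu'^(exp(lambda' t) (1 - chi))`. With rates per Myr, `t` is 1.
#'
#' @param extirpation_rate Population extirpation rate (mu'), per Myr, >= 0.
#' @param splitting_rate Population splitting rate (lambda'), per Myr.
#' @param conversion_rate Population conversion rate (chi), per Myr; must be
#'   < 1 so the exponent is positive.
#' @param horizon Time over which populations accumulate, Myr; default 1
#'   (rates per Myr).
#' @return Macro-level extinction rate (mu), per Myr.
#' @seealso [extirpation_rate_from_extinction()] for the inverse map.
#' @examples
#' species_extinction_from_extirpation(0.6, 1.16, 0.5)  # ~0.44
#' @export
species_extinction_from_extirpation <- function(extirpation_rate,
                                                splitting_rate,
                                                conversion_rate,
                                                horizon = 1) {
  stopifnot(is.numeric(extirpation_rate), is.finite(extirpation_rate),
            extirpation_rate >= 0)
  ex <- bd_pop_exponent(splitting_rate, conversion_rate, horizon)
  extirpation_rate^ex
}

#' Population extirpation rate implied by a macro-level extinction rate
#'
#' Algebraic inverse of [species_extinction_from_extirpation()]:
#' `mu' = mu^(1 / (exp(lambda' t) (1 - chi)))`. The extinction rate is
#' treated as a probability-like quantity and must lie in [0, 1].
#'
#' @param extinction_rate Macro-level extinction rate (mu), per Myr, in [0, 1].
#' @param splitting_rate Population splitting rate (lambda'), per Myr.
#' @param conversion_rate Population conversion rate (chi), per Myr; < 1.
#' @param horizon Time over which populations accumulate, Myr; default 1.
#' @return Population extirpation rate (mu'), per Myr.
#' @examples
#' extirpation_rate_from_extinction(0.45, 1.16, 0.5)   # ~0.61, printed 0.6
#' extirpation_rate_from_extinction(0.04, 1.13, 0.15)  # ~0.29, printed 0.3
#' @export
extirpation_rate_from_extinction <- function(extinction_rate,
                                             splitting_rate,
                                             conversion_rate,
                                             horizon = 1) {
  stopifnot(is.numeric(extinction_rate), is.finite(extinction_rate))
  if (any(extinction_rate < 0) || any(extinction_rate > 1))
    stop("'extinction_rate' must lie in [0, 1]", call. = FALSE)
  ex <- bd_pop_exponent(splitting_rate, conversion_rate, horizon)
  extinction_rate^(1 / ex)
}

#' Calibrate the three micro-level protracted rates from macro-level rates
#'
#' Combines the closed-form maps: chi = 1/(2 t), lambda' = lambda/chi,
#' mu' = mu^(1/(exp(lambda') (1 - chi))). Full-precision values are returned
#' together with values rounded to the conventional reporting precision
#' (2 decimals for chi and lambda', 1 for mu'), since published simulation
#' scenarios are usually parameterised with the rounded numbers.
#'
#' @param speciation_rate Macro speciation rate (lambda), per Myr.
#' @param extinction_rate Macro extinction rate (mu), per Myr, in [0, 1].
#' @param sister_age Mean sister-species divergence time (t), Myr.
#' @param horizon Accumulation time for the extirpation map, Myr; default 1.
#' @return A one-row data frame with columns `conversion_rate`,
#'   `splitting_rate`, `extirpation_rate` and their `_rounded` counterparts.
#'   The rounded lambda' and mu' are derived from the rounded chi, matching
#'   how the scenario rates are conventionally quoted.
#' @examples
#' calibrate_micro_rates(0.58, 0.45, 1)    # temperate birds
#' calibrate_micro_rates(0.17, 0.04, 3.4)  # tropical birds
#' @export
calibrate_micro_rates <- function(speciation_rate, extinction_rate,
                                  sister_age, horizon = 1) {
  chi <- chi_from_sister_age(sister_age)
  chi_r <- round(chi, 2)
  lam <- splitting_rate_from_speciation(speciation_rate, chi)
  lam_r <- round(splitting_rate_from_speciation(speciation_rate, chi_r), 2)
  mu <- extirpation_rate_from_extinction(extinction_rate, lam, chi, horizon)
  mu_r <- round(
    extirpation_rate_from_extinction(extinction_rate, lam_r, chi_r, horizon),
    1)
  data.frame(conversion_rate = chi, splitting_rate = lam,
             extirpation_rate = mu,
             conversion_rate_rounded = chi_r,
             splitting_rate_rounded = lam_r,
             extirpation_rate_rounded = mu_r)
}
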