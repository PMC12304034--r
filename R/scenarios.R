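# Bundled simulation scenarios.
#
# The generative parameters below are the reference thermoregulatory
# estimates for a cold-climate population of the lesser long-eared bat
# (Nyctophilus geoffroyi): per-sex inflection points and post-inflection
# slopes for whole-animal evaporative water loss (waEWL, g h^-1),
# whole-animal resting metabolic rate (waRMR, W) and subcutaneous
# temperature (Tsub, degC), baseline (below-inflection) levels at the
# reference minima, sample sizes of 13 females / 10 males, and heat
# tolerance limits of 44 degC (females) / 42 degC (males). They define the
# reference conditions for parameter-recovery simulations.

#' Reference generative parameters per response and sex
#'
#' @return nested list: `params[[response]][[sex]]` with `n`, `psi`
#'   (breakpoint, degC; `NA` for the linear female Tsub response),
#'   `slope_below`, `slope_above` (response units per degC), `intercept`,
#'   `max_ta`, plus per-response `random_intercept_sd` and `residual_sd`.
#' @seealso [study_sim_config()]
#' @export
study_params <- function() {
  list(
    waewl = list(
      female = list(n = 13L, psi = 37.7, slope_below = 0, slope_above = 0.054,
                    intercept = 0.05, max_ta = 44),
      male = list(n = 10L, psi = 33.1, slope_below = 0, slope_above = 0.023,
                  intercept = 0.04, max_ta = 42),
      random_intercept_sd = 0.02, residual_sd = 0.02, units = "g h^-1"
    ),
    warmr = list(
      # female thermoneutral floor spans the whole below-inflection range;
      # the male inflection sits at the protocol floor, so below it the
      # response rises as Ta falls (thermogenesis below thermoneutrality)
      # with the allometric minimum-conductance slope of a ~7-g bat
      # (~14 mW per degC)
      female = list(n = 13L, psi = 34.5, slope_below = 0, slope_above = 0.010,
                    intercept = 0.08, max_ta = 44),
      male = list(n = 10L, psi = 28.2, slope_below = -0.014,
                  slope_above = 0.007, intercept = 0.06 + 0.014 * 28.2,
                  max_ta = 42),
      random_intercept_sd = 0.01, residual_sd = 0.01, units = "W"
    ),
    tsub = list(
      # females show no inflection: linear rise of Tsub with Ta
      female = list(n = 13L, psi = NA_real_, slope_below = 0.61,
                    slope_above = 0.61, intercept = 33.4 - 0.61 * 28,
                    max_ta = 44),
      male = list(n = 10L, psi = 32.1, slope_below = 0, slope_above = 0.75,
                  intercept = 34.6, max_ta = 42),
      random_intercept_sd = 0.3, residual_sd = 0.3, units = "degC"
    )
  )
}

#' Simulation config for one reference response and sex
#'
#' Builds the [resp_sim_config()] whose generating values are the reference
#' estimates of [study_params()]: the stepped-protocol setpoints (28, 32,
#' 36, 40 degC then 2-degC steps) truncated at the sex's heat tolerance
#' limit, the sex's sample size, breakpoint and slopes, and that sex's
#' body-mass distribution (8.9 +/- 1.0 g females, 7.3 +/- 0.9 g males).
#' For the linear female Tsub response the config has equal slopes and a
#' nominal mid-range `psi` (the generated data contain no break).
#'
#' @param response `"waewl"`, `"warmr"` or `"tsub"`.
#' @param sex `"female"` or `"male"`.
#' @param seed integer seed.
#' @param termination `"limit"` (every individual reaches the sex's heat
#'   tolerance limit; the design of the parameter-recovery simulations) or
#'   `"observed"` (the reference termination distribution: 3 of 13 females
#'   to 44 degC with the rest to 42, 5 of 10 males to 42 degC with the rest
#'   to 40).
#' @return a [resp_sim_config()] with one group named after `sex`.
#' @examples
#' cfg <- study_sim_config("waewl", "female", seed = 1)
#' sim <- gen_respirometry(cfg)
#' head(sim$points)
#' @export
study_sim_config <- function(response = c("waewl", "warmr", "tsub"),
                             sex = c("female", "male"), seed = 1L,
                             termination = c("limit", "observed")) {
  response <- match.arg(response)
  sex <- match.arg(sex)
  termination <- match.arg(termination)
  p <- study_params()[[response]]
  g <- p[[sex]]
  mass <- if (sex == "female") c(8.9, 1.0) else c(7.3, 0.9)
  psi <- g$psi
  linear <- is.na(psi) || isTRUE(all.equal(g$slope_below, g$slope_above))
  if (is.na(psi)) psi <- (28 + g$max_ta) / 2
  n <- stats::setNames(g$n, sex)
  max_ta <- if (termination == "limit") g$max_ta else {
    lims <- if (sex == "female") c(rep(44, 3), rep(42, 10)) else
      c(rep(42, 5), rep(40, 5))
    stats::setNames(list(lims), sex)
  }
  cfg <- resp_sim_config(
    n = n,
    setpoints = c(28, 32, 36, 40, 42, 44),
    psi = stats::setNames(psi, sex),
    slope_below = g$slope_below,
    slope_above = g$slope_above,
    intercept = g$intercept,
    random_intercept_sd = p$random_intercept_sd,
    residual_sd = p$residual_sd,
    max_ta = max_ta,
    mass_mean = mass[1], mass_sd = mass[2],
    response = response,
    seed = seed
  )
  attr(cfg, "linear") <- linear
  cfg
}
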