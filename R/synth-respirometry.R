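# Synthetic per-setpoint physiological responses with known ground truth.
#
# Generates the statistical structure the segmented mixed model is fitted
# to: for each individual, one response value per air-temperature setpoint
# up to that individual's heat tolerance limit, following a piecewise-linear
# response with a random intercept per individual.

#' Configuration for the respirometry-response generator
#'
#' Each parameter may be a single value (shared by all groups) or a named
#' vector with one entry per group. The generative model for individual i of
#' a group at setpoint Ta is
#' `intercept + b_i + slope_below * Ta + (slope_above - slope_below) * max(0, Ta - psi) + eps`,
#' with `b_i ~ N(0, random_intercept_sd^2)` and
#' `eps ~ N(0, residual_sd^2)`. Individuals only contribute setpoints up to
#' their heat tolerance limit `max_ta`.
#'
#' @param n named integer vector: individuals per group (>= 2), e.g.
#'   `c(female = 13, male = 10)`.
#' @param setpoints degC, the stepped exposure protocol (default 28, 32, 36,
#'   40 degC then 2-degC steps to 44).
#' @param psi true breakpoint (degC) per group; a warning is issued if it
#'   lies outside the group's realized setpoint range (non-identifiable).
#' @param slope_below,slope_above response units per degC.
#' @param intercept response value extrapolated to Ta = 0 under the
#'   below-breakpoint slope.
#' @param random_intercept_sd,residual_sd response units.
#' @param max_ta degC, heat tolerance limit: a single value or named vector
#'   (one limit per group), or a named list of per-individual limit vectors
#'   (length `n[g]` for group g) when individuals within a group terminate
#'   at different setpoints. Individuals contribute setpoints `<= max_ta`.
#' @param ta_jitter degC, SD of the realized chamber temperature around
#'   each setpoint (default 0.5, a manually controlled chamber). The
#'   response is generated -- and regressed -- against the realized
#'   temperature, as in a real trial; continuous spread around the
#'   setpoints is what lets a breakpoint close to a setpoint be located
#'   between steps.
#' @param mass_mean,mass_sd g, body-mass distribution per group.
#' @param response name of the response column in the output (default
#'   `"value"`).
#' @param seed integer; expanded into per-individual streams (see
#'   [gen_respirometry()]).
#' @return object of class `resp_sim_config`.
#' @export
resp_sim_config <- function(n,
                            setpoints = c(28, 32, 36, 40, 42, 44),
                            psi,
                            slope_below = 0,
                            slope_above,
                            intercept,
                            random_intercept_sd = 0,
                            residual_sd = 0,
                            max_ta = max(setpoints),
                            ta_jitter = 0.5,
                            mass_mean = 8, mass_sd = 1,
                            response = "value",
                            seed = 1L) {
  if (is.null(names(n)) || any(!nzchar(names(n))))
    stopf("`n` must be a named vector of group sizes")
  if (any(n < 2)) stopf("need at least 2 individuals per group")
  groups <- names(n)
  per_group <- function(x, what) {
    if (length(x) == 1 && is.null(names(x))) {
      stats::setNames(rep(x, length(groups)), groups)
    } else {
      if (!all(groups %in% names(x)))
        stopf("`%s` must name every group (%s)", what,
              paste(groups, collapse = ", "))
      x[groups]
    }
  }
  if (is.list(max_ta)) {
    if (!all(groups %in% names(max_ta)))
      stopf("`max_ta` list must name every group")
    if (!all(vapply(max_ta, length, integer(1))[groups] == n[groups]))
      stopf("per-individual `max_ta` vectors must have length n per group")
    max_ta_ind <- max_ta[groups]
    max_ta <- vapply(max_ta_ind, max, numeric(1))
  } else max_ta_ind <- NULL
  cfg <- list(
    n = n, groups = groups, setpoints = sort(setpoints),
    psi = per_group(psi, "psi"),
    slope_below = per_group(slope_below, "slope_below"),
    slope_above = per_group(slope_above, "slope_above"),
    intercept = per_group(intercept, "intercept"),
    random_intercept_sd = per_group(random_intercept_sd, "random_intercept_sd"),
    residual_sd = per_group(residual_sd, "residual_sd"),
    max_ta = per_group(max_ta, "max_ta"),
    max_ta_ind = max_ta_ind,
    ta_jitter = ta_jitter,
    mass_mean = per_group(mass_mean, "mass_mean"),
    mass_sd = per_group(mass_sd, "mass_sd"),
    response = response, seed = as.integer(seed)
  )
  if (any(!is.finite(c(cfg$slope_below, cfg$slope_above))))
    stopf("slopes must be finite")
  for (g in groups) {
    sp <- cfg$setpoints[cfg$setpoints <= cfg$max_ta[g]]
    if (cfg$psi[g] <= min(sp) || cfg$psi[g] >= max(sp))
      warnf("group '%s': breakpoint %.1f outside its setpoint range [%g, %g]; not identifiable",
            g, cfg$psi[g], min(sp), max(sp))
  }
  structure(cfg, class = "resp_sim_config")
}

#' Generate piecewise-linear mixed responses
#'
#' Draws the per-setpoint response table described in [resp_sim_config()].
#' The single scenario seed is expanded deterministically into one RNG
#' stream per individual (individual k overall uses
#' `set.seed((seed * 2654435761 + 7919 k) mod (2^31 - 1))`), so adding or
#' reordering groups leaves the draws of unchanged individuals intact.
#'
#' @param config a [resp_sim_config()].
#' @return list with `points` (data.frame: `id`, `group`, `mass_g`, `ta`,
#'   and the response column) and `truth` (the generating parameters per
#'   group plus the realized per-individual random intercepts).
#' @examples
#' cfg <- resp_sim_config(n = c(female = 4, male = 4), psi = 36,
#'                        slope_above = 0.05, intercept = 0.05,
#'                        residual_sd = 0.01, seed = 42)
#' gen_respirometry(cfg)$points[1:3, ]
#' @export
gen_respirometry <- function(config) {
  stopifnot(inherits(config, "resp_sim_config"))
  cfg <- config
  rows <- list()
  b_tab <- list()
  k <- 0L
  for (g in cfg$groups) {
    for (i in seq_len(cfg$n[g])) {
      lim <- if (!is.null(cfg$max_ta_ind)) cfg$max_ta_ind[[g]][i] else cfg$max_ta[g]
      sp <- cfg$setpoints[cfg$setpoints <= lim]
      k <- k + 1L
      set.seed(split_seed(cfg$seed, k))
      b_i <- stats::rnorm(1, 0, cfg$random_intercept_sd[g])
      mass <- stats::rnorm(1, cfg$mass_mean[g], cfg$mass_sd[g])
      ta_real <- sp + stats::rnorm(length(sp), 0, cfg$ta_jitter)
      eps <- stats::rnorm(length(sp), 0, cfg$residual_sd[g])
      mu <- cfg$intercept[g] + b_i + cfg$slope_below[g] * ta_real +
        (cfg$slope_above[g] - cfg$slope_below[g]) * pmax(0, ta_real - cfg$psi[g])
      id <- sprintf("%s%02d", substr(g, 1, 1), i)
      rows[[k]] <- data.frame(id = id, group = g, mass_g = mass,
                              ta_set = sp, ta = ta_real, value = mu + eps)
      b_tab[[k]] <- data.frame(id = id, group = g, b = b_i, mass_g = mass,
                               max_ta = lim)
    }
  }
  points <- do.call(rbind, rows)
  names(points)[names(points) == "value"] <- cfg$response
  rownames(points) <- NULL
  list(points = points,
       truth = list(
         psi = cfg$psi, slope_below = cfg$slope_below,
         slope_above = cfg$slope_above, intercept = cfg$intercept,
         random_intercept_sd = cfg$random_intercept_sd,
         residual_sd = cfg$residual_sd, max_ta = cfg$max_ta,
         individuals = do.call(rbind, b_tab)))
}
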