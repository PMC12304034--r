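# Flow-through respirometry reduction.
#
# Raw traces are 5-s samples of fractional CO2 and H2O on a baseline
# (incurrent) line and a chamber (excurrent) line, plus flow rate, chamber
# air temperature and subcutaneous temperature, recorded over a stepped
# series of air-temperature setpoints. Reduction corrects analyser drift and
# lag, picks the lowest stable 5-min window at each setpoint, applies the
# mass-balance equations for CO2 production and evaporative water loss, and
# converts to whole-animal metabolic rate (W), evaporative water loss
# (g h^-1), evaporative heat loss (W) and the EHL/MHP ratio.

#' Energy and vapour constants for respirometry conversions
#'
#' Bundle of the physical constants used to convert gas-exchange rates to
#' heat equivalents: the assumed respiratory exchange ratio (RER) of a
#' post-absorptive animal, the joule equivalent of CO2 at that RER, the
#' density of water vapour and the latent heat of vapourisation of water at
#' high chamber temperature.
#'
#' @param rer respiratory exchange ratio, unitless (default 0.71,
#'   post-absorptive fat metabolism).
#' @param joules_per_ml_co2 J per ml CO2 at `rer` (default 27.8).
#' @param vapour_density mg H2O per ml vapour (default 0.803).
#' @param latent_heat J per mg H2O evaporated (default 2.406, at 40 degC).
#' @return object of class `energy_constants`.
#' @examples
#' energy_constants()
#' energy_constants(rer = 0.75, joules_per_ml_co2 = 27.54)
#' @export
energy_constants <- function(rer = 0.71, joules_per_ml_co2 = 27.8,
                             vapour_density = 0.803, latent_heat = 2.406) {
  vals <- c(rer = rer, joules_per_ml_co2 = joules_per_ml_co2,
            vapour_density = vapour_density, latent_heat = latent_heat)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stopf("all energy constants must be positive and finite")
  structure(as.list(vals), class = "energy_constants")
}

#' @export
print.energy_constants <- function(x, ...) {
  cat("Energy constants:\n")
  cat(sprintf("  RER                 %.2f\n", x$rer))
  cat(sprintf("  J per ml CO2        %.2f\n", x$joules_per_ml_co2))
  cat(sprintf("  vapour density      %.3f mg ml^-1\n", x$vapour_density))
  cat(sprintf("  latent heat         %.3f J mg^-1\n", x$latent_heat))
  invisible(x)
}

#' Rate of CO2 production from the mass balance
#'
#' VCO2 = excurrent flow x fractional excurrent CO2 - incurrent flow x
#' fractional incurrent CO2. Small negative results (baseline mis-set) are
#' returned but flagged with a warning beyond `-tolerance`.
#'
#' @param excurrent_flow,incurrent_flow flow rates, ml min^-1.
#' @param frac_ex_co2,frac_in_co2 fractional CO2 concentrations (0--0.05).
#' @param tolerance negative results beyond `-tolerance` trigger a warning.
#' @return VCO2 in ml min^-1.
#' @examples
#' compute_vco2(1000, 0.002, 1000, 0) # 2 ml min^-1
#' @export
compute_vco2 <- function(excurrent_flow, frac_ex_co2, incurrent_flow,
                         frac_in_co2, tolerance = 1e-6) {
  check_gas_inputs(excurrent_flow, frac_ex_co2, incurrent_flow, frac_in_co2)
  out <- excurrent_flow * frac_ex_co2 - incurrent_flow * frac_in_co2
  if (any(out < -tolerance))
    warnf("negative VCO2 (min %.3g ml min^-1): baseline may be mis-set", min(out))
  out
}

#' Evaporative water loss from the mass balance
#'
#' Water-vapour volume rate (excurrent flow x fractional excurrent H2O -
#' incurrent flow x fractional incurrent H2O) converted to mass using the
#' vapour density constant.
#'
#' @inheritParams compute_vco2
#' @param frac_ex_h2o,frac_in_h2o fractional water-vapour concentrations.
#' @param constants an [energy_constants()] bundle.
#' @param units `"mg_min"` (default) or `"g_h"`.
#' @return EWL in the requested units.
#' @examples
#' compute_ewl(1000, 0.001, 1000, 0)                  # 0.803 mg min^-1
#' compute_ewl(1000, 0.001, 1000, 0, units = "g_h")   # 0.04818 g h^-1
#' @export
compute_ewl <- function(excurrent_flow, frac_ex_h2o, incurrent_flow,
                        frac_in_h2o, constants = energy_constants(),
                        units = c("mg_min", "g_h"), tolerance = 1e-6) {
  units <- match.arg(units)
  check_gas_inputs(excurrent_flow, frac_ex_h2o, incurrent_flow, frac_in_h2o,
                   frac_max = 0.1)
  vol <- excurrent_flow * frac_ex_h2o - incurrent_flow * frac_in_h2o
  if (any(vol < -tolerance))
    warnf("negative EWL (min %.3g ml min^-1 vapour): baseline may be mis-set", min(vol))
  mg_min <- vol * constants$vapour_density
  if (units == "mg_min") mg_min else mg_min * 60 / 1000
}

#' @keywords internal
#' @noRd
check_gas_inputs <- function(f_ex, fr_ex, f_in, fr_in, frac_max = 0.05) {
  if (any(f_ex <= 0) || any(f_in <= 0)) stopf("flow rates must be positive")
  if (any(fr_ex < 0) || any(fr_in < 0) || any(fr_ex > frac_max) || any(fr_in > frac_max))
    stopf("fractional concentrations must lie in [0, %.2f]", frac_max)
  invisible(TRUE)
}

#' Convert CO2 production to metabolic rate
#'
#' Multiplies VCO2 (ml min^-1) by the joule equivalent of CO2 and rescales
#' minutes to seconds, giving whole-animal resting metabolic rate in watts.
#'
#' @param vco2 ml CO2 min^-1 (>= 0).
#' @param constants an [energy_constants()] bundle.
#' @return metabolic rate in W.
#' @examples
#' vco2_to_watts(1) # 27.8 / 60 = 0.4633 W
#' @export
vco2_to_watts <- function(vco2, constants = energy_constants()) {
  if (any(vco2 < 0)) stopf("`vco2` must be non-negative")
  vco2 * constants$joules_per_ml_co2 / 60
}

#' Evaporative heat loss and the EHL/MHP ratio
#'
#' Converts an evaporative water-loss rate to evaporative heat loss using
#' the latent heat of vapourisation, and forms the ratio of evaporative heat
#' loss to metabolic heat production. Values above 1 mean the animal can
#' dissipate more heat evaporatively than it generates. The ratio is
#' computed per individual per setpoint, before any averaging.
#'
#' @param waewl whole-animal evaporative water loss, g h^-1.
#' @param warmr whole-animal resting metabolic rate, W. Zero gives an
#'   undefined ratio (`NA`) with a warning.
#' @param constants an [energy_constants()] bundle.
#' @return data.frame with columns `ehl_w` and `ehl_mhp`.
#' @examples
#' ehl_and_ratio(1, 0.5)        # EHL 0.6683 W, ratio 1.337
#' ehl_and_ratio(0.38, 0.15)    # Ratio ~1.69
#' @export
ehl_and_ratio <- function(waewl, warmr, constants = energy_constants()) {
  if (any(waewl < 0)) stopf("`waewl` must be non-negative")
  ehl <- waewl * 1000 * constants$latent_heat / 3600
  ratio <- ifelse(warmr > 0, ehl / warmr, ifelse(ehl == 0, 0, NA_real_))
  if (anyNA(ratio))
    warnf("EHL/MHP undefined where metabolic rate is zero")
  data.frame(ehl_w = ehl, ehl_mhp = ratio)
}

#' Sensitivity of metabolic rate to the assumed respiratory exchange ratio
#'
#' Recomputes whole-animal metabolic rate from VCO2 under alternative RER /
#' joule-equivalent scenarios and reports, for each alternative, the root
#' mean squared difference (same units, W) and the R-squared of the
#' alternative against the default conversion.
#'
#' @param physio data.frame with a numeric `vco2` column (ml min^-1); rows
#'   with missing `vco2` are skipped with a message.
#' @param alternatives named numeric vector of joule equivalents (J ml^-1
#'   CO2), e.g. `c(rer_0.75 = 27.54, rer_0.83 = 26.57)`.
#' @param constants the default [energy_constants()].
#' @return data.frame with one row per scenario: `scenario`,
#'   `joules_per_ml_co2`, `rmsd_w`, `r_squared`.
#' @export
rer_scenario_comparison <- function(physio, alternatives,
                                    constants = energy_constants()) {
  if (!is.data.frame(physio) || !"vco2" %in% names(physio))
    stopf("`physio` must be a data.frame with a `vco2` column")
  if (is.null(names(alternatives)) || any(!nzchar(names(alternatives))))
    stopf("`alternatives` must be a named numeric vector")
  keep <- is.finite(physio$vco2)
  if (sum(!keep) > 0)
    message(sprintf("skipping %d rows with missing vco2", sum(!keep)))
  vco2 <- physio$vco2[keep]
  if (length(vco2) < 2) stopf("need at least 2 rows with vco2")
  ref <- vco2 * constants$joules_per_ml_co2 / 60
  out <- lapply(seq_along(alternatives), function(i) {
    alt <- vco2 * alternatives[i] / 60
    ss_res <- sum((alt - ref)^2)
    ss_tot <- sum((ref - mean(ref))^2)
    data.frame(scenario = names(alternatives)[i],
               joules_per_ml_co2 = unname(alternatives[i]),
               rmsd_w = sqrt(mean((alt - ref)^2)),
               r_squared = if (ss_tot > 0) {
                 stats::cor(alt, ref)^2
               } else NA_real_)
  })
  do.call(rbind, out)
}
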