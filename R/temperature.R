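# Temperature correction of mass-specific metabolic rate.

BOLTZMANN_K <- 8.6173e-5 # eV/K

#' Q10-style temperature correction of mass-specific metabolic rate
#'
#' Rescales a mass-specific metabolic rate `q` measured at temperature
#' `t_measured` (deg C) to a target temperature (default 25 deg C),
#' assuming the rate doubles per 10 deg C:
#' `q_X = q * 1e-3 * 2^((X - T)/10)`.
#'
#' The constant `1e-3` factor is retained as part of the published
#' transformation (a unit rescaling). Because every downstream statistic in
#' this package is rank-based and the factor is a common positive multiplier,
#' it cannot affect any correlation.
#'
#' @param q Mass-specific metabolic rate (W/g, positive; `NA` propagates).
#' @param t_measured Measurement temperature in deg C.
#' @param target Target temperature in deg C (default 25; the low-temperature
#'   variant used for prokaryote-rich panels is `target = 10`).
#' @return Corrected rate vector; `NA` where `q` or `t_measured` is `NA`.
#' @export
q10_style_correct <- function(q, t_measured, target = 25) {
  assert_numeric_finite(target, "target")
  assert_numeric_finite(t_measured, "t_measured", allow_na = TRUE)
  assert_numeric_finite(q, "q", allow_na = TRUE)
  if (any(!is.na(q) & q <= 0)) {
    abort("`q` must be positive where present.")
  }
  q * 1e-3 * 2^((target - t_measured) / 10)
}

#' Boltzmann-Arrhenius temperature correction
#'
#' Rescales a mass-specific metabolic rate measured at `t_measured` (deg C)
#' to `target` (deg C) using the Boltzmann-Arrhenius factor
#' `q_X = q * exp(-E/k * (1/(X + 273.15) - 1/(T + 273.15)))`,
#' with `k = 8.6173e-5` eV/K and `E` the average activation energy (eV) of
#' enzyme-catalysed reactions. The default `E = 0.65` eV lies in the
#' admissible range 0.4-0.8 eV; values outside it require
#' `allow_any_energy = TRUE`.
#'
#' @inheritParams q10_style_correct
#' @param activation_energy Activation energy E in eV (default 0.65).
#' @param allow_any_energy Permit E outside `[0.4, 0.8]` (e.g. 0 for a
#'   degenerate no-op correction).
#' @return Corrected rate vector in W/g.
#' @export
boltzmann_correct <- function(q, t_measured, target = 25,
                              activation_energy = 0.65,
                              allow_any_energy = FALSE) {
  assert_numeric_finite(target, "target")
  assert_numeric_finite(activation_energy, "activation_energy")
  assert_numeric_finite(t_measured, "t_measured", allow_na = TRUE)
  assert_numeric_finite(q, "q", allow_na = TRUE)
  if (!allow_any_energy &&
      (activation_energy < 0.4 || activation_energy > 0.8)) {
    abort("`activation_energy` outside [0.4, 0.8] eV; set `allow_any_energy = TRUE` to override.")
  }
  if (any(target <= -273.15) || any(!is.na(t_measured) & t_measured <= -273.15)) {
    abort("Temperatures must be above absolute zero (-273.15 deg C).")
  }
  q * exp(-activation_energy / BOLTZMANN_K *
            (1 / (target + 273.15) - 1 / (t_measured + 273.15)))
}

#' Filter organisms eligible for temperature-corrected analyses
#'
#' Drops ectothermic vertebrates (their body temperature is not meaningfully
#' rescaled to a common endotherm-like reference) and any record lacking a
#' measurement temperature. The number of records dropped for each reason
#' is reported via a message.
#'
#' @param data Trait tibble with `taxon_group` and `temp_C` columns.
#' @return The filtered tibble.
#' @export
filter_temperature_eligible <- function(data) {
  if (!all(c("taxon_group", "temp_C") %in% names(data))) {
    abort("`data` must have columns taxon_group and temp_C.")
  }
  is_ecto <- data$taxon_group == "ectothermic_vertebrate"
  no_temp <- !is_ecto & is.na(data$temp_C)
  inform(sprintf(
    "Temperature eligibility: dropped %d ectothermic vertebrate(s) and %d record(s) without temperature; %d retained.",
    sum(is_ecto), sum(no_temp), sum(!is_ecto & !no_temp)
  ))
  data[!is_ecto & !no_temp, , drop = FALSE]
}
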