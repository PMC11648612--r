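#' Ultrasound burst-pulse sequence
#'
#' Parametric description of a rectangular burst-pulse train: a carrier tone
#' gated at the pulse repetition frequency (PRF) with a fixed duty cycle, for
#' a total train duration, delivered at a given spatial-peak temporal-average
#' intensity (I_SPTA) from a transducer of known radiating area.
#'
#' @param carrier_hz carrier frequency in Hz (e.g. 1e6 for a 1-MHz carrier).
#' @param prf_hz pulse repetition frequency in Hz.
#' @param duty duty cycle, fraction of each PRF period the carrier is on,
#'   in (0, 1].
#' @param duration_s train duration in seconds. `duration_s * prf_hz` must be
#'   a whole number of bursts (tolerance 1e-9).
#' @param ispta_w_cm2 spatial-peak temporal-average intensity in W/cm^2,
#'   or `NA` if unknown.
#' @param area_cm2 radiating area of the transducer face in cm^2, or `NA`.
#'
#' @return An object of class `pulse_sequence`.
#' @examples
#' # the in vitro train: 1 MHz carrier, 50 bursts at 100 Hz PRF, 50% duty
#' ps <- pulse_sequence(1e6, 100, 0.5, 0.5, ispta_w_cm2 = 0.19,
#'                      area_cm2 = 0.28)
#' burst_count(ps)
#' @export
pulse_sequence <- function(carrier_hz, prf_hz, duty, duration_s,
                           ispta_w_cm2 = NA_real_, area_cm2 = NA_real_) {
  if (!is_number(carrier_hz) || carrier_hz <= 0)
    stopf("carrier_hz must be a positive number")
  if (!is_number(prf_hz) || prf_hz <= 0)
    stopf("prf_hz must be a positive number")
  if (!is_number(duty) || duty <= 0 || duty > 1)
    stopf("duty cycle must lie in (0, 1], got %g", duty)
  if (!is_number(duration_s) || duration_s <= 0)
    stopf("duration_s must be a positive number")
  if (carrier_hz < prf_hz)
    stopf("carrier frequency (%g Hz) must be >= PRF (%g Hz)",
          carrier_hz, prf_hz)
  n <- duration_s * prf_hz
  if (abs(n - round(n)) > 1e-9 || round(n) < 1)
    stopf("duration * PRF = %g is not a positive whole number of bursts", n)
  if (!is.na(ispta_w_cm2) && ispta_w_cm2 < 0)
    stopf("ispta_w_cm2 must be >= 0")
  if (!is.na(area_cm2) && area_cm2 <= 0)
    stopf("area_cm2 must be > 0")
  structure(
    list(carrier_hz = carrier_hz, prf_hz = prf_hz, duty = duty,
         duration_s = duration_s, ispta_w_cm2 = ispta_w_cm2,
         area_cm2 = area_cm2),
    class = "pulse_sequence"
  )
}

#' @export
print.pulse_sequence <- function(x, ...) {
  cat(sprintf(
    "Ultrasound burst-pulse sequence\n  carrier: %g MHz, PRF: %g Hz, duty: %g%%\n",
    x$carrier_hz / 1e6, x$prf_hz, 100 * x$duty))
  cat(sprintf("  duration: %g s (%d bursts)\n", x$duration_s, burst_count(x)))
  if (!is.na(x$ispta_w_cm2))
    cat(sprintf("  I_SPTA: %g W/cm2 (I_SPPA %g W/cm2)\n",
                x$ispta_w_cm2, isppa_from_ispta(x$ispta_w_cm2, x$duty)))
  if (!is.na(x$area_cm2))
    cat(sprintf("  radiating area: %g cm2\n", x$area_cm2))
  invisible(x)
}

#' Thermal context for the adiabatic heating bound
#'
#' Properties of the absorbing bath used to convert delivered acoustic energy
#' into a worst-case temperature rise. Defaults are the physical constants of
#' water (density 1 g/mL, specific heat 4.184 J/g/degC); the bound assumes
#' total absorption with no heat loss.
#'
#' @param bath_volume_ml bath volume in mL.
#' @param density_g_ml density in g/mL.
#' @param specific_heat specific heat capacity in J/g/degC.
#' @return An object of class `thermal_context`.
#' @export
thermal_context <- function(bath_volume_ml = 1, density_g_ml = 1,
                            specific_heat = 4.184) {
  for (v in c(bath_volume_ml, density_g_ml, specific_heat))
    if (!is_number(v) || v <= 0)
      stopf("all thermal_context fields must be strictly positive")
  structure(list(bath_volume_ml = bath_volume_ml, density_g_ml = density_g_ml,
                 specific_heat = specific_heat),
            class = "thermal_context")
}

#' Number of burst pulses in a train
#'
#' @param seq a [pulse_sequence()].
#' @return Integer burst count, `round(duration_s * prf_hz)`.
#' @export
burst_count <- function(seq) {
  stopifnot(inherits(seq, "pulse_sequence"))
  as.integer(round(seq$duration_s * seq$prf_hz))
}

#' Pulse-average intensity from temporal-average intensity
#'
#' For a rectangular burst train the carrier is on for a `duty_cycle`
#' fraction of the time, so I_SPPA = I_SPTA / duty_cycle.
#'
#' @param ispta_w_cm2 temporal-average intensity, W/cm^2, >= 0.
#' @param duty_cycle duty cycle in (0, 1].
#' @return Pulse-average intensity in W/cm^2.
#' @examples
#' isppa_from_ispta(0.19, 0.5)  # 0.38
#' @export
isppa_from_ispta <- function(ispta_w_cm2, duty_cycle) {
  if (!is_number(duty_cycle) || duty_cycle <= 0 || duty_cycle > 1)
    stopf("duty_cycle must lie in (0, 1]")
  if (!is_number(ispta_w_cm2) || ispta_w_cm2 < 0)
    stopf("ispta_w_cm2 must be >= 0")
  ispta_w_cm2 / duty_cycle
}

#' Acoustic energy of one stimulus train
#'
#' Temporal-average intensity times radiating area times train duration.
#' The duty cycle is already folded into I_SPTA, so no further correction
#' is applied.
#'
#' @param seq a [pulse_sequence()] with `ispta_w_cm2` and `area_cm2` set.
#' @return Energy in joules.
#' @examples
#' ps <- pulse_sequence(1e6, 100, 0.5, 0.5, 0.19, 0.28)
#' stimulus_energy(ps)  # 0.0266 J
#' @export
stimulus_energy <- function(seq) {
  stopifnot(inherits(seq, "pulse_sequence"))
  if (is.na(seq$ispta_w_cm2))
    stopf("pulse sequence has no ispta_w_cm2; cannot compute energy")
  if (is.na(seq$area_cm2))
    stopf("pulse sequence has no radiating area; cannot compute energy")
  seq$ispta_w_cm2 * seq$area_cm2 * seq$duration_s
}

#' Adiabatic temperature-rise bound
#'
#' Upper bound on the bath temperature rise assuming the whole stimulus
#' energy is absorbed with no conduction or convection loss:
#' dT = E / (V * rho * c).
#'
#' @param energy_j energy in joules, >= 0.
#' @param ctx a [thermal_context()].
#' @return Temperature rise in degrees Celsius.
#' @examples
#' adiabatic_temp_rise(0.0266, thermal_context())  # ~0.0064 degC
#' @export
adiabatic_temp_rise <- function(energy_j, ctx = thermal_context()) {
  stopifnot(inherits(ctx, "thermal_context"))
  if (!is_number(energy_j) || energy_j < 0)
    stopf("energy_j must be >= 0")
  energy_j / (ctx$bath_volume_ml * ctx$density_g_ml * ctx$specific_heat)
}

#' Idealized on/off envelope of a burst train
#'
#' Rectangular (unsmoothed) gating envelope sampled at `sample_rate_hz`:
#' within each PRF period the first `duty` fraction is on (1), the rest
#' off (0).
#'
#' @param seq a [pulse_sequence()].
#' @param sample_rate_hz sampling rate in Hz; must be at least `2 * prf_hz`.
#' @return Numeric 0/1 vector of length `round(duration_s * sample_rate_hz)`.
#' @export
envelope_waveform <- function(seq, sample_rate_hz) {
  stopifnot(inherits(seq, "pulse_sequence"))
  if (!is_number(sample_rate_hz) || sample_rate_hz < 2 * seq$prf_hz)
    stopf("sample_rate_hz must be >= 2 * PRF = %g Hz", 2 * seq$prf_hz)
  n <- round(seq$duration_s * sample_rate_hz)
  ratio <- sample_rate_hz / seq$prf_hz  # samples per PRF period
  if (abs(ratio - round(ratio)) < 1e-9) {
    # exact integer arithmetic avoids floating-point phase drift
    phase <- ((seq_len(n) - 1) %% round(ratio)) / round(ratio)
  } else {
    t <- (seq_len(n) - 1) / sample_rate_hz
    phase <- (t * seq$prf_hz) %% 1  # position within the PRF period
  }
  as.numeric(phase < seq$duty)
}

#' Dosimetry summary of a pulse sequence
#'
#' Burst count, I_SPPA, per-stimulus energy and the adiabatic temperature
#' rise bound, as a one-row data frame. Values are exact; round only for
#' presentation.
#'
#' @param seq a [pulse_sequence()].
#' @param ctx a [thermal_context()] for the heating bound.
#' @return data.frame with columns `burst_count`, `isppa_w_cm2`, `energy_j`,
#'   `temp_rise_c` (the last two `NA` when intensity or area are unset).
#' @export
dose_summary <- function(seq, ctx = thermal_context()) {
  e <- if (!is.na(seq$ispta_w_cm2) && !is.na(seq$area_cm2))
    stimulus_energy(seq) else NA_real_
  data.frame(
    burst_count = burst_count(seq),
    isppa_w_cm2 = if (is.na(seq$ispta_w_cm2)) NA_real_
                  else isppa_from_ispta(seq$ispta_w_cm2, seq$duty),
    energy_j = e,
    temp_rise_c = if (is.na(e)) NA_real_ else adiabatic_temp_rise(e, ctx)
  )
}
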