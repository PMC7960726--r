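#' Configuration for the synthetic pump-probe shot generator
#'
#' Collects every parameter of the synthetic experiment emulated by
#' [generate_shot_series()]. Defaults reproduce the study conditions of the
#' two-pulse microjet measurement the package analyses: a ~5 um, ~50 m/s
#' gas-dynamic-virtual-nozzle jet probed 122.5 ns after the pump with a 5 um
#' upstream offset, a weak pump (mean 0.03 mJ) strongly anti-correlated with
#' a ~0.9 mJ probe, a 19% base hit probability, and a resolution penalty of
#' the pump (damage) opposed by a signal gain of the probe.
#'
#' @param n_shots number of X-ray events to simulate.
#' @param mode_fraction_pump_probe fraction of shots taken in pump-probe
#'   mode; the rest are single-pulse (probe only) reference shots.
#' @param run_size shots per run; runs model contiguous acquisition blocks.
#' @param jet_speed jet speed, m/s.
#' @param jet_diameter jet diameter, um.
#' @param pump_probe_delay pump-probe delay, ns.
#' @param beam_offset probe offset upstream of the pump, um.
#' @param pump_energy_mean,pump_energy_sd pump pulse energy law, mJ
#'   (bivariate normal with the probe, truncated at zero by redrawing).
#' @param probe_energy_mean,probe_energy_sd probe pulse energy law, mJ.
#' @param energy_anticorrelation target Pearson correlation between pump and
#'   probe energies, in [-1, 0].
#' @param hit_probability_base probability that a shot hits a crystal when
#'   undamaged.
#' @param hit_damage_coefficient per-mJ exponential suppression of the hit
#'   probability by the pump (shock-damaged crystals fall below the 10-peak
#'   hit definition).
#' @param index_probability probability that a hit can be indexed.
#' @param damage_coefficient resolution penalty per unit pump energy, A/mJ.
#' @param signal_coefficient resolution gain per unit probe energy, A/mJ.
#' @param d_base,d_best baseline and best attainable per-image resolution,
#'   A: true d_min = max(d_best, d_base - signal*probe + damage*pump).
#' @param noise_trace_fraction fraction of shots whose diode traces carry
#'   high pre-pulse electronic noise.
#' @param leak_fraction fraction of pump-probe shots where pump photons leak
#'   through the masking foil (elevated masked-diode pump signal).
#' @param abnormal_jet_fraction fraction of shots with abnormal jet
#'   morphology (over-wide jet, upstream break-up, or a spurious upstream
#'   gap).
#' @param n_trace_samples,trace_dt_ns diode trace length and sampling step.
#' @param trace_noise_sd baseline diode noise SD, V.
#' @param pump_arrival_sample sample index of pump pulse arrival.
#' @param image_width_px,image_height_px jet snapshot dimensions; rows run
#'   downstream from the nozzle (top edge), 0-based pixel convention.
#' @param um_per_px image calibration, um per pixel.
#' @param pump_position_um pump interaction position along the jet axis, um
#'   from the top edge of the image.
#' @param gap_length_um length of an explosion gap in the jet, um.
#' @param wiggle_amplitude_px,wiggle_wavelength_px jet wiggle (crystal-laden
#'   jets are unstable); amplitude/wavelength are free parameters.
#' @param seed master seed; all stage sub-streams derive from it.
#' @return an object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(n_shots = 1000,
                              mode_fraction_pump_probe = 0.5,
                              run_size = 500,
                              jet_speed = 50,
                              jet_diameter = 5,
                              pump_probe_delay = 122.5,
                              beam_offset = 5,
                              pump_energy_mean = 0.03,
                              pump_energy_sd = 0.02,
                              probe_energy_mean = 0.9,
                              probe_energy_sd = 0.2,
                              energy_anticorrelation = -0.7,
                              hit_probability_base = 0.19,
                              hit_damage_coefficient = 12.7,
                              index_probability = 0.235,
                              damage_coefficient = 11.5,
                              signal_coefficient = 0.5,
                              d_base = 3.45,
                              d_best = 1.8,
                              noise_trace_fraction = 0.05,
                              leak_fraction = 0.05,
                              abnormal_jet_fraction = 0.05,
                              n_trace_samples = 256,
                              trace_dt_ns = 1,
                              trace_noise_sd = 0.01,
                              pump_arrival_sample = 100,
                              image_width_px = 96,
                              image_height_px = 240,
                              um_per_px = 0.5,
                              pump_position_um = 70,
                              gap_length_um = 3,
                              wiggle_amplitude_px = 1.5,
                              wiggle_wavelength_px = 40,
                              seed = 1) {
  cfg <- as.list(environment())
  for (f in c("mode_fraction_pump_probe", "hit_probability_base",
              "index_probability", "noise_trace_fraction", "leak_fraction",
              "abnormal_jet_fraction"))
    check_fraction(cfg[[f]], f)
  for (f in c("jet_speed", "jet_diameter", "pump_probe_delay",
              "probe_energy_mean", "um_per_px", "trace_dt_ns", "d_base",
              "d_best", "gap_length_um"))
    check_positive(cfg[[f]], f)
  for (f in c("beam_offset", "pump_energy_mean", "pump_energy_sd",
              "probe_energy_sd", "damage_coefficient", "signal_coefficient",
              "hit_damage_coefficient", "trace_noise_sd",
              "wiggle_amplitude_px"))
    check_positive(cfg[[f]], f, strict = FALSE)
  if (!is.numeric(cfg$energy_anticorrelation) ||
      length(cfg$energy_anticorrelation) != 1L ||
      !is.finite(cfg$energy_anticorrelation) ||
      cfg$energy_anticorrelation < -1 || cfg$energy_anticorrelation > 0)
    stop("'energy_anticorrelation' must be in [-1, 0]", call. = FALSE)
  if (cfg$n_shots < 1 || cfg$n_shots != round(cfg$n_shots))
    stop("'n_shots' must be a positive integer", call. = FALSE)
  if (cfg$d_best > cfg$d_base)
    stop("'d_best' must not exceed 'd_base'", call. = FALSE)
  if (!is.finite(cfg$seed)) stop("'seed' must be finite", call. = FALSE)
  class(cfg) <- "simulation_config"
  cfg
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("simulation_config: %d shots (%.0f%% pump-probe), seed %s\n",
              x$n_shots, 100 * x$mode_fraction_pump_probe,
              format(x$seed)))
  cat(sprintf("  jet %.3g um @ %.3g m/s; delay %.4g ns, offset %.3g um\n",
              x$jet_diameter, x$jet_speed, x$pump_probe_delay,
              x$beam_offset))
  cat(sprintf("  pump %.3g +/- %.3g mJ, probe %.3g +/- %.3g mJ, rho %.2f\n",
              x$pump_energy_mean, x$pump_energy_sd, x$probe_energy_mean,
              x$probe_energy_sd, x$energy_anticorrelation))
  invisible(x)
}
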