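# End-to-end orchestration: simulate -> jet features -> filters -> rates ->
# resolution statistics -> merging metrics -> structural comparison ->
# kinematics, with a serialisable configuration and a summary report.

#' Pipeline configuration
#'
#' Bundles the synthetic-experiment configuration with the analysis
#' parameters of every stage. Defaults equal the study conditions (see
#' [simulation_config()]).
#'
#' @param sim a [simulation_config()].
#' @param stages character subset of
#'   `c("jets", "traces", "stats", "structure")`; stages left out are
#'   skipped (filters then use only the remaining evidence).
#' @param snr_threshold per-image resolution SNR threshold.
#' @param n_energy_bins probe-energy bins for the resolution-vs-energy
#'   table.
#' @param n_resolution_bins resolution bins for merging metrics.
#' @param stats_d_min resolution limit of the synthetic reflection data.
#' @param stats_n_images images per synthetic reflection data set.
#' @param stats_b_factor Wilson B planted in the synthetic intensities.
#' @param stats_scale overall intensity scale of the synthetic data.
#' @param stats_noise_sd single-pulse observation noise level (noise SD is
#'   `stats_noise_sd * sqrt(I)` per observation).
#' @param damage_noise_factor multiplier on the reflection noise of the
#'   pump-probe set relative to the single-pulse set (lattice-order loss).
#' @param n_boot bootstrap ensemble size.
#' @param structure_amplitude,structure_compaction,structure_noise_sd,
#'   structure_n_images parameters of the synthetic structure pair.
#' @param leak_k pump-leakage threshold multiplier.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            stages = c("jets", "traces", "stats",
                                       "structure"),
                            snr_threshold = 4,
                            n_energy_bins = 5,
                            n_resolution_bins = 10,
                            stats_d_min = 3.0,
                            stats_n_images = 60,
                            stats_b_factor = 47.4,
                            stats_scale = 1e4,
                            stats_noise_sd = 30,
                            damage_noise_factor = 2.5,
                            n_boot = 100,
                            structure_amplitude = 0.11,
                            structure_compaction = 0.9995,
                            structure_noise_sd = 0.85,
                            structure_n_images = 50,
                            leak_k = 1.5) {
  stopifnot(inherits(sim, "simulation_config"))
  if (length(stages) > 0)
    stages <- match.arg(stages, c("jets", "traces", "stats", "structure"),
                        several.ok = TRUE)
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(cfg), tf, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tf))
}

#' Run the full analysis pipeline on synthetic data
#'
#' Generates a shot series, analyses jet snapshots for hits, applies the
#' diode-noise, pump-leakage and jet-morphology filters, computes hit and
#' indexing rates, per-image resolution statistics and probe-energy
#' binning, Table-style merging metrics for the single-pulse and
#' pump-probe data sets, a structural comparison with bootstrap coordinate
#' errors, and the shock kinematics block. Deterministic for a fixed
#' configuration.
#'
#' @param config a [pipeline_config()].
#' @return object of class `shock_summary_report`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- config$sim
  components <- c("peaks",
                  if ("traces" %in% config$stages) "traces",
                  if ("jets" %in% config$stages) "jets")
  series <- generate_shot_series(sim, components = components)
  truth <- series$truth
  n <- nrow(truth)
  log <- list(n_shots = n)

  shots_df <- data.frame(shot_id = truth$shot_id, run = truth$run,
                         mode = truth$mode,
                         pump_energy = truth$pump_energy,
                         probe_energy = truth$probe_energy,
                         stringsAsFactors = FALSE)
  shots_df$hit <- vapply(series$shots, function(s)
    classify_hit(s$peaks), TRUE)
  shots_df$indexed <- shots_df$hit & truth$true_indexed
  shots_df$resolution <- vapply(series$shots, function(s)
    image_resolution(s$peaks, config$snr_threshold), 0)

  keep <- rep(TRUE, n)
  reasons <- rep("", n)

  if ("traces" %in% config$stages) {
    noise_sds <- vapply(series$shots, function(s)
      trace_noise_std(s$traces$unmasked), 0)
    keep_noise <- diode_noise_filter(noise_sds)
    reasons[!keep_noise] <- paste0(reasons[!keep_noise], "noisy_trace,")
    keep <- keep & keep_noise
    log$noise_filter <- list(n_in = n, n_excluded = sum(!keep_noise),
                             threshold = attr(keep_noise, "threshold"))

    pp <- which(truth$mode == "pump_probe")
    sig <- vapply(series$shots[pp], function(s)
      pump_window_signal(s$traces$masked, sim$pump_arrival_sample), 0)
    keep_leak_pp <- pump_leakage_filter(sig, k = config$leak_k)
    keep_leak <- rep(TRUE, n)
    keep_leak[pp] <- keep_leak_pp
    reasons[!keep_leak] <- paste0(reasons[!keep_leak], "pump_leakage,")
    keep <- keep & keep_leak
    log$leak_filter <- list(n_in = length(pp),
                            n_excluded = sum(!keep_leak_pp))
  }

  if ("jets" %in% config$stages) {
    # morphology rules apply to pump-probe hits (shock-analysis subset)
    pp_hits <- shots_df$shot_id[shots_df$hit &
                                  truth$mode == "pump_probe"]
    if (length(pp_hits) > 0) {
      feats <- series_jet_features(series, shot_ids = pp_hits)
      dec <- morphology_filter(feats$table,
                               pump_position_um = sim$pump_position_um,
                               probe_position_um = sim$pump_position_um -
                                 sim$beam_offset)
      bad <- dec$shot_id[!dec$passed]
      idx <- match(bad, shots_df$shot_id)
      bad_reason <- dec$reasons[!dec$passed]
      reasons[idx] <- paste0(reasons[idx], bad_reason, ",")
      keep[idx] <- FALSE
      log$morphology_filter <- list(n_in = length(pp_hits),
                                    n_excluded = length(bad))
    }
  }

  shots_df$filtered_pass <- keep
  shots_df$exclusion_reasons <- sub(",$", "", reasons)

  counts <- shots_to_run_counts(shots_df)
  rates <- list(
    all = rate_report(counts),
    pump_probe = rate_report(shots_to_run_counts(
      shots_df[shots_df$mode == "pump_probe", , drop = FALSE])),
    single = rate_report(shots_to_run_counts(
      shots_df[shots_df$mode == "single", , drop = FALSE])))

  # per-image resolution of indexed, filtered hits, by data set
  idx_ok <- shots_df$indexed & shots_df$filtered_pass &
    is.finite(shots_df$resolution)
  res_pp <- shots_df$resolution[idx_ok & shots_df$mode == "pump_probe"]
  res_sp <- shots_df$resolution[idx_ok & shots_df$mode == "single"]
  e_pp <- shots_df$probe_energy[idx_ok & shots_df$mode == "pump_probe"]
  e_sp <- shots_df$probe_energy[idx_ok & shots_df$mode == "single"]
  all_e <- c(e_pp, e_sp)
  energy_bins <- NULL
  if (length(all_e) > 1) {
    edges <- seq(min(all_e), max(all_e), length.out =
                   config$n_energy_bins + 1)
    energy_bins <- list(
      pump_probe = bin_by_probe_energy(res_pp, e_pp, edges),
      single = bin_by_probe_energy(res_sp, e_sp, edges))
  }
  resolution <- list(
    median_pump_probe = if (length(res_pp)) stats::median(res_pp)
    else NA_real_,
    median_single = if (length(res_sp)) stats::median(res_sp)
    else NA_real_,
    n_pump_probe = length(res_pp), n_single = length(res_sp),
    energy_bins = energy_bins)
  resolution$drop <- resolution$median_pump_probe -
    resolution$median_single

  metrics <- NULL
  if ("stats" %in% config$stages) {
    model_I <- wilson_intensities(d_min = config$stats_d_min,
                                  b_factor = config$stats_b_factor,
                                  scale = config$stats_scale,
                                  seed = substream_seed(sim$seed, "wilson"))
    mk <- function(noise, tag) {
      obs <- generate_reflection_observations(
        model_I, n_images = config$stats_n_images, scale_sd = 0.1,
        noise_sd = noise, seed = substream_seed(sim$seed, tag))
      merged <- merge_observations(obs)
      hs <- half_set_metrics(obs, n_bins = config$n_resolution_bins,
                             seed = substream_seed(sim$seed,
                                                   paste0(tag, "half")))
      comp <- completeness(merged, d_limits = c(min(merged$d),
                                                max(merged$d)),
                           n_bins = config$n_resolution_bins)
      wb <- wilson_b(merged)
      cut <- auto_resolution_cutoff(merged,
                                    n_bins = config$n_resolution_bins * 2)
      list(overall = hs$overall, bins = hs$bins,
           completeness_pct = comp$overall_pct,
           wilson_b = wb$b_factor, d_cutoff = cut$d_cutoff,
           multiplicity = mean(merged$multiplicity))
    }
    metrics <- list(single = mk(config$stats_noise_sd, "obs_single"),
                    pump_probe = mk(config$stats_noise_sd *
                                      config$damage_noise_factor,
                                    "obs_pp"))
  }

  structural <- NULL
  if ("structure" %in% config$stages) {
    ref <- synthetic_globin_model()
    pair <- generate_structure_pair(
      ref,
      displacement_spec = list(amplitude = config$structure_amplitude,
                               wavelength = 25),
      compaction = config$structure_compaction,
      noise_sd = config$structure_noise_sd,
      n_images = config$structure_n_images,
      seed = substream_seed(sim$seed, "structure"))
    eng <- surrogate_engine(pair$observations)
    ens <- bootstrap_ensemble(dimnames(pair$observations)[[3]], eng,
                              n_boot = config$n_boot,
                              seed = substream_seed(sim$seed, "boot"))
    rep_ <- compare_report(ref, pair$model, ensemble = ens)
    structural <- list(comparison = rep_,
                       two_sigma = two_sigma_check(
                         ens, as.matrix(
                           ca_atoms(pair$model)[c("x", "y", "z")])))
  }

  geom <- shock_geometry(sim$pump_probe_delay, sim$beam_offset,
                         sim$jet_speed)
  kinematics <- list(delay_ns = sim$pump_probe_delay,
                     offset_um = sim$beam_offset,
                     jet_speed_m_s = sim$jet_speed,
                     effective_delay_ns = effective_delay(geom),
                     equivalent_rate_mhz = equivalent_rep_rate(geom),
                     travel_distance_um = shock_travel_distance(geom))

  structure(list(config = config, config_hash = config_hash(config),
                 shots = shots_df, counts = counts, rates = rates,
                 resolution = resolution, metrics = metrics,
                 structural = structural, kinematics = kinematics,
                 log = log),
            class = "shock_summary_report")
}

#' @export
print.shock_summary_report <- function(x, ...) {
  cat("shock pipeline summary (config", substr(x$config_hash, 1, 8), ")\n")
  p <- x$rates$pump_probe$pooled
  s <- x$rates$single$pooled
  cat(sprintf("  pump-probe: %d shots, %d hits (%.1f%%), %d indexed (%.1f%% of filtered hits)\n",
              p$n_shots, p$n_hits, p$hit_rate_pct, p$n_indexed,
              p$indexing_rate_pct))
  cat(sprintf("  single:     %d shots, %d hits (%.1f%%), %d indexed (%.1f%% of filtered hits)\n",
              s$n_shots, s$n_hits, s$hit_rate_pct, s$n_indexed,
              s$indexing_rate_pct))
  cat(sprintf("  median resolution: %.2f A (pump-probe) vs %.2f A (single), drop %.2f A\n",
              x$resolution$median_pump_probe, x$resolution$median_single,
              x$resolution$drop))
  if (!is.null(x$metrics))
    cat(sprintf("  CC1/2 %.3f / %.3f, Rsplit %.1f%% / %.1f%% (single / pump-probe)\n",
                x$metrics$single$overall$cc_half,
                x$metrics$pump_probe$overall$cc_half,
                x$metrics$single$overall$rsplit_pct,
                x$metrics$pump_probe$overall$rsplit_pct))
  if (!is.null(x$structural))
    cat(sprintf("  structural: RMSD %.3f A over %d pairs, Rg ratio %.4f\n",
                x$structural$comparison$rmsd,
                x$structural$comparison$n_pairs,
                x$structural$comparison$rg_b /
                  x$structural$comparison$rg_a))
  cat(sprintf("  kinematics: effective delay %.1f ns (%.2f MHz), travel %.2f um\n",
              x$kinematics$effective_delay_ns,
              x$kinematics$equivalent_rate_mhz,
              x$kinematics$travel_distance_um))
  invisible(x)
}

#' Write a summary report to files
#'
#' Always writes `report.json`; with `"tsv"` also the shot table, per-run
#' rates, per-bin metric tables and (when present) the distance-difference
#' matrix; with `"plots"` a few base-graphics PDF figures (hit rate per
#' run, resolution histogram, resolution vs probe energy).
#'
#' @param report a [run_pipeline()] result.
#' @param dir output directory.
#' @param formats subset of `c("json", "tsv", "plots")`.
#' @return `dir`, invisibly.
#' @export
render_report <- function(report, dir, formats = c("json", "tsv")) {
  stopifnot(inherits(report, "shock_summary_report"))
  formats <- match.arg(formats, c("json", "tsv", "plots"),
                       several.ok = TRUE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if ("json" %in% formats) {
    slim <- report
    slim$shots <- NULL
    slim$structural$comparison$per_residue_compaction <- NULL
    slim$structural$comparison$displacement <- NULL
    slim$structural$comparison$coordinate_error <- NULL
    slim$structural$two_sigma$within <- NULL
    slim$config <- unclass(slim$config)
    slim$config$sim <- unclass(slim$config$sim)
    jsonlite::write_json(slim, file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         pretty = TRUE)
  }
  if ("tsv" %in% formats) {
    write_tsv_table(report$shots, file.path(dir, "shots.tsv"))
    write_tsv_table(report$rates$all$per_run,
                    file.path(dir, "run_rates.tsv"))
    if (!is.null(report$resolution$energy_bins)) {
      write_tsv_table(report$resolution$energy_bins$pump_probe,
                      file.path(dir, "energy_bins_pump_probe.tsv"))
      write_tsv_table(report$resolution$energy_bins$single,
                      file.path(dir, "energy_bins_single.tsv"))
    }
    if (!is.null(report$metrics)) {
      write_tsv_table(report$metrics$single$bins,
                      file.path(dir, "metrics_bins_single.tsv"))
      write_tsv_table(report$metrics$pump_probe$bins,
                      file.path(dir, "metrics_bins_pump_probe.tsv"))
    }
    if (!is.null(report$structural))
      write_tsv_table(report$structural$comparison$displacement,
                      file.path(dir, "displacement_field.tsv"))
  }
  if ("plots" %in% formats) {
    grDevices::pdf(file.path(dir, "figures.pdf"), width = 7, height = 5)
    on.exit(grDevices::dev.off())
    pr <- report$rates$all$per_run
    plot(seq_len(nrow(pr)), pr$hit_rate_pct, type = "b",
         xlab = "run", ylab = "hit rate (%)", main = "Hit rate per run")
    res <- report$shots$resolution[report$shots$indexed &
                                     report$shots$filtered_pass]
    res <- res[is.finite(res)]
    if (length(res))
      graphics::hist(res, breaks = 30, xlab = "resolution (A)",
                     main = "Per-image resolution")
    eb <- report$resolution$energy_bins
    if (!is.null(eb)) {
      ok <- eb$pump_probe$n > 0 | eb$single$n > 0
      plot(eb$single$e_low[ok], eb$single$median_resolution[ok],
           type = "b", col = "blue", xlab = "probe energy (mJ)",
           ylab = "median resolution (A)",
           main = "Resolution vs probe energy",
           ylim = range(c(eb$single$median_resolution,
                          eb$pump_probe$median_resolution), na.rm = TRUE))
      graphics::lines(eb$pump_probe$e_low[ok],
                      eb$pump_probe$median_resolution[ok], type = "b",
                      col = "darkorange")
    }
  }
  invisible(dir)
}
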