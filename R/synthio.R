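# Synthetic experiment generator: per-shot pulse energies, diode traces,
# jet snapshots and peak lists with full ground truth, so every downstream
# stage (filtering, statistics, structural comparison) is testable without
# beam-time data.

# Anti-correlated bivariate normal energies, truncated at zero by redrawing.
draw_energies <- function(n, mu, sd, rho) {
  Sigma <- matrix(c(sd[1]^2, rho * sd[1] * sd[2],
                    rho * sd[1] * sd[2], sd[2]^2), 2)
  out <- matrix(NA_real_, n, 2)
  need <- seq_len(n)
  for (iter in 1:200) {
    if (length(need) == 0L) break
    draw <- MASS::mvrnorm(length(need), mu = mu, Sigma = Sigma)
    draw <- matrix(draw, ncol = 2)
    ok <- draw[, 1] > 0 & draw[, 2] > 0
    out[need[ok], ] <- draw[ok, , drop = FALSE]
    need <- need[!ok]
  }
  if (length(need) > 0L)
    stop("energy truncation failed to converge; check means/sds",
         call. = FALSE)
  out
}

gaussian_bump <- function(n, centre, width, amplitude) {
  amplitude * exp(-0.5 * ((seq_len(n) - 1 - centre) / width)^2)
}

# One synthetic diode trace: baseline noise plus Gaussian pulse bumps.
make_trace <- function(cfg, pump_amp, probe_amp, noisy) {
  n <- cfg$n_trace_samples
  sdv <- cfg$trace_noise_sd * if (noisy) 10 else 1
  v <- stats::rnorm(n, 0, sdv)
  i_pump <- cfg$pump_arrival_sample
  i_probe <- cfg$pump_arrival_sample +
    round(cfg$pump_probe_delay / cfg$trace_dt_ns)
  if (pump_amp > 0) v <- v + gaussian_bump(n, i_pump, 2, pump_amp)
  if (probe_amp > 0 && i_probe < n)
    v <- v + gaussian_bump(n, i_probe, 2, probe_amp)
  diode_trace(v, dt_ns = cfg$trace_dt_ns,
              pre_pulse_window = c(1L, i_pump - 20L))
}

# Peak list whose best resolution at I/sigma >= 4 equals d_true exactly:
# one anchor peak at d_true with SNR >= 4, additional peaks at d >= d_true,
# and a few sub-threshold peaks at better d to exercise the SNR rule.
make_peaks <- function(n_peaks, d_true, hit) {
  if (n_peaks == 0L)
    return(data.frame(d = numeric(0), I = numeric(0), sigma = numeric(0)))
  if (hit) {
    d <- c(d_true, d_true + stats::rexp(n_peaks - 1, 1 / 1.5))
    snr <- c(4 + stats::rexp(1, 1 / 3),
             1 + stats::rexp(n_peaks - 1, 1 / 5))
    n_sub <- stats::rbinom(1, 2, 0.5)
    if (n_sub > 0) {
      d <- c(d, stats::runif(n_sub, 0.8 * d_true, d_true))
      snr <- c(snr, stats::runif(n_sub, 0.5, 3.9))
    }
  } else {
    d <- 3 + stats::rexp(n_peaks, 1 / 2)
    snr <- stats::runif(n_peaks, 0.5, 6)
  }
  sigma <- stats::rlnorm(length(d), 0, 0.3) * 10
  data.frame(d = d, I = snr * sigma, sigma = sigma)
}

# Jet render parameters for one shot. Normal jets carry the pump gap (and
# probe gap upstream of it) at their nominal positions with small jitter;
# abnormal jets are over-wide, broken up upstream of the pump, or carry a
# spurious upstream gap.
make_jet_params <- function(cfg, mode, struck, abnormal_type, shot_seed) {
  upp <- cfg$um_per_px
  width_px <- max(1, round(cfg$jet_diameter / upp))
  gap_half <- cfg$gap_length_um / 2
  pump_um <- cfg$pump_position_um
  probe_um <- pump_um - cfg$beam_offset    # probe is upstream
  gaps_um <- list()
  if (struck) {
    jit <- stats::runif(2, -0.5, 0.5)
    if (mode == "pump_probe") {
      gaps_um <- list(c(pump_um - gap_half, pump_um + gap_half) + jit[1],
                      c(probe_um - gap_half, probe_um + gap_half) + jit[2])
    } else {
      gaps_um <- list(c(probe_um - gap_half, probe_um + gap_half) + jit[1])
    }
  }
  breakup_row <- NULL
  if (abnormal_type == "wide") {
    width_px <- round(2.2 * width_px)
  } else if (abnormal_type == "breakup") {
    breakup_um <- stats::runif(1, 30, 45)   # upstream of the pump at 70 um
    breakup_row <- floor(breakup_um / upp)
    gaps_um <- Filter(function(g) g[2] < breakup_um, gaps_um)
  } else if (abnormal_type == "extra_gap") {
    extra_um <- stats::runif(1, 20, 40)
    gaps_um <- c(gaps_um, list(c(extra_um - gap_half, extra_um + gap_half)))
  }
  gaps_px <- lapply(gaps_um, function(g)
    c(max(0, floor(g[1] / upp)), min(cfg$image_height_px - 1,
                                     ceiling(g[2] / upp))))
  list(width_px = cfg$image_width_px, height_px = cfg$image_height_px,
       jet_axis_column = cfg$image_width_px / 2 + stats::runif(1, -3, 3),
       jet_width_px = width_px, gaps = gaps_px, breakup_row = breakup_row,
       wiggle_amplitude_px = cfg$wiggle_amplitude_px,
       wiggle_wavelength_px = cfg$wiggle_wavelength_px,
       wiggle_phase = stats::runif(1, 0, 2 * pi),
       seed = shot_seed,
       gap_centres_um = vapply(gaps_um, mean, 0),
       breakup_um = if (is.null(breakup_row)) NA_real_ else
         breakup_row * upp)
}

#' Render the jet snapshot of a generated shot
#'
#' Shots store jet geometry parameters rather than pixels, so large series
#' stay small in memory; this renders the deterministic snapshot for one
#' shot on demand (bit-identical for a fixed series seed).
#'
#' @param shot one element of the `shots` list of a [generate_shot_series()]
#'   result.
#' @return grayscale image matrix (see [render_jet_image()]).
#' @export
shot_jet_image <- function(shot) {
  p <- shot$jet
  render_jet_image(p$width_px, p$height_px, p$jet_axis_column,
                   p$jet_width_px, gaps = p$gaps,
                   breakup_row = p$breakup_row,
                   wiggle_amplitude_px = p$wiggle_amplitude_px,
                   wiggle_wavelength_px = p$wiggle_wavelength_px,
                   wiggle_phase = p$wiggle_phase, seed = p$seed)
}

#' Generate a synthetic pump-probe shot series with ground truth
#'
#' Simulates `config$n_shots` X-ray events: interleaved pump-probe and
#' single-pulse modes, anti-correlated pump/probe pulse energies, photodiode
#' traces (a stated fraction with high pre-pulse noise, a stated fraction of
#' pump-probe shots with pump leakage through the masking foil), jet
#' snapshot geometry (a stated fraction abnormal), and per-shot peak lists
#' whose best resolution worsens with pump energy (shock damage) and
#' improves with probe energy (signal).
#'
#' @param config a [simulation_config()].
#' @param components character subset of `c("peaks", "traces", "jets")`;
#'   stages not requested are omitted from the shot records (ground truth is
#'   always complete).
#' @return an object of class `shot_series`: list with `shots` (list of
#'   per-shot records), `truth` (one ground-truth row per shot) and
#'   `config`. Identical config (including seed) gives identical output.
#' @export
generate_shot_series <- function(config,
                                 components = c("peaks", "traces", "jets")) {
  stopifnot(inherits(config, "simulation_config"))
  components <- match.arg(components, c("peaks", "traces", "jets"),
                          several.ok = TRUE)
  cfg <- config
  n <- cfg$n_shots

  meta <- with_seed(substream_seed(cfg$seed, "modes"), {
    mode <- ifelse(stats::runif(n) < cfg$mode_fraction_pump_probe,
                   "pump_probe", "single")
    run <- paste0("r", sprintf("%03d", (seq_len(n) - 1) %/% cfg$run_size + 1))
    noisy <- stats::runif(n) < cfg$noise_trace_fraction
    leaked <- mode == "pump_probe" & stats::runif(n) < cfg$leak_fraction
    abnormal <- stats::runif(n) < cfg$abnormal_jet_fraction
    abn_type <- ifelse(abnormal,
                       sample(c("wide", "breakup", "extra_gap"), n,
                              replace = TRUE),
                       "none")
    list(mode = mode, run = run, noisy = noisy, leaked = leaked,
         abn_type = abn_type)
  })

  en <- with_seed(substream_seed(cfg$seed, "energies"), {
    e <- draw_energies(n, c(cfg$pump_energy_mean, cfg$probe_energy_mean),
                       c(max(cfg$pump_energy_sd, 1e-12),
                         max(cfg$probe_energy_sd, 1e-12)),
                       cfg$energy_anticorrelation)
    e[meta$mode == "single", 1] <- 0   # pump suppressed in reference mode
    e
  })
  pump_e <- en[, 1]
  probe_e <- en[, 2]

  d_true <- pmax(cfg$d_best,
                 cfg$d_base - cfg$signal_coefficient * probe_e +
                   cfg$damage_coefficient * pump_e)

  hits_idx <- with_seed(substream_seed(cfg$seed, "hits"), {
    p_hit <- cfg$hit_probability_base *
      exp(-cfg$hit_damage_coefficient * pump_e)
    hit <- stats::runif(n) < p_hit
    indexed <- hit & stats::runif(n) < cfg$index_probability
    list(hit = hit, indexed = indexed)
  })
  hit <- hits_idx$hit
  indexed <- hits_idx$indexed

  peaks <- NULL
  if ("peaks" %in% components) {
    peaks <- with_seed(substream_seed(cfg$seed, "peaks"), {
      # peak count grows with probe signal
      lam <- pmax(0.5, 8 * probe_e / cfg$probe_energy_mean)
      n_pk <- ifelse(hit, 10L + stats::rpois(n, lam),
                     pmin(9L, stats::rpois(n, 3)))
      lapply(seq_len(n), function(i)
        make_peaks(n_pk[i], d_true[i], hit[i]))
    })
  }

  traces <- NULL
  if ("traces" %in% components) {
    traces <- with_seed(substream_seed(cfg$seed, "traces"), {
      amp <- 50  # V per mJ, arbitrary diode gain
      lapply(seq_len(n), function(i) {
        # foil transmits ~2% of the above-edge pump; a photon-energy drift
        # below the edge (leak) adds a strong below-edge component
        leak_extra <- if (meta$leaked[i]) stats::runif(1, 0.03, 0.08) else 0
        list(unmasked = make_trace(cfg, amp * pump_e[i], amp * probe_e[i],
                                   meta$noisy[i]),
             masked = make_trace(cfg,
                                 amp * (pump_e[i] * 0.02 + leak_extra),
                                 amp * probe_e[i] * 0.9, meta$noisy[i]))
      })
    })
  }

  jets <- NULL
  if ("jets" %in% components) {
    jets <- with_seed(substream_seed(cfg$seed, "jets"), {
      struck <- stats::runif(n) < 0.97   # pulses almost always hit the jet
      lapply(seq_len(n), function(i)
        make_jet_params(cfg, meta$mode[i], struck[i], meta$abn_type[i],
                        shot_seed = substream_seed(cfg$seed,
                                                   paste0("jetpix", i))))
    })
  }

  shots <- lapply(seq_len(n), function(i) {
    s <- list(shot_id = sprintf("s%06d", i), run = meta$run[i],
              mode = meta$mode[i], pump_energy = pump_e[i],
              probe_energy = probe_e[i], hit = hit[i],
              indexed = indexed[i])
    if (!is.null(peaks)) s$peaks <- peaks[[i]]
    if (!is.null(traces)) s$traces <- traces[[i]]
    if (!is.null(jets)) s$jet <- jets[[i]]
    s
  })

  gap1 <- gap2 <- breakup <- rep(NA_real_, n)
  width_um <- rep(cfg$jet_diameter, n)
  if (!is.null(jets)) {
    for (i in seq_len(n)) {
      gc <- jets[[i]]$gap_centres_um
      if (length(gc) >= 1) gap1[i] <- gc[1]
      if (length(gc) >= 2) gap2[i] <- gc[2]
      breakup[i] <- jets[[i]]$breakup_um
      width_um[i] <- jets[[i]]$jet_width_px * cfg$um_per_px
    }
  }
  truth <- data.frame(
    shot_id = sprintf("s%06d", seq_len(n)), run = meta$run,
    mode = meta$mode, pump_energy = pump_e, probe_energy = probe_e,
    true_hit = hit, true_indexed = indexed, true_resolution = d_true,
    trace_noisy = meta$noisy, pump_leaked = meta$leaked,
    jet_abnormal = meta$abn_type != "none",
    abnormal_type = meta$abn_type, jet_width_um = width_um,
    gap1_um = gap1, gap2_um = gap2, breakup_um = breakup,
    stringsAsFactors = FALSE)

  structure(list(shots = shots, truth = truth, config = cfg),
            class = "shot_series")
}

#' @export
print.shot_series <- function(x, ...) {
  tr <- x$truth
  cat(sprintf("shot_series: %d shots (%d pump-probe / %d single), %d hits\n",
              nrow(tr), sum(tr$mode == "pump_probe"),
              sum(tr$mode == "single"), sum(tr$true_hit)))
  invisible(x)
}

#' Write a shot series to plain-text files
#'
#' Emits the shot table (TSV), per-shot peak lists (one TSV), diode traces
#' (one long TSV) and ground truth (JSON) under `dir`. Jet snapshots can be
#' written as ASCII PGM with `images = TRUE` (large; off by default).
#'
#' @param series a [generate_shot_series()] result.
#' @param dir output directory (created if needed).
#' @param images also write rendered jet snapshots as PGM.
#' @return `dir`, invisibly.
#' @export
write_shot_series <- function(series, dir, images = FALSE) {
  stopifnot(inherits(series, "shot_series"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- series$truth
  shot_tab <- tr[c("shot_id", "run", "mode", "pump_energy", "probe_energy",
                   "true_hit", "true_indexed")]
  names(shot_tab)[6:7] <- c("hit", "indexed")
  write_tsv_table(shot_tab, file.path(dir, "shots.tsv"))
  jsonlite::write_json(tr, file.path(dir, "ground_truth.json"),
                       digits = NA, auto_unbox = TRUE)
  pk <- lapply(series$shots, function(s) {
    if (is.null(s$peaks) || nrow(s$peaks) == 0L) return(NULL)
    cbind(shot_id = s$shot_id, s$peaks)
  })
  pk <- do.call(rbind, pk)
  if (!is.null(pk)) write_tsv_table(pk, file.path(dir, "peaks.tsv"))
  if (!is.null(series$shots[[1]]$traces)) {
    tr_rows <- lapply(series$shots, function(s) {
      data.frame(shot_id = s$shot_id,
                 t_ns = (seq_along(s$traces$unmasked$samples) - 1) *
                   s$traces$unmasked$dt_ns,
                 unmasked = s$traces$unmasked$samples,
                 masked = s$traces$masked$samples)
    })
    write_tsv_table(do.call(rbind, tr_rows), file.path(dir, "traces.tsv"))
  }
  if (images && !is.null(series$shots[[1]]$jet)) {
    img_dir <- file.path(dir, "jets")
    dir.create(img_dir, showWarnings = FALSE)
    for (s in series$shots)
      write_pgm(shot_jet_image(s), file.path(img_dir,
                                             paste0(s$shot_id, ".pgm")))
  }
  invisible(dir)
}
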