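# Per-shot acceptance rules: diode-trace electronic noise, pump leakage
# through the masking foil, and jet morphology, plus hit classification and
# hit/indexing rate accounting.

#' Photodiode voltage trace
#'
#' @param samples voltage samples, V.
#' @param dt_ns sampling step, ns.
#' @param pre_pulse_window `c(first, last)` 1-based sample indices of the
#'   interval preceding pulse arrival, used for the noise estimate.
#' @param masked was this diode covered by the Fe masking foil (it then
#'   sees the probe, and only leaked pump photons)?
#' @return object of class `diode_trace`.
#' @export
diode_trace <- function(samples, dt_ns, pre_pulse_window,
                        masked = FALSE) {
  stopifnot(is.numeric(samples), length(samples) > 0)
  check_positive(dt_ns, "dt_ns")
  w <- as.integer(pre_pulse_window)
  if (length(w) != 2L || w[1] < 1L || w[2] > length(samples) || w[1] > w[2])
    stop("'pre_pulse_window' must be valid sample indices", call. = FALSE)
  structure(list(samples = as.numeric(samples), dt_ns = dt_ns,
                 pre_pulse_window = w, masked = isTRUE(masked)),
            class = "diode_trace")
}

#' Pre-pulse noise of a diode trace
#'
#' Standard deviation of the voltage over the interval preceding pulse
#' arrival (population SD, divisor n — fixed convention).
#'
#' @param trace a [diode_trace()].
#' @return noise SD, V.
#' @export
trace_noise_std <- function(trace) {
  stopifnot(inherits(trace, "diode_trace"))
  w <- trace$pre_pulse_window
  if (w[2] - w[1] + 1L < 8L)
    stop("pre-pulse window shorter than 8 samples", call. = FALSE)
  pop_sd(trace$samples[w[1]:w[2]])
}

#' Diode electronic-noise filter
#'
#' Excludes shots with abnormally noisy diode traces. The "noise-less"
#' reference population is estimated robustly in a first pass (per-shot
#' noise SDs within 3 scaled-MADs of the median are retained); a shot is
#' then excluded iff its noise SD is strictly greater than
#' mean(retained) + 3 * SD(retained).
#'
#' @param noise_sds per-shot pre-pulse noise SDs (from
#'   [trace_noise_std()]), or a list of [diode_trace()] objects.
#' @return logical keep-flag vector; attributes `threshold` and `retained`
#'   record the reference population.
#' @export
diode_noise_filter <- function(noise_sds) {
  if (is.list(noise_sds))
    noise_sds <- vapply(noise_sds, trace_noise_std, 0)
  if (length(noise_sds) < 50L)
    stop("need at least 50 shots for population statistics", call. = FALSE)
  med <- stats::median(noise_sds)
  madv <- stats::mad(noise_sds)
  retained <- if (madv == 0) noise_sds[noise_sds == med] else
    noise_sds[abs(noise_sds - med) <= 3 * madv]
  if (length(retained) == 0L)
    stop("no traces qualify as noise-less: population estimate impossible",
         call. = FALSE)
  thr <- mean(retained) + 3 * pop_sd(retained)
  keep <- noise_sds <= thr          # strictly greater than threshold fails
  attr(keep, "threshold") <- thr
  attr(keep, "retained") <- length(retained)
  keep
}

#' Integrated masked-diode signal in the pump window
#'
#' Baseline-subtracted integral of the trace over a window centred on pump
#' arrival; elevated values on the foil-masked diode indicate pump photons
#' leaking below the absorption edge.
#'
#' @param trace a [diode_trace()].
#' @param pump_sample 1-based sample index of pump arrival.
#' @param half_window_samples window half-width in samples.
#' @return integrated signal, V*ns.
#' @export
pump_window_signal <- function(trace, pump_sample, half_window_samples = 6L) {
  stopifnot(inherits(trace, "diode_trace"))
  idx <- max(1L, pump_sample - half_window_samples):
    min(length(trace$samples), pump_sample + half_window_samples)
  w <- trace$pre_pulse_window
  baseline <- mean(trace$samples[w[1]:w[2]])
  sum(trace$samples[idx] - baseline) * trace$dt_ns
}

#' Pump-leakage filter
#'
#' Keeps pump-probe shots whose integrated masked-diode pump-window signal
#' is strictly smaller than mean + `k` * SD over all shots (population SD);
#' larger signals indicate pump photon energy leaking through the masking
#' foil into the recorded diffraction.
#'
#' @param signals per-shot integrated pump-window signals
#'   (see [pump_window_signal()]).
#' @param k threshold multiplier (default 1.5).
#' @return logical keep-flag vector with attribute `threshold`.
#' @export
pump_leakage_filter <- function(signals, k = 1.5) {
  if (length(signals) == 0L) stop("empty input", call. = FALSE)
  s <- pop_sd(signals)
  if (s == 0) {                      # zero-variance population: all kept
    keep <- rep(TRUE, length(signals))
    attr(keep, "threshold") <- Inf
    return(keep)
  }
  thr <- mean(signals) + k * s
  keep <- signals < thr
  attr(keep, "threshold") <- thr
  keep
}

#' Jet-morphology filter
#'
#' Applies the jet-shape acceptance rules per shot: (i) projected jet width
#' within one standard deviation of the run median width, (ii) one or two
#' explosion gaps, each attributable to the pump or probe position (a probe
#' gap need not exist), and (iii) no unattributable gap and no break-up
#' upstream of the pump position, so a launched shock can propagate to the
#' probed segment.
#'
#' @param features_table data frame from [series_jet_features()]`$table`
#'   (columns shot_id, run, no_jet, width_um, n_gaps, gap1_um, gap2_um,
#'   breakup_um).
#' @param pump_position_um nominal pump interaction position, um.
#' @param probe_position_um nominal probe position, um (upstream of the
#'   pump); gaps within `position_tol_um` of either position are
#'   attributable.
#' @param position_tol_um attribution tolerance, um.
#' @return data frame of class `filter_decisions`: shot_id, passed, and a
#'   `reasons` string column (comma-separated subset of abnormal_width,
#'   wrong_gap_count, discontinuous_upstream, no_jet; empty iff passed).
#' @export
morphology_filter <- function(features_table, pump_position_um,
                              probe_position_um = NULL,
                              position_tol_um = 3) {
  ft <- features_table
  stopifnot(all(c("shot_id", "run", "width_um", "n_gaps") %in% names(ft)))
  ok_pos <- c(pump_position_um, probe_position_um)
  reasons <- vector("list", nrow(ft))
  for (rn in unique(ft$run)) {
    in_run <- which(ft$run == rn)
    w <- ft$width_um[in_run]
    med <- stats::median(w, na.rm = TRUE)
    sdv <- pop_sd(w)
    for (i in in_run) {
      rs <- character(0)
      if (isTRUE(ft$no_jet[i]) || is.na(ft$width_um[i])) {
        reasons[[i]] <- "no_jet"
        next
      }
      if (abs(ft$width_um[i] - med) > sdv) rs <- c(rs, "abnormal_width")
      if (!(ft$n_gaps[i] %in% c(1L, 2L))) rs <- c(rs, "wrong_gap_count")
      gaps <- c(ft$gap1_um[i], ft$gap2_um[i])
      gaps <- gaps[!is.na(gaps)]
      stray <- gaps[vapply(gaps, function(g)
        all(abs(g - ok_pos) > position_tol_um), TRUE)]
      upstream_break <- !is.na(ft$breakup_um[i]) &&
        ft$breakup_um[i] < pump_position_um
      if (any(stray < pump_position_um) || upstream_break)
        rs <- c(rs, "discontinuous_upstream")
      reasons[[i]] <- rs
    }
  }
  out <- data.frame(shot_id = ft$shot_id,
                    passed = lengths(reasons) == 0L,
                    reasons = vapply(reasons, paste, "", collapse = ","),
                    stringsAsFactors = FALSE)
  class(out) <- c("filter_decisions", class(out))
  out
}

#' Classify a diffraction image as a crystal hit
#'
#' An image is a hit iff it contains at least 10 diffraction peaks.
#'
#' @param peaks a peak-list data frame (one row per peak) or a peak count.
#' @return logical.
#' @export
classify_hit <- function(peaks) {
  n <- if (is.data.frame(peaks)) nrow(peaks) else as.integer(peaks)
  n >= 10L
}

#' Hit and indexing rates per run and pooled
#'
#' The hit rate of a run is hits / shots; the indexing rate is indexed hits
#' / filtered hits (hits passing the shot filters). Reports per-run rates,
#' their unweighted average over runs, and pooled (aggregate-count) rates.
#' Runs with zero shots are dropped from the averages; rates with a zero
#' denominator are reported as NA.
#'
#' @param counts data frame with columns `run`, `n_shots`, `n_hits`,
#'   `n_filtered_hits`, `n_indexed` (one row per run); see
#'   [shots_to_run_counts()].
#' @return list with `per_run` (rates appended, percent), `average`
#'   (unweighted over runs) and `pooled`.
#' @export
rate_report <- function(counts) {
  req <- c("run", "n_shots", "n_hits", "n_filtered_hits", "n_indexed")
  stopifnot(all(req %in% names(counts)))
  counts <- counts[counts$n_shots > 0, , drop = FALSE]
  rate <- function(n, d) ifelse(d > 0, 100 * n / d, NA_real_)
  per_run <- counts
  per_run$hit_rate_pct <- rate(counts$n_hits, counts$n_shots)
  per_run$indexing_rate_pct <- rate(counts$n_indexed,
                                    counts$n_filtered_hits)
  pooled <- list(
    n_shots = sum(counts$n_shots), n_hits = sum(counts$n_hits),
    n_filtered_hits = sum(counts$n_filtered_hits),
    n_indexed = sum(counts$n_indexed),
    hit_rate_pct = rate(sum(counts$n_hits), sum(counts$n_shots)),
    indexing_rate_pct = rate(sum(counts$n_indexed),
                             sum(counts$n_filtered_hits)))
  list(per_run = per_run,
       average = list(
         hit_rate_pct = mean(per_run$hit_rate_pct, na.rm = TRUE),
         indexing_rate_pct = mean(per_run$indexing_rate_pct,
                                  na.rm = TRUE)),
       pooled = pooled)
}

#' Per-run counts from a per-shot table
#'
#' @param shots data frame with columns `run`, `hit`, `filtered_pass`
#'   (shot passed all filters) and `indexed`.
#' @return per-run counts data frame for [rate_report()].
#' @export
shots_to_run_counts <- function(shots) {
  stopifnot(all(c("run", "hit", "filtered_pass", "indexed") %in%
                  names(shots)))
  agg <- function(v) tapply(v, shots$run, sum)
  runs <- sort(unique(shots$run))
  data.frame(run = runs,
             n_shots = as.integer(table(factor(shots$run, levels = runs))),
             n_hits = as.integer(agg(shots$hit)[runs]),
             n_filtered_hits = as.integer(
               agg(shots$hit & shots$filtered_pass)[runs]),
             n_indexed = as.integer(
               agg(shots$hit & shots$filtered_pass & shots$indexed)[runs]),
             stringsAsFactors = FALSE)
}
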