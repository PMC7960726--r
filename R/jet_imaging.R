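# Jet snapshot analysis: segment the jet, locate explosion gaps and the
# break-up point, and measure the projected width and the jet speed.

#' Extract jet geometry from a snapshot image
#'
#' Segments the dark jet from the bright background by thresholding (Otsu's
#' method on the intensity histogram by default), builds the row-wise jet
#' presence profile, and reports: explosion gaps (maximal runs of jet-free
#' rows between jet-present rows), the break-up position (first row
#' downstream of which the stream is intermittent, droplet-like), and the
#' projected width (median horizontal extent over jet-present rows). Rows
#' run downstream from the nozzle; positions are um from the top edge,
#' 0-based pixel convention.
#'
#' @param image single-channel numeric matrix (values in [0, 1], dark jet).
#' @param um_per_px image calibration, um per pixel (> 0).
#' @param intensity_threshold segmentation threshold; pixels strictly below
#'   it are jet. `NULL` (default) uses Otsu's method.
#' @param min_gap_px minimum gap length in rows; shorter jet-free runs are
#'   treated as noise (default 2).
#' @param min_segment_px minimum length of a contiguous jet run to count as
#'   continuous stream rather than a droplet (default 10).
#' @return an object of class `jet_features`: list with `no_jet`,
#'   `projected_width_um`, `gaps_um` (list of c(start, end), disjoint,
#'   sorted downstream), `breakup_um` (or NA), `axis_column_um`,
#'   `threshold`, `um_per_px` and the imaged span.
#' @export
extract_jet_features <- function(image, um_per_px,
                                 intensity_threshold = NULL,
                                 min_gap_px = 2, min_segment_px = 10) {
  if (!is.matrix(image)) stop("'image' must be a matrix", call. = FALSE)
  check_positive(um_per_px, "um_per_px")
  thr <- if (is.null(intensity_threshold)) {
    EBImage::otsu(image, range = c(0, 1))
  } else intensity_threshold
  jet <- image < thr

  present <- rowSums(jet) > 0
  if (!any(present)) {
    return(structure(list(no_jet = TRUE, projected_width_um = NA_real_,
                          gaps_um = list(), breakup_um = NA_real_,
                          axis_column_um = NA_real_, threshold = thr,
                          um_per_px = um_per_px,
                          span_um = (nrow(image) - 1) * um_per_px),
                     class = "jet_features"))
  }

  # run-length structure of the presence profile
  r <- rle(present)
  ends <- cumsum(r$lengths)          # 1-based row of each run end
  starts <- ends - r$lengths + 1L

  # break-up: downstream of the last "long" jet run only short droplet runs
  # remain; gaps are only counted upstream of the break-up point
  long_runs <- which(r$values & r$lengths >= min_segment_px)
  breakup_um <- NA_real_
  last_row <- ends[length(ends)]     # last row considered continuous stream
  if (length(long_runs) > 0L) {
    last_long <- long_runs[length(long_runs)]
    trailing <- which(r$values & seq_along(r$values) > last_long)
    if (length(trailing) >= 2L) {    # >= 2 short runs behave like droplets
      breakup_um <- (ends[last_long] - 1L) * um_per_px
      last_row <- ends[last_long]
    }
  }
  first_row <- starts[which(r$values)[1]]

  gaps_um <- list()
  gap_runs <- which(!r$values & r$lengths >= min_gap_px)
  for (g in gap_runs) {
    if (starts[g] > first_row && ends[g] < last_row)
      gaps_um[[length(gaps_um) + 1L]] <-
        c((starts[g] - 1L) * um_per_px, (ends[g] - 1L) * um_per_px)
  }

  rows_ok <- which(present)
  rows_ok <- rows_ok[rows_ok <= last_row]
  ext <- vapply(rows_ok, function(i) {
    w <- which(jet[i, ])
    (w[length(w)] - w[1] + 1)
  }, 0)
  axis <- stats::median(vapply(rows_ok, function(i)
    mean(range(which(jet[i, ]))), 0))

  structure(list(no_jet = FALSE,
                 projected_width_um = stats::median(ext) * um_per_px,
                 gaps_um = gaps_um, breakup_um = breakup_um,
                 axis_column_um = (axis - 1) * um_per_px,
                 threshold = thr, um_per_px = um_per_px,
                 span_um = (nrow(image) - 1) * um_per_px),
            class = "jet_features")
}

#' @export
print.jet_features <- function(x, ...) {
  if (x$no_jet) {
    cat("jet_features: no jet detected\n")
    return(invisible(x))
  }
  cat(sprintf("jet_features: width %.2f um, %d gap(s)%s\n",
              x$projected_width_um, length(x$gaps_um),
              if (is.na(x$breakup_um)) ""
              else sprintf(", break-up at %.1f um", x$breakup_um)))
  invisible(x)
}

#' Centre of the n-th explosion gap
#'
#' @param features a [extract_jet_features()] result.
#' @param which 1-based ordinal of the gap, counted downstream.
#' @return gap centre position, um from the top edge.
#' @export
gap_centre <- function(features, which = 1L) {
  stopifnot(inherits(features, "jet_features"))
  if (which < 1 || which > length(features$gaps_um))
    stop("gap ", which, " does not exist (", length(features$gaps_um),
         " gap(s) detected)", call. = FALSE)
  mean(features$gaps_um[[which]])
}

#' Is the jet continuous upstream of a position?
#'
#' TRUE iff no detected gap and no break-up point lies upstream of (i.e. at
#' a smaller axis position than) `position_um`.
#'
#' @param features a [extract_jet_features()] result.
#' @param position_um query position, um from the top edge.
#' @export
jet_continuous_upstream <- function(features, position_um) {
  stopifnot(inherits(features, "jet_features"))
  if (features$no_jet) return(FALSE)
  for (g in features$gaps_um) if (g[1] < position_um) return(FALSE)
  if (!is.na(features$breakup_um) && features$breakup_um < position_um)
    return(FALSE)
  TRUE
}

#' Jet speed from gap positions at two imaging delays
#'
#' The centre of an explosion gap advects downstream with the jet, so two
#' sightings give the speed `v = (y1 - y2) / (t1 - t2)`; 1 um/ns equals
#' 1000 m/s exactly. Positive values mean downstream motion (position
#' increasing with time).
#'
#' @param y1_um,y2_um gap centre positions, um.
#' @param t1_ns,t2_ns imaging delays, ns.
#' @return jet speed, m/s.
#' @export
jet_speed <- function(y1_um, t1_ns, y2_um, t2_ns) {
  if (t1_ns == t2_ns)
    stop("imaging delays are equal: speed undefined", call. = FALSE)
  1000 * (y1_um - y2_um) / (t1_ns - t2_ns)
}

#' Extract jet features for every shot of a series
#'
#' Renders each shot's snapshot on demand and runs
#' [extract_jet_features()], returning one row per shot plus the feature
#' objects. Shots without jet parameters get `no_jet = TRUE`.
#'
#' @param series a [generate_shot_series()] result (jets component present).
#' @param shot_ids optional subset of shot ids to analyse.
#' @param ... passed to [extract_jet_features()].
#' @return list with `table` (data frame: shot_id, run, no_jet, width,
#'   n_gaps, gap centres, breakup) and `features` (named list).
#' @export
series_jet_features <- function(series, shot_ids = NULL, ...) {
  stopifnot(inherits(series, "shot_series"))
  upp <- series$config$um_per_px
  shots <- series$shots
  if (!is.null(shot_ids)) {
    keep <- vapply(shots, function(s) s$shot_id %in% shot_ids, TRUE)
    shots <- shots[keep]
  }
  feats <- lapply(shots, function(s) {
    if (is.null(s$jet)) return(NULL)
    extract_jet_features(shot_jet_image(s), um_per_px = upp, ...)
  })
  names(feats) <- vapply(shots, `[[`, "", "shot_id")
  rows <- lapply(seq_along(shots), function(i) {
    f <- feats[[i]]
    if (is.null(f))
      return(data.frame(shot_id = shots[[i]]$shot_id, run = shots[[i]]$run,
                        no_jet = TRUE, width_um = NA_real_, n_gaps = 0L,
                        gap1_um = NA_real_, gap2_um = NA_real_,
                        breakup_um = NA_real_))
    gc <- vapply(f$gaps_um, mean, 0)
    data.frame(shot_id = shots[[i]]$shot_id, run = shots[[i]]$run,
               no_jet = f$no_jet, width_um = f$projected_width_um,
               n_gaps = length(f$gaps_um),
               gap1_um = if (length(gc) >= 1) gc[1] else NA_real_,
               gap2_um = if (length(gc) >= 2) gc[2] else NA_real_,
               breakup_um = f$breakup_um)
  })
  list(table = do.call(rbind, rows), features = feats)
}
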