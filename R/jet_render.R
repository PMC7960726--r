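#' Render a synthetic jet snapshot
#'
#' Draws a dark liquid jet on a bright background, emulating femtosecond
#' shadowgraph snapshots of a microjet: a roughly vertical column (rows run
#' downstream from the nozzle at the top edge; 0-based pixel convention)
#' with optional explosion gaps, a Rayleigh break-up point below which the
#' stream decays into droplets, and sinusoidal wiggle.
#'
#' @param width_px,height_px image size in pixels.
#' @param jet_axis_column jet axis column (0-based, may be fractional).
#' @param jet_width_px jet width in pixels (>= 1).
#' @param gaps list of `c(start_row, end_row)` 0-based inclusive row
#'   intervals with no jet (explosion gaps); must be disjoint and inside
#'   the image.
#' @param breakup_row 0-based row downstream of which the continuous jet is
#'   replaced by droplets, or `NULL` for an unbroken jet.
#' @param wiggle_amplitude_px,wiggle_wavelength_px,wiggle_phase sinusoidal
#'   displacement of the jet axis with row.
#' @param droplet_period_px,droplet_length_px droplet train geometry below
#'   the break-up point.
#' @param noise_sd pixel noise SD (image values are clipped to [0, 1]).
#' @param seed optional seed for the pixel noise.
#' @return numeric matrix `height_px x width_px` in [0, 1]; dark jet
#'   (~0.12) on bright background (~0.88). Row `i` of the matrix is pixel
#'   row `i - 1`.
#' @export
render_jet_image <- function(width_px, height_px, jet_axis_column,
                             jet_width_px, gaps = list(),
                             breakup_row = NULL,
                             wiggle_amplitude_px = 0,
                             wiggle_wavelength_px = 40,
                             wiggle_phase = 0,
                             droplet_period_px = 14,
                             droplet_length_px = 5,
                             noise_sd = 0.02, seed = NULL) {
  if (jet_width_px < 1) stop("'jet_width_px' must be >= 1", call. = FALSE)
  gaps <- lapply(gaps, function(g) {
    if (length(g) != 2L || g[1] > g[2])
      stop("each gap must be c(start_row, end_row) with start <= end",
           call. = FALSE)
    if (g[1] < 0 || g[2] > height_px - 1)
      stop("gap lies outside the image", call. = FALSE)
    as.numeric(g)
  })
  if (length(gaps) > 1L) {
    o <- order(vapply(gaps, `[`, 0, 1L))
    gaps <- gaps[o]
    starts <- vapply(gaps, `[`, 0, 1L)
    ends <- vapply(gaps, `[`, 0, 2L)
    if (any(starts[-1L] <= ends[-length(ends)]))
      stop("gap intervals overlap", call. = FALSE)
  }

  draw <- function() {
    bg <- 0.88
    fg <- 0.12
    img <- matrix(bg, nrow = height_px, ncol = width_px)
    rows0 <- 0:(height_px - 1)
    centre <- jet_axis_column + wiggle_amplitude_px *
      sin(2 * pi * rows0 / wiggle_wavelength_px + wiggle_phase)
    half <- jet_width_px / 2
    in_gap <- rep(FALSE, height_px)
    for (g in gaps) in_gap[rows0 >= g[1] & rows0 <= g[2]] <- TRUE
    for (i in seq_len(height_px)) {
      r0 <- rows0[i]
      if (in_gap[i]) next
      if (!is.null(breakup_row) && r0 > breakup_row) {
        # droplet train: short dark blobs separated by clear stream
        if (((r0 - breakup_row) %% droplet_period_px) >= droplet_length_px)
          next
      }
      c1 <- max(1L, as.integer(ceiling(centre[i] - half)) + 1L)
      c2 <- min(width_px, as.integer(floor(centre[i] + half)) + 1L)
      if (c1 <= c2) img[i, c1:c2] <- fg
    }
    if (noise_sd > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, noise_sd),
                          nrow = height_px)
    pmin(pmax(img, 0), 1)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Write / read a plain-text PGM (P2) image
#'
#' 8-bit ASCII portable graymap, the plain-text exchange format used for
#' synthetic jet snapshots.
#'
#' @param img numeric matrix in [0, 1].
#' @param path file path.
#' @return `read_pgm` returns a numeric matrix in [0, 1].
#' @export
write_pgm <- function(img, path) {
  v <- round(pmin(pmax(img, 0), 1) * 255)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), "255"), con)
  apply_rows <- apply(v, 1L, paste, collapse = " ")
  writeLines(apply_rows, con)
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  txt <- readLines(path)
  txt <- txt[!grepl("^#", txt)]
  if (txt[1] != "P2") stop("not an ASCII PGM (P2) file", call. = FALSE)
  dims <- scan(text = txt[2], quiet = TRUE)
  maxv <- scan(text = txt[3], quiet = TRUE)
  vals <- scan(text = paste(txt[-(1:3)], collapse = " "), quiet = TRUE)
  matrix(vals / maxv, nrow = dims[2], ncol = dims[1], byrow = TRUE)
}
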