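# Per-image resolution statistics, probe-energy binning, and merged
# half-dataset quality metrics (Rsplit, CC1/2, CC*, I/sigma, completeness,
# Wilson B, automatic resolution cutoff).

#' Per-image diffraction resolution
#'
#' The best (smallest) d among peaks with signal-to-noise ratio
#' `I/sigma(I) >= snr_threshold` (boundary inclusive). Returns `NA` when no
#' peak qualifies.
#'
#' @param peak_list data frame with columns `d`, `I`, `sigma` (one row per
#'   peak).
#' @param snr_threshold signal-to-noise threshold (default 4).
#' @return d_min in Angstrom, or NA.
#' @export
image_resolution <- function(peak_list, snr_threshold = 4) {
  stopifnot(is.data.frame(peak_list),
            all(c("d", "I", "sigma") %in% names(peak_list)))
  if (nrow(peak_list) == 0L) return(NA_real_)
  ok <- peak_list$I / peak_list$sigma >= snr_threshold
  if (!any(ok)) return(NA_real_)
  min(peak_list$d[ok])
}

#' Bin per-image resolutions by probe pulse energy
#'
#' For each probe-energy bin: number of images, median per-image
#' resolution, and the error of the mean (SD / sqrt(n); NA for n < 2).
#' Empty bins are reported with n = 0 and no statistics.
#'
#' @param resolutions per-image resolution values, Angstrom.
#' @param energies matching probe pulse energies, mJ.
#' @param bin_edges energy bin edges (length >= 2, increasing).
#' @return data frame: bin, e_low, e_high, n, median_resolution,
#'   error_of_mean.
#' @export
bin_by_probe_energy <- function(resolutions, energies, bin_edges) {
  stopifnot(length(resolutions) == length(energies),
            length(bin_edges) >= 2, !is.unsorted(bin_edges))
  keep <- is.finite(resolutions) & is.finite(energies)
  resolutions <- resolutions[keep]
  energies <- energies[keep]
  idx <- findInterval(energies, bin_edges, rightmost.closed = TRUE)
  n_bins <- length(bin_edges) - 1L
  rows <- lapply(seq_len(n_bins), function(b) {
    v <- resolutions[idx == b]
    data.frame(bin = b, e_low = bin_edges[b], e_high = bin_edges[b + 1],
               n = length(v),
               median_resolution = if (length(v)) stats::median(v)
               else NA_real_,
               error_of_mean = if (length(v) >= 2)
                 stats::sd(v) / sqrt(length(v)) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Equalize two probe-energy distributions by per-bin subsampling
#'
#' Within each common energy bin both sets are randomly subsampled without
#' replacement to the smaller of the two bin counts, removing distribution
#' differences before comparing resolution statistics.
#'
#' @param energies_a,energies_b probe energies of the two sets.
#' @param bin_edges common energy bin edges.
#' @param seed RNG seed for the subsampling.
#' @return list with integer index vectors `idx_a`, `idx_b` into the
#'   original sets.
#' @export
equalize_energy_distributions <- function(energies_a, energies_b,
                                          bin_edges, seed = 1) {
  ia <- findInterval(energies_a, bin_edges, rightmost.closed = TRUE)
  ib <- findInterval(energies_b, bin_edges, rightmost.closed = TRUE)
  n_bins <- length(bin_edges) - 1L
  with_seed(seed, {
    keep_a <- integer(0)
    keep_b <- integer(0)
    for (b in seq_len(n_bins)) {
      wa <- which(ia == b)
      wb <- which(ib == b)
      m <- min(length(wa), length(wb))
      if (m == 0L) next
      keep_a <- c(keep_a, if (length(wa) > m) sample(wa, m) else wa)
      keep_b <- c(keep_b, if (length(wb) > m) sample(wb, m) else wb)
    }
    list(idx_a = sort(keep_a), idx_b = sort(keep_b))
  })
}

#' Reflection observations container
#'
#' Per-image observations `(h, k, l, I, sigma, image_id)` in a fixed
#' orthorhombic cell.
#'
#' @param df data frame with columns h, k, l, I, sigma, image_id.
#' @param cell cell edges `c(a, b, c)`, Angstrom.
#' @param space_group space-group symbol.
#' @return object of class `reflection_obs` (the data frame with cell and
#'   space group attached as attributes).
#' @export
reflection_obs <- function(df, cell, space_group = "P212121") {
  stopifnot(all(c("h", "k", "l", "I", "sigma", "image_id") %in% names(df)))
  check_space_group(space_group)
  attr(df, "cell") <- cell[1:3]
  attr(df, "space_group") <- space_group
  class(df) <- c("reflection_obs", "data.frame")
  df
}

#' Write / read reflection observations as plain text
#'
#' Whitespace-separated columns `h k l I sigma image_id` with a `# cell`
#' and `# space_group` header.
#'
#' @param obs a [reflection_obs()].
#' @param path file path.
#' @export
write_reflection_obs <- function(obs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("# cell", paste(attr(obs, "cell"), collapse = " ")),
               paste("# space_group", attr(obs, "space_group"))), con)
  utils::write.table(as.data.frame(obs), con, sep = " ", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_reflection_obs
#' @export
read_reflection_obs <- function(path) {
  hdr <- readLines(path, n = 2)
  cell <- as.numeric(strsplit(sub("# cell ", "", hdr[1]), " ")[[1]])
  sg <- sub("# space_group ", "", hdr[2])
  df <- utils::read.table(path, header = TRUE, skip = 2)
  reflection_obs(df, cell = cell, space_group = sg)
}

#' Merge per-image observations into a unique reflection set
#'
#' Reduces every observation to the mmm asymmetric unit and takes the
#' unweighted mean intensity per unique reflection, without scaling or
#' partiality correction. The sigma of the mean is SD / sqrt(multiplicity)
#' (sample SD; for multiplicity 1 the observation's own sigma estimate is
#' kept).
#'
#' @param obs a [reflection_obs()] (or data frame with the same columns
#'   plus `cell`/`space_group` arguments).
#' @param cell,space_group override the attributes attached to `obs`.
#' @return object of class `merged_set`: data frame h, k, l, d, I, sigma,
#'   multiplicity with cell/space-group attributes; `sum(multiplicity)`
#'   equals the number of observations merged.
#' @export
merge_observations <- function(obs, cell = attr(obs, "cell"),
                               space_group = attr(obs, "space_group")) {
  if (is.null(cell)) stop("cell required", call. = FALSE)
  if (is.null(space_group)) space_group <- "P212121"
  check_space_group(space_group)
  a <- asu_mmm(obs$h, obs$k, obs$l)
  key <- paste(a$h, a$k, a$l)
  I_mean <- tapply(obs$I, key, mean)
  mult <- tapply(obs$I, key, length)
  I_sd <- tapply(obs$I, key, stats::sd)          # NA for multiplicity 1
  sig_first <- tapply(obs$sigma, key, function(s) s[1])
  hkl <- do.call(rbind, lapply(strsplit(names(I_mean), " "), as.integer))
  out <- data.frame(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                    d = d_spacing(hkl[, 1], hkl[, 2], hkl[, 3], cell),
                    I = as.numeric(I_mean),
                    sigma = ifelse(mult > 1,
                                   as.numeric(I_sd) / sqrt(as.numeric(mult)),
                                   as.numeric(sig_first)),
                    multiplicity = as.integer(mult))
  out <- out[order(-out$d), ]
  rownames(out) <- NULL
  attr(out, "cell") <- cell[1:3]
  attr(out, "space_group") <- space_group
  class(out) <- c("merged_set", "data.frame")
  out
}

#' CC* from the half-dataset correlation
#'
#' `CC* = sqrt(2 CC1/2 / (1 + CC1/2))`: the estimated correlation of the
#' merged intensities with the unknown true intensities.
#'
#' @param cc_half half-dataset Pearson correlation CC1/2 (vectorised).
#' @return CC* values; NA where CC1/2 is negative (no signal, CC*
#'   undefined).
#' @export
cc_star <- function(cc_half) {
  c0 <- pmax(cc_half, 0)
  out <- sqrt(2 * c0 / (1 + c0))
  out[is.na(cc_half) | cc_half < 0] <- NA_real_
  out
}

# Rsplit over reflections present in both halves:
# 2^(-1/2) * sum|I1 - I2| / (0.5 * sum(I1 + I2)), in percent.
rsplit_value <- function(I1, I2) {
  denom <- 0.5 * sum(I1 + I2)
  if (denom == 0) return(NA_real_)
  100 * (2^(-0.5)) * sum(abs(I1 - I2)) / denom
}

#' Half-dataset merging quality metrics
#'
#' Randomly assigns whole images to two half sets (seeded), merges each
#' half independently, and over reflections present in both halves
#' computes Rsplit, CC1/2 (Pearson correlation of half-set mean
#' intensities) and CC*, overall and in equal-volume resolution bins
#' (uniform shells in 1/d^3). Mean I/sigma(I) is taken from the full merge.
#'
#' @param obs a [reflection_obs()].
#' @param n_bins number of resolution bins (default 10).
#' @param seed RNG seed for the half-set split.
#' @param cell,space_group override attributes of `obs`.
#' @return list with `overall` (n_images, n_common, rsplit_pct, cc_half,
#'   cc_star, mean_i_over_sigma, d_min, d_max), `bins` (per-bin data
#'   frame) and `half_assignment` (image id -> 1/2).
#' @export
half_set_metrics <- function(obs, n_bins = 10, seed = 1,
                             cell = attr(obs, "cell"),
                             space_group = attr(obs, "space_group")) {
  ids <- unique(obs$image_id)
  if (length(ids) < 2L)
    stop("need at least 2 images to form half sets", call. = FALSE)
  half <- with_seed(seed, {
    h <- rep(1:2, length.out = length(ids))
    sample(h)
  })
  names(half) <- as.character(ids)
  in_half1 <- half[as.character(obs$image_id)] == 1L
  m1 <- merge_observations(obs[in_half1, , drop = FALSE], cell, space_group)
  m2 <- merge_observations(obs[!in_half1, , drop = FALSE], cell, space_group)
  full <- merge_observations(obs, cell, space_group)

  key1 <- paste(m1$h, m1$k, m1$l)
  key2 <- paste(m2$h, m2$k, m2$l)
  common <- intersect(key1, key2)
  i1 <- m1$I[match(common, key1)]
  i2 <- m2$I[match(common, key2)]
  d_common <- m1$d[match(common, key1)]

  mean_isig <- mean(full$I / full$sigma, na.rm = TRUE)
  overall <- list(n_images = length(ids), n_common = length(common),
                  rsplit_pct = rsplit_value(i1, i2),
                  cc_half = if (length(common) >= 3)
                    stats::cor(i1, i2) else NA_real_,
                  mean_i_over_sigma = mean_isig,
                  d_min = min(full$d), d_max = max(full$d))
  overall$cc_star <- cc_star(overall$cc_half)

  bins <- NULL
  if (length(common) > 0) {
    edges <- volume_bin_edges(min(d_common), max(d_common), n_bins)
    bi <- volume_bin_index(d_common, edges)
    full_bi <- volume_bin_index(full$d, edges)
    bins <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
      sel <- bi == b
      cc <- if (sum(sel) >= 3) stats::cor(i1[sel], i2[sel]) else NA_real_
      data.frame(bin = b, d_low = edges[b], d_high = edges[b + 1],
                 n_common = sum(sel),
                 rsplit_pct = if (any(sel)) rsplit_value(i1[sel], i2[sel])
                 else NA_real_,
                 cc_half = cc, cc_star = cc_star(cc),
                 mean_i_over_sigma = if (any(full_bi == b))
                   mean(full$I[full_bi == b] / full$sigma[full_bi == b],
                        na.rm = TRUE) else NA_real_)
    }))
  }
  list(overall = overall, bins = bins, half_assignment = half)
}

#' Completeness of a merged set
#'
#' Observed unique reflections divided by all symmetry-unique reflections
#' (screw-axis absences excluded) in the resolution range, in percent;
#' overall and per equal-volume bin.
#'
#' @param merged a [merge_observations()] result.
#' @param d_limits `c(d_min, d_max)` resolution range, Angstrom.
#' @param n_bins number of resolution bins (default 10).
#' @return list with `overall_pct` and per-bin data frame `bins`.
#' @export
completeness <- function(merged, d_limits, n_bins = 10) {
  if (d_limits[1] > d_limits[2])
    stop("'d_limits' must be c(d_min, d_max) with d_min <= d_max",
         call. = FALSE)
  cell <- attr(merged, "cell")
  sg <- attr(merged, "space_group")
  ref <- unique_reflections(cell, sg, d_min = d_limits[1],
                            d_max = d_limits[2])
  obs_key <- paste(merged$h, merged$k, merged$l)
  ref_key <- paste(ref$h, ref$k, ref$l)
  seen <- ref_key %in% obs_key
  edges <- volume_bin_edges(d_limits[1], d_limits[2], n_bins)
  bi <- volume_bin_index(ref$d, edges)
  bins <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    n_ref <- sum(bi == b)
    data.frame(bin = b, d_low = edges[b], d_high = edges[b + 1],
               n_possible = n_ref, n_observed = sum(seen[bi == b]),
               completeness_pct = if (n_ref > 0)
                 100 * sum(seen[bi == b]) / n_ref else NA_real_)
  }))
  list(overall_pct = 100 * sum(seen) / length(seen), bins = bins)
}

#' Wilson B factor from merged intensities
#'
#' Least-squares slope of `ln <I>` versus `s^2 = (1/(2d))^2` over
#' resolution bins with `d < fit_d_max`, with `I ~ exp(-2 B s^2)`, so
#' `B = -slope / 2`. Bins with non-positive mean intensity are skipped;
#' fewer than 3 usable bins is an error.
#'
#' @param merged a [merge_observations()] result.
#' @param fit_d_max low-resolution limit of the fit range, Angstrom
#'   (default 4.5, avoiding the non-Wilson low-resolution regime).
#' @param n_bins number of equal-volume bins over the fit range.
#' @return list with `b_factor` (Angstrom^2), `slope`, and the per-bin fit
#'   table.
#' @export
wilson_b <- function(merged, fit_d_max = 4.5, n_bins = 20) {
  sel <- merged$d < fit_d_max
  if (sum(sel) < 3) stop("too few reflections below fit_d_max",
                         call. = FALSE)
  d <- merged$d[sel]
  I <- merged$I[sel]
  edges <- volume_bin_edges(min(d), max(d), n_bins)
  bi <- volume_bin_index(d, edges)
  tab <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    if (!any(bi == b)) return(NULL)
    data.frame(s2 = mean((1 / (2 * d[bi == b]))^2),
               mean_I = mean(I[bi == b]), n = sum(bi == b))
  }))
  tab <- tab[tab$mean_I > 0, , drop = FALSE]
  if (nrow(tab) < 3) stop("fewer than 3 usable Wilson bins", call. = FALSE)
  fit <- stats::lm(log(mean_I) ~ s2, data = tab, weights = tab$n)
  slope <- unname(stats::coef(fit)[2])
  list(b_factor = -slope / 2, slope = slope, bins = tab)
}

#' Automatic high-resolution cutoff
#'
#' Splits the merged data into `n_bins` equal-volume resolution bins,
#' computes mean I/sigma(I) per bin, and walks from low to high
#' resolution: the cutoff is the inner (high-resolution) d edge of the
#' last bin whose mean I/sigma(I) is still > 1.0 before the first bin that
#' fails — a first-crossing rule, even if later bins recover. If every bin
#' passes, the overall d_min is returned; if the first bin already fails,
#' there is no usable data and an error is raised.
#'
#' @param obs a [reflection_obs()] (merged internally) or a
#'   [merge_observations()] result.
#' @param n_bins number of resolution bins (default 20).
#' @param cell,space_group used when `obs` are raw observations.
#' @return list with `d_cutoff` (Angstrom) and the per-bin table.
#' @export
auto_resolution_cutoff <- function(obs, n_bins = 20,
                                   cell = attr(obs, "cell"),
                                   space_group = attr(obs, "space_group")) {
  merged <- if (inherits(obs, "merged_set")) obs else
    merge_observations(obs, cell, space_group)
  edges <- volume_bin_edges(min(merged$d), max(merged$d), n_bins)
  bi <- volume_bin_index(merged$d, edges)
  isig <- vapply(seq_len(n_bins), function(b) {
    if (!any(bi == b)) return(NA_real_)
    mean(merged$I[bi == b] / merged$sigma[bi == b], na.rm = TRUE)
  }, 0)
  tab <- data.frame(bin = seq_len(n_bins), d_low = edges[-length(edges)],
                    d_high = edges[-1], mean_i_over_sigma = isig)
  pass <- !is.na(isig) & isig > 1.0
  if (!pass[1])
    stop("lowest-resolution bin already has I/sigma <= 1: no usable data",
         call. = FALSE)
  first_fail <- which(!pass)[1]
  d_cut <- if (is.na(first_fail)) min(merged$d) else
    tab$d_high[first_fail - 1L]
  list(d_cutoff = d_cut, bins = tab)
}
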