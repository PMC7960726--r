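# Orthorhombic reflection bookkeeping: d-spacings, reduction to the mmm
# asymmetric unit, screw-axis systematic absences, and enumeration of the
# symmetry-unique reflection list.

#' Resolution of reflections in an orthorhombic cell
#'
#' `1/d^2 = h^2/a^2 + k^2/b^2 + l^2/c^2`.
#'
#' @param h,k,l Miller indices (vectorised).
#' @param cell cell edges `c(a, b, c)` in Angstrom (angles are 90 degrees).
#' @return d-spacings, Angstrom.
#' @export
d_spacing <- function(h, k, l, cell) {
  stopifnot(length(cell) >= 3, all(cell[1:3] > 0))
  1 / sqrt(h^2 / cell[1]^2 + k^2 / cell[2]^2 + l^2 / cell[3]^2)
}

# Reduce hkl to the mmm asymmetric unit (h,k,l >= 0): point group mmm plus
# Friedel symmetry maps every reflection to |h|,|k|,|l|.
asu_mmm <- function(h, k, l) list(h = abs(h), k = abs(k), l = abs(l))

# P212121 screw-axis absences: axial reflections with odd index.
is_absent_p212121 <- function(h, k, l) {
  (k == 0 & l == 0 & h %% 2 == 1) |
    (h == 0 & l == 0 & k %% 2 == 1) |
    (h == 0 & k == 0 & l %% 2 == 1)
}

check_space_group <- function(space_group) {
  sg <- gsub("[ _]", "", space_group)
  if (!toupper(sg) %in% c("P212121", "P222"))
    stop("unsupported space group '", space_group,
         "' (orthorhombic P212121 or P222)", call. = FALSE)
  toupper(sg)
}

#' Enumerate symmetry-unique reflections
#'
#' All mmm-unique reflections of an orthorhombic cell with `d_min <= d <=
#' d_max`, excluding F000 and (for P212121) the 2_1 screw-axis systematic
#' absences h00 (h odd), 0k0 (k odd), 00l (l odd).
#'
#' @param cell cell edges `c(a, b, c)`, Angstrom.
#' @param space_group "P212121" (default) or "P222".
#' @param d_min high-resolution limit, Angstrom.
#' @param d_max low-resolution limit, Angstrom (default Inf).
#' @return data frame h, k, l, d.
#' @export
unique_reflections <- function(cell, space_group = "P212121", d_min,
                               d_max = Inf) {
  check_positive(d_min, "d_min")
  sg <- check_space_group(space_group)
  hmax <- floor(cell[1] / d_min)
  kmax <- floor(cell[2] / d_min)
  lmax <- floor(cell[3] / d_min)
  g <- expand.grid(h = 0:hmax, k = 0:kmax, l = 0:lmax)
  g <- g[!(g$h == 0 & g$k == 0 & g$l == 0), ]
  g$d <- d_spacing(g$h, g$k, g$l, cell)
  g <- g[g$d >= d_min & g$d <= d_max, ]
  if (sg == "P212121")
    g <- g[!is_absent_p212121(g$h, g$k, g$l), ]
  rownames(g) <- NULL
  g
}

# Equal-volume resolution bin edges in 1/d^3 (uniform reciprocal-space
# shell volume per bin). Returns a vector of d edges from d_max to d_min.
volume_bin_edges <- function(d_min, d_max, n_bins) {
  if (!is.finite(d_max)) d_max <- 1e6
  s3 <- seq(1 / d_max^3, 1 / d_min^3, length.out = n_bins + 1)
  (1 / s3)^(1 / 3)
}

# Assign d values to equal-volume bins; bin 1 = lowest resolution.
volume_bin_index <- function(d, edges) {
  idx <- findInterval(-d, -edges, rightmost.closed = TRUE)
  pmin(pmax(idx, 1L), length(edges) - 1L)
}
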