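# Shared fixtures: tiny hand-built models, peak lists and independent
# brute-force oracles used across the suite.

peak_list <- function(d, snr, sigma = rep(10, length(d))) {
  data.frame(d = d, I = snr * sigma, sigma = sigma)
}

# Independent oracle for image_resolution: explicit min-scan loop.
oracle_image_resolution <- function(pl, thr = 4) {
  best <- NA_real_
  for (i in seq_len(nrow(pl))) {
    if (pl$I[i] / pl$sigma[i] >= thr) {
      if (is.na(best) || pl$d[i] < best) best <- pl$d[i]
    }
  }
  best
}

# Independent oracle for the unique-reflection count: expand the full
# +/-hmax grid, reduce every reflection by |h|,|k|,|l|, drop duplicates,
# and remove screw-axis absent representatives.
oracle_unique_count <- function(cell, d_min, d_max = Inf) {
  hmax <- floor(cell[1] / d_min)
  kmax <- floor(cell[2] / d_min)
  lmax <- floor(cell[3] / d_min)
  g <- expand.grid(h = -hmax:hmax, k = -kmax:kmax, l = -lmax:lmax)
  g <- g[!(g$h == 0 & g$k == 0 & g$l == 0), ]
  d <- 1 / sqrt(g$h^2 / cell[1]^2 + g$k^2 / cell[2]^2 + g$l^2 / cell[3]^2)
  g <- g[d >= d_min & d <= d_max, ]
  key <- unique(paste(abs(g$h), abs(g$k), abs(g$l)))
  hkl <- do.call(rbind, lapply(strsplit(key, " "), as.integer))
  absent <- (hkl[, 2] == 0 & hkl[, 3] == 0 & hkl[, 1] %% 2 == 1) |
    (hkl[, 1] == 0 & hkl[, 3] == 0 & hkl[, 2] %% 2 == 1) |
    (hkl[, 1] == 0 & hkl[, 2] == 0 & hkl[, 3] %% 2 == 1)
  sum(!absent)
}

# Minimal CA-only model from a coordinate matrix.
toy_model <- function(xyz, chain = "A") {
  structure_model(data.frame(
    chain = chain, resno = seq_len(nrow(xyz)), resid = "ALA",
    elety = "CA", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    b = 0, o = 1, stringsAsFactors = FALSE))
}

# Non-degenerate 3D point cloud for superposition tests.
random_cloud <- function(n, seed = 1) {
  set.seed(seed)
  matrix(stats::rnorm(3 * n, sd = 10), ncol = 3)
}

rot_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

# Hand-assembled merged set (already-reduced reflections) for cutoff tests.
fake_merged <- function(d, I, sigma, cell = c(30, 40, 50)) {
  out <- data.frame(h = seq_along(d), k = 0L, l = 1L, d = d, I = I,
                    sigma = sigma, multiplicity = 1L)
  out <- out[order(-out$d), ]
  attr(out, "cell") <- cell
  attr(out, "space_group") <- "P212121"
  class(out) <- c("merged_set", "data.frame")
  out
}
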