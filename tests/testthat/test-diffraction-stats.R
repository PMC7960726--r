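test_that("per-image resolution applies the inclusive SNR threshold", {
  pl <- peak_list(d = c(2.2, 2.8, 3.4), snr = c(3.5, 4.0, 9))
  expect_equal(image_resolution(pl), 2.8)
  expect_true(is.na(image_resolution(peak_list(c(2, 3), c(1, 3.9)))))
  expect_equal(image_resolution(peak_list(3.0, 5)), 3.0)
  expect_true(is.na(image_resolution(peak_list(numeric(0), numeric(0)))))
})

test_that("per-image resolution matches a brute-force oracle on random lists", {
  set.seed(51)
  for (i in 1:1000) {
    n <- sample(0:12, 1)
    pl <- peak_list(d = runif(n, 1.5, 12), snr = runif(n, 0, 10))
    expect_identical(image_resolution(pl), oracle_image_resolution(pl))
  }
})

test_that("probe-energy binning reports median and error of the mean", {
  b <- bin_by_probe_energy(c(3.0, 3.2, 3.4), c(0.5, 0.6, 0.7), c(0, 1, 2))
  expect_equal(b$n, c(3, 0))
  expect_equal(b$median_resolution[1], 3.2)
  expect_equal(b$error_of_mean[1], sd(c(3, 3.2, 3.4)) / sqrt(3))
  expect_true(is.na(b$median_resolution[2]))
  one <- bin_by_probe_energy(3.1, 0.5, c(0, 1))
  expect_true(is.na(one$error_of_mean[1]))
})

test_that("energy equalization subsamples to the per-bin minimum", {
  # bin counts A = (10, 20), B = (15, 5) -> equalized (10, 5)
  ea <- c(runif(10, 0, 1), runif(20, 1, 2))
  eb <- c(runif(15, 0, 1), runif(5, 1, 2))
  eq <- equalize_energy_distributions(ea, eb, c(0, 1, 2), seed = 2)
  expect_equal(sum(ea[eq$idx_a] <= 1), 10)
  expect_equal(sum(ea[eq$idx_a] > 1), 5)
  expect_equal(sum(eb[eq$idx_b] <= 1), 10)
  expect_equal(sum(eb[eq$idx_b] > 1), 5)

  # identical distributions: unchanged up to ordering
  eq2 <- equalize_energy_distributions(ea, ea, c(0, 1, 2), seed = 3)
  expect_equal(eq2$idx_a, seq_along(ea))
  expect_equal(eq2$idx_b, seq_along(ea))

  # disjoint supports: both empty
  eq3 <- equalize_energy_distributions(runif(5, 0, 1), runif(5, 1, 2),
                                       c(0, 1, 2), seed = 4)
  expect_length(eq3$idx_a, 0)
  expect_length(eq3$idx_b, 0)
})

test_that("merging counts multiplicities and applies mmm/Friedel symmetry", {
  cell <- c(30, 40, 50)
  obs <- reflection_obs(data.frame(
    h = c(1, 1, 1, 0), k = c(0, 0, 0, 1), l = c(0, 0, 0, 0),
    I = c(10, 12, 14, 5), sigma = 1, image_id = c(1, 2, 3, 1)),
    cell = cell)
  m <- merge_observations(obs)
  expect_equal(sort(m$multiplicity), c(1, 3))
  expect_equal(m$I[m$h == 1 & m$k == 0], 12)

  # Friedel mates merge into one record
  obs2 <- reflection_obs(data.frame(h = c(2, -2), k = c(3, -3),
                                    l = c(1, -1), I = c(8, 10), sigma = 1,
                                    image_id = c(1, 2)), cell = cell)
  m2 <- merge_observations(obs2)
  expect_equal(nrow(m2), 1)
  expect_equal(m2$I, 9)
  expect_equal(m2$multiplicity, 2)

  # single observations pass through unchanged
  obs3 <- reflection_obs(data.frame(h = 1:3, k = 0, l = 1, I = c(1, 2, 3),
                                    sigma = 0.5, image_id = 1),
                         cell = cell)
  m3 <- merge_observations(obs3)
  expect_equal(sort(m3$I), c(1, 2, 3))
  expect_equal(m3$sigma, rep(0.5, 3))
})

test_that("merge conserves observation counts on random data", {
  mi <- wilson_intensities(cell = c(25, 30, 35), d_min = 3.5, seed = 6)
  obs <- generate_reflection_observations(mi, n_images = 15, seed = 7)
  m <- merge_observations(obs)
  expect_equal(sum(m$multiplicity), nrow(obs))
})

test_that("Rsplit matches hand arithmetic and its zero law", {
  # two images as the two halves: I1 = (100, 50), I2 = (90, 60)
  cell <- c(30, 40, 50)
  obs <- reflection_obs(data.frame(
    h = c(1, 2, 1, 2), k = 1, l = 1, I = c(100, 50, 90, 60),
    sigma = 1, image_id = c(1, 1, 2, 2)), cell = cell)
  hs <- half_set_metrics(obs, n_bins = 1, seed = 1)
  expect_equal(hs$overall$rsplit_pct, 100 * 2^(-0.5) * 20 / 150,
               tolerance = 1e-12)
  expect_error(half_set_metrics(obs[obs$image_id == 1, ]), "2 images")
})

test_that("CC* follows its closed form and is monotone", {
  expect_equal(round(cc_star(0.705), 3), 0.909)
  expect_equal(round(cc_star(0.857), 3), 0.961)
  cc <- seq(0.05, 1, by = 0.05)
  expect_true(all(diff(cc_star(cc)) > 0))
  expect_equal(cc_star(1), 1)
})

test_that("completeness agrees with the brute-force enumeration oracle", {
  cell <- c(14, 17, 23)
  for (dmin in c(3, 4, 5)) {
    u <- unique_reflections(cell, "P212121", d_min = dmin)
    expect_equal(nrow(u), oracle_unique_count(cell, dmin))
  }
  # screw-axis absences are excluded from the unique list
  u <- unique_reflections(cell, "P212121", d_min = 3)
  expect_false(any(u$k == 0 & u$l == 0 & u$h %% 2 == 1))

  # a merged set holding every unique reflection is 100% complete
  u$I <- 1
  u$sigma <- 1
  u$image_id <- 1
  m_all <- merge_observations(reflection_obs(u, cell = cell))
  comp <- completeness(m_all, c(3, max(u$d)))
  expect_equal(comp$overall_pct, 100)

  # exactly half the unique list: 50%
  half <- u[seq(1, nrow(u), by = 2), ]
  m_half <- merge_observations(reflection_obs(half, cell = cell))
  comp2 <- completeness(m_half, c(3, max(u$d)))
  expect_equal(comp2$overall_pct, 100 * nrow(half) / nrow(u))
  expect_error(completeness(m_all, c(10, 3)), "d_limits")
})

test_that("completeness is monotone as observations are added", {
  cell <- c(14, 17, 23)
  u <- unique_reflections(cell, "P212121", d_min = 3)
  set.seed(52)
  u <- u[sample(nrow(u)), ]
  u$I <- 1; u$sigma <- 1; u$image_id <- 1
  prev <- 0
  for (frac in c(0.2, 0.5, 0.8, 1)) {
    sub <- u[seq_len(ceiling(frac * nrow(u))), ]
    m <- merge_observations(reflection_obs(sub, cell = cell))
    val <- completeness(m, c(3, max(u$d)))$overall_pct
    expect_gte(val, prev)
    expect_lte(val, 100)
    prev <- val
  }
})

test_that("Wilson B recovery from planted fall-offs", {
  # noise-free smooth envelope: recovery within 0.5 A^2
  mi <- wilson_intensities(cell = c(30, 40, 50), d_min = 2.8,
                           b_factor = 50, modulate = FALSE)
  expect_lt(abs(wilson_b(mi)$b_factor - 50), 0.5)

  # flat intensities: B = 0
  flat <- mi
  flat$I <- 1
  expect_lt(abs(wilson_b(flat)$b_factor), 1e-10)

  # planted 47.4 with 5% multiplicative noise: within 5%
  set.seed(53)
  noisy <- wilson_intensities(cell = c(30, 40, 50), d_min = 2.8,
                              b_factor = 47.4, modulate = FALSE)
  noisy$I <- noisy$I * (1 + rnorm(nrow(noisy), 0, 0.05))
  expect_lt(abs(wilson_b(noisy)$b_factor - 47.4) / 47.4, 0.05)
})

test_that("automatic resolution cutoff follows the first-crossing rule", {
  n_bins <- 20
  d <- seq(20, 2.0, length.out = 400)

  # monotone I/sigma crossing 1.0 partway: cutoff at the last passing edge
  I <- seq(40, 0.2, length.out = 400)
  cut <- auto_resolution_cutoff(fake_merged(d, I, rep(1, 400)),
                                n_bins = n_bins)
  fail <- which(!(cut$bins$mean_i_over_sigma > 1))[1]
  expect_equal(cut$d_cutoff, cut$bins$d_high[fail - 1])
  expect_gt(cut$d_cutoff, 2.0)

  # all bins passing: cutoff equals the overall d_min
  cut2 <- auto_resolution_cutoff(fake_merged(d, rep(50, 400), rep(1, 400)),
                                 n_bins = n_bins)
  expect_equal(cut2$d_cutoff, 2.0)

  # a non-monotone dip below 1.0 terminates at the first crossing even
  # though later bins recover
  edges_d <- (1 / seq(1 / 20^3, 1 / 2^3, length.out = n_bins + 1))^(1 / 3)
  bin_of <- function(dd) findInterval(-dd, -edges_d, rightmost.closed = TRUE)
  I3 <- ifelse(bin_of(d) == 7, 0.5, 50)
  cut3 <- auto_resolution_cutoff(fake_merged(d, I3, rep(1, 400)),
                                 n_bins = n_bins)
  expect_equal(cut3$d_cutoff, cut3$bins$d_high[6])

  # no usable data at all
  expect_error(auto_resolution_cutoff(fake_merged(d, rep(0.5, 400),
                                                  rep(1, 400)),
                                      n_bins = n_bins),
               "no usable data")
})

test_that("equal-volume bins populate uniformly in 1/d^3", {
  # uniform sampling in 1/d^3 should fill bins near-evenly
  set.seed(54)
  s3 <- runif(4000, 1 / 10^3, 1 / 2^3)
  d <- (1 / s3)^(1 / 3)
  edges <- shockjet:::volume_bin_edges(2, 10, 8)
  idx <- shockjet:::volume_bin_index(d, edges)
  counts <- tabulate(idx, 8)
  expect_lt(max(abs(counts - 500)) / 500, 0.15)
})
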