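test_that("config validation names the offending field", {
  expect_error(simulation_config(noise_trace_fraction = 1.2),
               "noise_trace_fraction")
  expect_error(simulation_config(jet_speed = -1), "jet_speed")
  expect_error(simulation_config(energy_anticorrelation = 0.5),
               "energy_anticorrelation")
  expect_error(simulation_config(pump_probe_delay = NaN),
               "pump_probe_delay")
})

test_that("pump and probe energies reach the requested anti-correlation", {
  cfg <- simulation_config(n_shots = 2000, mode_fraction_pump_probe = 1,
                           energy_anticorrelation = -0.7, seed = 3)
  s <- generate_shot_series(cfg, components = "peaks")
  r <- cor(s$truth$pump_energy, s$truth$probe_energy)
  expect_gt(r, -0.8)
  expect_lt(r, -0.6)
})

test_that("degenerate configurations propagate to null effects", {
  # no hits at zero hit probability: every peak list is below 10 peaks
  cfg0 <- simulation_config(n_shots = 300, hit_probability_base = 0,
                            seed = 4)
  s0 <- generate_shot_series(cfg0, components = "peaks")
  npk <- vapply(s0$shots, function(x) nrow(x$peaks), 0L)
  expect_true(all(npk < 10))
  expect_false(any(s0$truth$true_hit))

  # zero damage: pump-probe and single-pulse true resolutions agree
  cfgn <- simulation_config(n_shots = 4000, damage_coefficient = 0,
                            hit_damage_coefficient = 0, seed = 5)
  sn <- generate_shot_series(cfgn, components = "peaks")
  tr <- sn$truth
  dmed <- median(tr$true_resolution[tr$mode == "pump_probe"]) -
    median(tr$true_resolution[tr$mode == "single"])
  expect_lt(abs(dmed), 0.05)
})

test_that("identical seed and config give identical output", {
  cfg <- simulation_config(n_shots = 60, seed = 9)
  a <- generate_shot_series(cfg)
  b <- generate_shot_series(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$shots[[7]]$peaks, b$shots[[7]]$peaks)
  expect_identical(a$shots[[7]]$traces$masked$samples,
                   b$shots[[7]]$traces$masked$samples)
  expect_identical(shot_jet_image(a$shots[[3]]),
                   shot_jet_image(b$shots[[3]]))
})

test_that("rendered gaps are recovered by the extractor (round trip)", {
  img <- render_jet_image(60, 200, 30, 10, gaps = list(c(40, 60)),
                          seed = 1)
  f <- extract_jet_features(img, um_per_px = 1)
  expect_length(f$gaps_um, 1)
  expect_lt(abs(gap_centre(f, 1) - 50), 2)

  # no gaps, no break-up: continuous at every queried row
  img2 <- render_jet_image(60, 200, 30, 10, seed = 2)
  f2 <- extract_jet_features(img2, um_per_px = 1)
  expect_length(f2$gaps_um, 0)
  expect_true(all(vapply(seq(0, 199, by = 10), function(p)
    jet_continuous_upstream(f2, p), TRUE)))

  # two planted gaps -> exactly two detected
  img3 <- render_jet_image(60, 200, 30, 10,
                           gaps = list(c(120, 130), c(140, 150)), seed = 3)
  f3 <- extract_jet_features(img3, um_per_px = 1)
  expect_length(f3$gaps_um, 2)

  expect_error(render_jet_image(60, 200, 30, 10,
                                gaps = list(c(40, 60), c(50, 70))),
               "overlap")
  expect_error(render_jet_image(60, 200, 30, 0.5), "jet_width_px")
})

test_that("PGM round trip preserves the image to 8-bit precision", {
  img <- render_jet_image(40, 80, 20, 8, gaps = list(c(30, 40)), seed = 8)
  path <- tempfile(fileext = ".pgm")
  write_pgm(img, path)
  back <- read_pgm(path)
  expect_equal(dim(back), dim(img))
  expect_lt(max(abs(back - img)), 1 / 255)
})

test_that("noise-free identical-scale observations give Rsplit 0", {
  mi <- wilson_intensities(cell = c(25, 30, 35), d_min = 3.5, seed = 1)
  obs <- generate_reflection_observations(mi, n_images = 20, scale_sd = 0,
                                          noise_sd = 0, seed = 2)
  hs <- half_set_metrics(obs, n_bins = 4, seed = 3)
  expect_equal(hs$overall$rsplit_pct, 0)
  expect_equal(hs$overall$cc_half, 1, tolerance = 1e-12)
  expect_equal(hs$overall$cc_star, 1, tolerance = 1e-12)
})

test_that("CC1/2 decreases monotonically with observation noise", {
  mi <- wilson_intensities(cell = c(25, 30, 35), d_min = 3.5, scale = 100,
                           seed = 1)
  mean_cc <- vapply(c(1, 4, 12), function(noise) {
    mean(vapply(1:20, function(rep) {
      obs <- generate_reflection_observations(
        mi, n_images = 16, scale_sd = 0.05, noise_sd = noise,
        seed = 100 * noise + rep)
      half_set_metrics(obs, n_bins = 4, seed = rep)$overall$cc_half
    }, 0))
  }, 0)
  expect_true(all(diff(mean_cc) < 0))
})

test_that("single-image observation sets are rejected", {
  mi <- wilson_intensities(cell = c(25, 30, 35), d_min = 4, seed = 1)
  expect_error(generate_reflection_observations(mi, n_images = 1),
               "half-set")
  mi_bad <- mi
  mi_bad$I[1] <- -1
  expect_error(generate_reflection_observations(mi_bad, n_images = 5),
               "positive")
})

test_that("structure pair generator plants exactly what it reports", {
  ref <- synthetic_globin_model()

  # compaction 1, zero field: displacement identically zero
  p0 <- generate_structure_pair(ref, list(amplitude = 0, wavelength = 25),
                                compaction = 1, noise_sd = 0,
                                n_images = 3, seed = 1)
  expect_equal(max(abs(p0$truth$displacement_field)), 0)
  expect_equal(as.matrix(p0$model$atoms[c("x", "y", "z")]),
               as.matrix(ref$atoms[c("x", "y", "z")]),
               ignore_attr = TRUE)

  # pure compaction is a similarity transform: -1% distances, Rg ratio 0.99
  p1 <- generate_structure_pair(ref, list(amplitude = 0),
                                compaction = 0.99, noise_sd = 0,
                                n_images = 3, seed = 1)
  expect_equal(radius_of_gyration(p1$model) / radius_of_gyration(ref),
               0.99, tolerance = 1e-12)

  # planted field has the requested RMS amplitude
  p2 <- generate_structure_pair(ref, list(amplitude = 0.3,
                                          wavelength = 25),
                                compaction = 1, noise_sd = 0,
                                n_images = 3, seed = 2)
  expect_equal(sqrt(mean(rowSums(p2$truth$displacement_field^2))), 0.3,
               tolerance = 1e-12)

  expect_error(generate_structure_pair(ref, compaction = 0.85), "compaction")
})

test_that("shot series exports to plain-text files", {
  cfg <- simulation_config(n_shots = 20, run_size = 10, seed = 13)
  s <- generate_shot_series(cfg)
  dir <- tempfile("series")
  write_shot_series(s, dir, images = TRUE)
  expect_true(all(file.exists(file.path(
    dir, c("shots.tsv", "ground_truth.json", "peaks.tsv", "traces.tsv")))))
  tab <- read_tsv_table(file.path(dir, "shots.tsv"))
  expect_equal(nrow(tab), 20)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(gt$pump_energy, s$truth$pump_energy, tolerance = 1e-12)
  img <- read_pgm(file.path(dir, "jets", paste0(s$shots[[1]]$shot_id,
                                                ".pgm")))
  expect_equal(dim(img), c(cfg$image_height_px, cfg$image_width_px))
})
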