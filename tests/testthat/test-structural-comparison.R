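test_that("pairing matches residues by chain and number", {
  ref <- synthetic_globin_model()
  p <- pair_models(ref, ref)
  expect_equal(nrow(p$keys), 574)

  # drop 22 residues from B (disordered termini): 552 pairs remain
  b <- ref
  drop <- c(paste("A", 1:6), paste("B", 1:6), paste("C", 1:5),
            paste("D", 1:5))
  keep <- !(paste(b$atoms$chain, b$atoms$resno) %in% drop)
  b$atoms <- b$atoms[keep, ]
  p2 <- pair_models(ref, b)
  expect_equal(nrow(p2$keys), 552)
  expect_equal(length(p2$unmatched_a), 22)

  # renamed chains with no mapping: no common residues
  c_mod <- b
  c_mod$atoms$chain <- paste0("X", c_mod$atoms$chain)
  expect_error(pair_models(ref, c_mod), "no common")
})

test_that("Kabsch superposition recovers rigid transforms exactly", {
  xyz <- random_cloud(100, seed = 61)
  a <- toy_model(xyz)
  b_xyz <- sweep(xyz %*% t(rot_z(pi / 2)), 2, c(5, -3, 7), `+`)
  b <- toy_model(b_xyz)
  p <- pair_models(a, b)
  sup <- superpose(p)
  expect_lt(sup$rmsd, 1e-10)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-10)

  # self-superposition: identity rotation to numerical tolerance
  sup_self <- superpose(pair_models(a, a))
  expect_lt(max(abs(sup_self$rotation - diag(3))), 1e-10)
  expect_lt(sup_self$rmsd, 1e-10)
})

test_that("superposition RMSD under isotropic noise matches sqrt(3) sigma", {
  xyz <- random_cloud(500, seed = 62)
  set.seed(63)
  noise <- matrix(rnorm(1500, 0, 0.1), ncol = 3)
  sup <- superpose(pair_models(toy_model(xyz), toy_model(xyz + noise)))
  expect_lt(abs(sup$rmsd - 0.1 * sqrt(3)) / (0.1 * sqrt(3)), 0.1)
})

test_that("reflections are never absorbed into the rotation", {
  xyz <- random_cloud(50, seed = 64)
  mirror <- xyz
  mirror[, 1] <- -mirror[, 1]
  sup <- superpose(pair_models(toy_model(xyz), toy_model(mirror)))
  expect_equal(det(sup$rotation), 1, tolerance = 1e-10)
  expect_gt(sup$rmsd, 1)   # a proper rotation cannot undo a mirror
})

test_that("superposed RMSD never exceeds the unsuperposed value", {
  set.seed(65)
  for (i in 1:20) {
    xyz <- random_cloud(40, seed = 600 + i)
    b_xyz <- xyz + matrix(rnorm(120, 0, 0.5), ncol = 3) +
      matrix(runif(3, -2, 2), 40, 3, byrow = TRUE)
    p <- pair_models(toy_model(xyz), toy_model(b_xyz))
    raw <- sqrt(mean(rowSums((p$xyz_b - p$xyz_a)^2)))
    expect_lte(superpose(p)$rmsd, raw + 1e-12)
  }
})

test_that("displacement fields recover planted correlated motion", {
  ref <- synthetic_globin_model()
  p0 <- pair_models(ref, ref)
  d0 <- displacement_field(p0)
  expect_lt(max(d0$length), 1e-10)

  pr <- generate_structure_pair(ref, list(amplitude = 0.3,
                                          wavelength = 25),
                                compaction = 1, noise_sd = 0,
                                n_images = 3, seed = 66)
  p <- pair_models(ref, pr$model)
  df <- displacement_field(p, superpose_first = TRUE)
  planted <- pr$truth$displacement_field
  expect_gt(cor(c(df$dx, df$dy, df$dz), c(planted)), 0.99)

  # arrow export is exactly 10x the unscaled vectors
  expect_equal(df$arrow_dx, 10 * df$dx)
  expect_equal(sqrt(df$arrow_dx^2 + df$arrow_dy^2 + df$arrow_dz^2),
               10 * df$length)
})

test_that("distance-difference matrices obey exact geometric laws", {
  ref <- synthetic_globin_model()
  p_id <- pair_models(ref, ref)
  ddm0 <- distance_difference_matrix(p_id)
  expect_equal(max(abs(ddm0$delta)), 0)

  # uniform 0.99 scaling: every off-diagonal relative entry is -1%
  pr <- generate_structure_pair(ref, list(amplitude = 0),
                                compaction = 0.99, noise_sd = 0,
                                n_images = 3, seed = 67)
  ddm <- distance_difference_matrix(pair_models(ref, pr$model))
  off <- ddm$relative[upper.tri(ddm$relative)]
  expect_equal(range(off), c(-0.01, -0.01), tolerance = 1e-9)

  # symmetry, zero diagonal, rigid-motion invariance
  xyz <- random_cloud(30, seed = 68)
  b_xyz <- xyz + matrix(rnorm(90, 0, 0.3), ncol = 3)
  p <- pair_models(toy_model(xyz), toy_model(b_xyz))
  dd <- distance_difference_matrix(p)
  expect_equal(dd$delta, t(dd$delta))
  expect_equal(diag(dd$delta), rep(0, 30), ignore_attr = TRUE)
  b_rot <- sweep(b_xyz %*% t(rot_z(1.1)), 2, c(3, 4, 5), `+`)
  dd2 <- distance_difference_matrix(pair_models(toy_model(xyz),
                                                toy_model(b_rot)))
  expect_equal(dd$delta, dd2$delta, tolerance = 1e-9)

  # hand-worked 3-atom geometry: D23 = 3*sqrt(2) - 5
  a3 <- toy_model(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0)))
  b3 <- toy_model(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0)))
  dd3 <- distance_difference_matrix(pair_models(a3, b3))
  expect_equal(dd3$delta[2, 3], 3 * sqrt(2) - 5, tolerance = 1e-12)
})

test_that("radius of gyration follows its closed form", {
  expect_equal(radius_of_gyration(toy_model(matrix(c(1, 2, 3), 1))), 0)
  four <- toy_model(rbind(c(1, 1, 0), c(1, -1, 0), c(-1, 1, 0),
                          c(-1, -1, 0)))
  expect_equal(radius_of_gyration(four), sqrt(2))
  # homogeneity: uniform scaling scales Rg exactly
  xyz <- random_cloud(80, seed = 69)
  expect_equal(radius_of_gyration(toy_model(xyz * 1.7)),
               1.7 * radius_of_gyration(toy_model(xyz)))
})

test_that("bootstrap coordinate error matches the closed form sigma/sqrt(m)", {
  ref <- synthetic_globin_model()
  pr <- generate_structure_pair(ref, list(amplitude = 0), compaction = 1,
                                noise_sd = 0.1, n_images = 50, seed = 71)
  eng <- surrogate_engine(pr$observations)
  ens <- bootstrap_ensemble(dimnames(pr$observations)[[3]], eng,
                            n_boot = 100, seed = 72)
  target <- 0.1 / sqrt(50)
  expect_lt(abs(mean(ens$sd) - target) / target, 0.25)

  # zero-noise observations: degenerate zero-SD ensemble
  pr0 <- generate_structure_pair(ref, list(amplitude = 0), compaction = 1,
                                 noise_sd = 0, n_images = 10, seed = 73)
  ens0 <- bootstrap_ensemble(dimnames(pr0$observations)[[3]],
                             surrogate_engine(pr0$observations),
                             n_boot = 10, seed = 74)
  chk <- two_sigma_check(ens0, ens0$mean)
  expect_true(chk$degenerate)
  expect_equal(chk$fraction_within, 1)

  expect_error(bootstrap_ensemble(1:10, eng, n_boot = 1), "n_boot")
})

test_that("bootstrap error converges with ensemble size", {
  xyz <- random_cloud(40, seed = 75)
  pr <- generate_structure_pair(toy_model(xyz), list(amplitude = 0),
                                compaction = 1, noise_sd = 0.1,
                                n_images = 50, seed = 76)
  ens <- bootstrap_ensemble(dimnames(pr$observations)[[3]],
                            surrogate_engine(pr$observations),
                            n_boot = 1000, seed = 77)
  target <- 0.1 / sqrt(50)
  expect_lt(abs(mean(ens$sd) - target) / target, 0.10)
})

test_that("correlated displacements are significant where single atoms are not", {
  ref <- synthetic_globin_model()
  pr <- generate_structure_pair(ref, list(amplitude = 0.11,
                                          wavelength = 50),
                                compaction = 1, noise_sd = 0.4,
                                n_images = 50, seed = 78)
  ens <- bootstrap_ensemble(dimnames(pr$observations)[[3]],
                            surrogate_engine(pr$observations),
                            n_boot = 200, seed = 79)
  planted <- pr$truth$displacement_field

  # individual-atom significance is rare: per-atom error ~0.5/sqrt(50)
  err_atom <- sqrt(rowMeans(ens$sd^2))
  disp <- sqrt(rowSums((ens$mean -
                          as.matrix(ref$atoms[c("x", "y", "z")]))^2))
  expect_lt(mean(disp > 5 * err_atom), 0.25)

  # a coherent same-direction cluster of chain A is detected at > 5 sigma
  selA <- which(ref$atoms$chain == "A")
  w <- selA[which(planted[selA, 1] > 0.7 * max(planted[selA, 1]))]
  expect_gt(length(w), 8)
  cluster_means <- apply(ens$models[w, 1, ], 2, mean)
  obs_mean <- mean(ens$mean[w, 1]) - mean(ref$atoms$x[w])
  se <- sd(cluster_means)
  expect_gt(abs(obs_mean) / se, 5)
})

test_that("comparison report summarises displacement and compaction", {
  ref <- synthetic_globin_model()
  same <- compare_report(ref, ref)
  expect_equal(same$rmsd, 0, tolerance = 1e-10)
  expect_equal(same$mean_displacement, 0, tolerance = 1e-10)

  pr <- generate_structure_pair(ref, list(amplitude = 0.05,
                                          wavelength = 25),
                                compaction = 0.995, noise_sd = 0,
                                n_images = 3, seed = 80)
  rep_ <- compare_report(ref, pr$model)
  expect_true(rep_$net_compaction)
  expect_lt(rep_$rg_b / rep_$rg_a, 1)
  expect_equal(rep_$n_pairs, 574)
})
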