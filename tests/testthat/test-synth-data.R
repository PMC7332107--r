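test_that("empty scene is pure background with empty truth", {
  sc <- generate_snapshot_scene(scene_config(n_cells = 0, stray_fraction = 0,
                                             rng_seed = 1))
  expect_equal(nrow(sc$truth), 0)
  expect_true(all(sc$masks == 0L))
  expect_equal(mean(sc$image), 100, tolerance = 0.02)
})

test_that("rendered cluster masses match planted fractions without noise", {
  sc <- generate_snapshot_scene(
    scene_config(n_cells = 1, shot_noise = FALSE, read_noise_sd = 0,
                 stray_fraction = 0, rng_seed = 2))
  tr <- sc$truth
  bgsub <- sc$image - sc$config$background_level
  total <- sum(bgsub)  # all signal belongs to the single cell
  for (k in 1:2) {
    ctr_t <- c(tr[[paste0("pole", k, "_x")]], tr[[paste0("pole", k, "_y")]])
    other <- c(tr[[paste0("pole", 3 - k, "_x")]],
               tr[[paste0("pole", 3 - k, "_y")]])
    u <- (other - ctr_t) / sqrt(sum((other - ctr_t)^2))
    ctr <- ctr_t + 2 * u
    foot <- mxpolarity:::disc_pixels(ctr, 5, ncol(sc$image), nrow(sc$image))
    diffuse_in_foot <- tr$total_true *
      (1 - tr$p1_true - tr$p2_true) / sum(sc$masks == 1) *
      sum(sc$masks[foot] == 1)
    frac <- (sum(bgsub[foot]) - diffuse_in_foot) / total
    expect_equal(unname(frac), unname(tr[[paste0("p", k, "_true")]]),
                 tolerance = 0.01, ignore_attr = TRUE)
  }
  # planted total is conserved in the rendered image
  expect_equal(total, tr$total_true, tolerance = 0.02 * tr$total_true)
})

test_that("scene generation is bit-identical under a fixed seed", {
  a <- generate_snapshot_scene(scene_config(n_cells = 5, rng_seed = 7))
  b <- generate_snapshot_scene(scene_config(n_cells = 5, rng_seed = 7))
  expect_identical(a$image, b$image)
  expect_identical(a$masks, b$masks)
  expect_identical(a$truth, b$truth)
})

test_that("placement failure errors with the failing cell count", {
  cfg <- scene_config(image_width = 120, image_height = 120, n_cells = 40,
                      rng_seed = 1)
  expect_error(generate_snapshot_scene(cfg), "place cell")
})

test_that("inversion dynamics follow the configured Markov switching", {
  base <- scene_config(n_cells = 10, image_width = 700, image_height = 700)
  tl0 <- generate_timelapse(base, timelapse_config(n_frames = 8,
                                                   inversion_prob = 0,
                                                   division_prob = 0),
                            seed = 3)
  dom <- tapply(tl0$truth$p1_true > tl0$truth$p2_true,
                tl0$truth$cell_id, function(x) length(unique(x)))
  expect_true(all(dom == 1))

  tl1 <- generate_timelapse(base, timelapse_config(n_frames = 8,
                                                   inversion_prob = 1,
                                                   division_prob = 0),
                            seed = 3)
  flips <- tapply(tl1$truth$p1_true > tl1$truth$p2_true,
                  tl1$truth$cell_id, function(x) all(diff(x) != 0))
  expect_true(all(flips))

  tl <- generate_timelapse(scene_config(n_cells = 20, image_width = 900,
                                        image_height = 900),
                           timelapse_config(n_frames = 12,
                                            inversion_prob = 0.39,
                                            division_prob = 0),
                           seed = 4)
  realized <- mean(tl$truth$inverted_this_frame[tl$truth$frame > 1])
  n <- sum(tl$truth$frame > 1)
  expect_lt(abs(realized - 0.39), 3 * sqrt(0.39 * 0.61 / n))
})

test_that("division bookkeeping records lineage and old poles", {
  tl <- generate_timelapse(scene_config(n_cells = 12, image_width = 800,
                                        image_height = 800),
                           timelapse_config(n_frames = 10,
                                            inversion_prob = 0,
                                            division_prob = 0.15),
                           seed = 9)
  daughters <- unique(tl$truth$cell_id[!is.na(tl$truth$parent_id)])
  expect_gt(length(daughters), 0)
  expect_true(all(tl$truth$old_pole[!is.na(tl$truth$parent_id)] == 1L))
  # daughters appear in pairs with a common parent
  fam <- table(tl$truth$parent_id[!duplicated(tl$truth$cell_id) &
                                    !is.na(tl$truth$parent_id)])
  expect_true(all(fam == 2))
})

test_that("induction series encodes the cooperativity signature", {
  flat <- generate_induction_series(induction_config(hill_coefficient = 1))
  expect_equal(length(unique(round(flat$p1_frac, 12))), 1)
  expect_equal(flat$p1_frac[1] / (flat$p1_frac[1] + flat$p2_frac[1]),
               3 / 4)  # asymmetry_ratio 3

  expect_equal(mxpolarity:::induction_fraction(0, 0.3, 2, 30), 0)

  hill2 <- generate_induction_series(induction_config(hill_coefficient = 2,
                                                      n_timepoints = 50))
  expect_true(all(diff(hill2$p1_frac) > 0))
  expect_lt(max(hill2$p1_frac), 0.3)  # saturating below capacity
})

test_that("strain sampler recovers target moments and respects truncation", {
  one <- generate_strain_sample(0.3, 1, diag(1e-4, 2), 500, seed = 1)
  expect_lt(mean(one$P2), 0.02)

  s <- generate_strain_sample(0.212, 0.5, diag(0.02^2, 2), 10000, seed = 2)
  expect_lt(abs(mean(s$P1 + s$P2) - 0.212), 0.01 * 0.212)
  omega_hat <- mean((s$P1 - s$P2) / (s$P1 + s$P2))
  expect_lt(abs(omega_hat - 0.5), 0.02)
  expect_true(all(s$P1 >= 0 & s$P2 >= 0 & s$P1 + s$P2 <= 1))

  fixed <- generate_strain_sample(0.2, 0.4, 0, 50, seed = 3)
  expect_equal(nrow(unique(fixed)), 1)

  expect_error(generate_strain_sample(1.5, 0.5, 0, 10), "mean_total")
  expect_error(generate_strain_sample(0.5, 1.5, 0, 10), "omega")
  expect_error(generate_strain_sample(0.2, 0.4, diag(c(1, -1)), 10),
               "semidefinite")
})
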