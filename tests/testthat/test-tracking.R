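geom_row <- function(cell_id, p1, p2, f1 = 0.2, f2 = 0.1, frame = 1L) {
  tibble::tibble(frame = frame, cell_id = cell_id,
                 pole1_x = p1[1], pole1_y = p1[2],
                 pole2_x = p2[1], pole2_y = p2[2],
                 p_pole1 = f1, p_pole2 = f2)
}

test_that("identical frames link as the same cells with no divisions", {
  prev <- dplyr::bind_rows(geom_row(1L, c(0, 0), c(70, 0)),
                           geom_row(2L, c(0, 50), c(70, 50)))
  out <- link_frames(prev, prev)
  expect_true(all(out$link == "same"))
  expect_equal(out$prev_id, prev$cell_id)
  expect_true(all(!out$swap))
})

test_that("a split cell yields two daughters with correct old poles", {
  prev <- geom_row(1L, c(0, 0), c(120, 0))
  cur <- dplyr::bind_rows(geom_row(2L, c(0, 0), c(55, 0)),
                          geom_row(3L, c(65, 0), c(120, 0)))
  out <- link_frames(prev, cur)
  expect_equal(out$link, c("daughter", "daughter"))
  expect_equal(out$prev_id, c(1L, 1L))
  expect_equal(out$old_pole, c(1L, 2L))  # the retained outer poles
})

test_that("displacement beyond the threshold creates a new cell", {
  prev <- geom_row(1L, c(0, 0), c(70, 0))
  cur <- geom_row(1L, c(45, 45), c(115, 45))  # both poles > 40 px away
  out <- link_frames(prev, cur)
  expect_equal(out$link, "new")
  expect_true(is.na(out$old_pole))
})

test_that("single-frame gaps are merged, longer gaps are not", {
  g <- dplyr::bind_rows(
    geom_row(1L, c(0, 0), c(70, 0), frame = 1L),
    geom_row(1L, c(0, 0), c(70, 0), frame = 2L),
    geom_row(9L, c(1, 0), c(71, 0), frame = 4L),
    geom_row(9L, c(1, 0), c(71, 0), frame = 5L))
  tr <- track_cells(g)
  expect_equal(length(unique(tr$track_id)), 2)
  merged <- merge_gap_tracks(tr)
  expect_equal(length(unique(merged$track_id)), 1)

  g2 <- dplyr::bind_rows(
    geom_row(1L, c(0, 0), c(70, 0), frame = 1L),
    geom_row(9L, c(1, 0), c(71, 0), frame = 5L))
  tr2 <- track_cells(g2)
  expect_identical(merge_gap_tracks(tr2)$track_id, tr2$track_id)

  # no gaps: unchanged
  g3 <- dplyr::bind_rows(geom_row(1L, c(0, 0), c(70, 0), frame = 1L),
                         geom_row(1L, c(0, 0), c(70, 0), frame = 2L))
  tr3 <- track_cells(g3)
  expect_identical(merge_gap_tracks(tr3), tr3)
})

test_that("drift-free tracking reproduces the generator identities", {
  tl <- generate_timelapse(
    scene_config(n_cells = 15, image_width = 800, image_height = 800),
    timelapse_config(n_frames = 10, inversion_prob = 0.2,
                     division_prob = 0, drift_sd = 0),
    seed = 6)
  tr <- track_cells(tl$truth)
  expect_equal(length(unique(tr$track_id)), 15)
  # every track follows exactly one generator cell
  map <- table(tr$track_id, tr$cell_id)
  expect_true(all(rowSums(map > 0) == 1))
})

test_that("inversion probability counts dominant-pole flips", {
  mono <- make_tracks(data.frame(track_id = 1L, frame = 1:5,
                                 P_A = seq(0.3, 0.2, length.out = 5),
                                 P_B = 0.1))
  expect_equal(inversion_probability(mono)$probability, 0)

  alt <- make_tracks(data.frame(track_id = 1L, frame = 1:6,
                                P_A = rep(c(0.3, 0.1), 3),
                                P_B = rep(c(0.1, 0.3), 3)))
  expect_equal(inversion_probability(alt)$probability, 1)

  # ties are never inversions
  tie <- make_tracks(data.frame(track_id = 1L, frame = 1:3,
                                P_A = c(0.2, 0.2, 0.3),
                                P_B = c(0.2, 0.2, 0.1)))
  expect_equal(inversion_probability(tie)$probability, 0)

  expect_error(inversion_probability(mono[1, ]), "eligible")
})

test_that("inversion estimator matches the generator switching rate", {
  tl <- generate_timelapse(
    scene_config(n_cells = 25, image_width = 900, image_height = 900),
    timelapse_config(n_frames = 25, inversion_prob = 0.2,
                     division_prob = 0, drift_sd = 0.5),
    seed = 14)
  tr <- track_cells(tl$truth)
  inv <- inversion_probability(tr)
  expect_gt(inv$n_pairs, 500)
  se <- sqrt(0.2 * 0.8 / inv$n_pairs)
  expect_lt(abs(inv$probability - 0.2), 3 * se)
})

test_that("old-pole bias after division is recovered and tested", {
  tl <- generate_timelapse(
    scene_config(n_cells = 60, image_width = 1500, image_height = 1500),
    timelapse_config(n_frames = 15, inversion_prob = 0,
                     division_prob = 0.15, old_pole_bias_prob = 0.64),
    seed = 10)
  tr <- track_cells(tl$truth)
  pb <- pole_bias_after_division(tr)
  expect_gt(pb$n, 50)
  se <- sqrt(0.64 * 0.36 / pb$n)
  expect_lt(abs(pb$bias_fraction - 0.64), 3 * se)

  # all cells biased: fraction 1 and decisive test
  allb <- make_tracks(data.frame(track_id = rep(1:12, each = 2),
                                 frame = rep(c(1L, 2L), 12),
                                 P_A = 0.3, P_B = 0.1,
                                 old_pole = "A"))
  pb2 <- pole_bias_after_division(allb)
  expect_equal(pb2$bias_fraction, 1)
  expect_lt(pb2$p_value, 0.001)

  expect_error(pole_bias_after_division(make_tracks(
    data.frame(track_id = 1L, frame = 1L, P_A = 0.2, P_B = 0.1))),
    "post-division")
})

test_that("autocorrelation is 1 at lag 0 and ~0 for white noise", {
  set.seed(3)
  n_tracks <- 40
  n_frames <- 30
  wn <- make_tracks(data.frame(
    track_id = rep(seq_len(n_tracks), each = n_frames),
    frame = rep(seq_len(n_frames), n_tracks),
    P_A = runif(n_tracks * n_frames, 0, 0.4),
    P_B = runif(n_tracks * n_frames, 0, 0.4)))
  ac <- polar_autocorrelation(wn, max_lag = 5)
  expect_equal(ac$C[ac$lag == 0], 1, tolerance = 1e-12)
  for (k in 1:5) {
    expect_lt(abs(ac$C[ac$lag == k]), 3 / sqrt(ac$n_pairs[ac$lag == k]))
  }

  # frozen asymmetry with frame-independent means: C = 1 at every lag
  frozen <- make_tracks(data.frame(
    track_id = rep(1:6, each = 10),
    frame = rep(1:10, 6),
    P_A = rep(seq(0.05, 0.3, length.out = 6), each = 10),
    P_B = rep(seq(0.3, 0.05, length.out = 6), each = 10)))
  ac2 <- polar_autocorrelation(frozen, max_lag = 4)
  expect_equal(ac2$C, rep(1, 5), tolerance = 1e-10)

  # a frame with zero cross-pole variance is skipped with a warning
  flat <- make_tracks(data.frame(track_id = rep(1:3, each = 2),
                                 frame = rep(1:2, 3),
                                 P_A = c(0.1, 0.2, 0.1, 0.3, 0.1, 0.4),
                                 P_B = c(0.1, 0.1, 0.1, 0.2, 0.1, 0.3)))
  expect_warning(polar_autocorrelation(flat, max_lag = 1), "variance")
})

test_that("leading pole follows the direction of motion", {
  base <- data.frame(track_id = 1L, frame = 1:2,
                     poleA_x = c(70, 84), poleA_y = 0,
                     poleB_x = c(0, 14), poleB_y = 0,
                     P_A = 0.2, P_B = 0.1)
  tr <- assign_leading_lagging(make_tracks(base))
  expect_equal(tr$leading_pole, c(NA, "A"))  # 20% of length toward A

  small <- base
  small$poleA_x <- c(70, 73.5)
  small$poleB_x <- c(0, 3.5)  # 5% displacement
  tr2 <- assign_leading_lagging(make_tracks(small))
  expect_true(all(is.na(tr2$leading_pole)))

  rev <- data.frame(track_id = 1L, frame = 1:3,
                    poleA_x = c(70, 84, 70), poleA_y = 0,
                    poleB_x = c(0, 14, 0), poleB_y = 0,
                    P_A = 0.2, P_B = 0.1)
  tr3 <- assign_leading_lagging(make_tracks(rev))
  expect_equal(tr3$leading_pole, c(NA, "A", "B"))
})
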