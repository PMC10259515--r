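test_that("the 90-degree inversion criterion is strict", {
  make_ser <- function(final) angle_series(pair_from_angles(seq(0, final, length.out = 20)))
  expect_true(classify_inversion(make_ser(150)))
  expect_false(classify_inversion(make_ser(60)))
  expect_false(classify_inversion(make_ser(90))) # exactly critical: not inverting
  expect_true(classify_inversion(make_ser(-150))) # absolute cumulative angle
  expect_true(classify_inversion(make_ser(60), critical_angle_deg = 50))
})

test_that("overshoot measures the return from the maximal turn", {
  expect_equal(overshoot(angle_series(pair_from_angles(c(seq(0, 180, 10), rep(180, 5))))), 0)
  rise_settle <- c(seq(0, 200, 10), seq(195, 180, -5))
  expect_equal(overshoot(angle_series(pair_from_angles(rise_settle))), 20)
  reversal <- c(seq(0, 180, 10), seq(170, 0, -10))
  expect_equal(overshoot(angle_series(pair_from_angles(reversal))), 180)
})

test_that("wobbling is the arc in excess of the net turn", {
  expect_equal(wobbling(angle_series(pair_from_angles(seq(0, 170, 10)))), 0)
  ser <- angle_series(pair_from_angles(cumsum(c(0, 10, -10, 180))))
  expect_equal(tail(ser$arc_deg, 1), 200)
  expect_equal(tail(ser$turn_deg, 1), 180)
  expect_equal(wobbling(ser), 20)
  # pure rocking back to start: wobbling equals the whole arc
  rock <- angle_series(pair_from_angles(c(0, 30, 0, -30, 0)))
  expect_equal(wobbling(rock), tail(rock$arc_deg, 1))
})

test_that("handedness follows the sign of the final cumulative angle", {
  expect_equal(handedness(angle_series(pair_from_angles(seq(0, 150, 10))))$handedness, "CCW")
  expect_equal(handedness(angle_series(pair_from_angles(seq(0, -150, -10))))$handedness, "CW")
  tie <- handedness(angle_series(pair_from_angles(c(0, 20, 0))))
  expect_true(tie$tie)
  expect_true(is.na(tie$handedness))
})

test_that("trajectory noise is exact on constructed paths", {
  # both cells on straight lines -> exactly 1
  n <- 20
  tr <- make_tracks(
    a = cbind(seq(0, 5, length.out = n), 0),
    b = cbind(-seq(0, 5, length.out = n), 0)
  )
  nz <- trajectory_noise(cell_pair(tr, "a", "b"))
  expect_equal(nz$noise, 1.0)
  expect_false(nz$excluded)

  # zig-zag doubling the path at fixed chord -> exactly 2
  # (independent construction: dx = 1 per step, dy alternating +/- sqrt(3),
  #  so each segment has length 2 while the chord advances by 1)
  # the fixture must be mirror-symmetric about the pair centroid: pairwise
  # centering (part of the pipeline) makes the two cells exact mirrors, so a
  # zig-zag shared by both cells would cancel
  n_steps <- 10
  x <- 0:n_steps
  y <- c(0, cumsum(rep(c(sqrt(3), -sqrt(3)), n_steps / 2)))
  tr2 <- make_tracks(a = cbind(x, y), b = cbind(-x, -y))
  nz2 <- trajectory_noise(cell_pair(tr2, "a", "b"))
  path_oracle <- sum(sqrt(diff(x)^2 + diff(y)^2)) # = 2 * chord by construction
  expect_equal(path_oracle, 2 * (max(x) - min(x)))
  expect_equal(nz2$noise, 2.0, tolerance = 1e-12)

  # per-cell-mean aggregation agrees (centered cells have equal ratios)
  expect_equal(trajectory_noise(cell_pair(tr2, "a", "b"), aggregation = "mean")$noise, 2.0)

  # sub-threshold net displacement excludes the pair
  tr3 <- make_tracks(
    a = cbind(seq(0, 1.5, length.out = n), 0), # chord 1.5 um < 2 um
    b = cbind(-seq(0, 1.5, length.out = n), 0)
  )
  nz3 <- trajectory_noise(cell_pair(tr3, "a", "b"))
  expect_true(nz3$excluded)
  expect_true(is.na(nz3$noise))
  expect_match(nz3$reason, "net displacement")

  # only the first frame_cap frames enter
  alpha <- c(seq(0, 90, length.out = 100), rep(c(90, 270), 50))
  p <- pair_from_angles(alpha)
  expect_equal(
    trajectory_noise(p, frame_cap = 100, min_displacement_um = 0)$noise,
    trajectory_noise(pair_from_angles(alpha[1:100]), min_displacement_um = 0)$noise
  )
})

test_that("rotation_metrics assembles a consistent per-pair row", {
  cfg <- default_config()
  pars <- pair_synthesis_params(wobble_sd_deg = 3)
  pair <- cell_pair(generate_pair_tracks(pars, seed = 9), "cell_a", "cell_b",
    genotype = "synthetic"
  )
  m <- rotation_metrics(pair, cfg)
  expect_s3_class(m, "rotation_metrics")
  expect_true(m$inverting)
  expect_gte(m$overshoot_deg, 0)
  expect_gte(m$wobbling_deg, 0)
  expect_gte(m$noise, 1)
  expect_equal(m$overshoot_deg, m$max_turn_deg - m$final_turn_deg)
  expect_false(m$fit_failed)
  expect_lt(abs(m$Ic_min - (pars$a_min - 2 / pars$b_per_min)), 10)
  expect_equal(m$duration_min, m$Id_min - m$Ic_min)
  expect_equal(m$onset_min, m$Ic_min) # birth at t = 0

  # non-inverting pair: no fit attempted
  rock <- cell_pair(
    generate_pair_tracks(pair_synthesis_params(
      inverting = FALSE,
      wobble_sd_deg = 2
    ), seed = 4),
    "cell_a", "cell_b",
    genotype = "synthetic"
  )
  mr <- rotation_metrics(rock, cfg)
  expect_false(mr$inverting)
  expect_true(is.na(mr$Ic_min))
})

test_that("analyze_pairs maps a cohort to one metrics row per pair", {
  cfg <- default_config()
  t1 <- generate_pair_tracks(pair_synthesis_params(), seed = 1)
  t2 <- generate_pair_tracks(pair_synthesis_params(inverting = FALSE), seed = 2)
  t2$track_id <- paste0(t2$track_id, "2")
  tracks <- rbind(t1, t2)
  class(tracks) <- c("track_table", "data.frame")
  pairs <- data.frame(
    pair_id = c("p1", "p2"),
    track_a = c("cell_a", "cell_a2"),
    track_b = c("cell_b", "cell_b2"),
    genotype = "synthetic"
  )
  m <- analyze_pairs(tracks, pairs, cfg)
  expect_equal(nrow(m), 2)
  expect_equal(m$inverting, c(TRUE, FALSE))
})
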