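test_that("positional angles follow the A-P axis convention", {
  tr <- make_tracks(
    a = rbind(c(-1, 0), c(0, -1), c(1, 1)),
    b = rbind(c(1, 0), c(0, 1), c(-1, -1))
  )
  p <- cell_pair(tr, "a", "b")
  expect_equal(positional_angle(p, frame = 0), 0)
  expect_equal(positional_angle(p, frame = 1), 90)
  expect_equal(positional_angle(p, frame = 2), -135)

  # coincident centroids are an error naming the frame
  tr2 <- make_tracks(a = rbind(c(0, 0), c(1, 1)), b = rbind(c(0, 0), c(1, 1)))
  expect_error(positional_angle(cell_pair(tr2, "a", "b")), "frame")
})

test_that("centering puts the pair midpoint at the origin and removes drift", {
  tr <- make_tracks(a = rbind(c(1, 0), c(1, 1)), b = rbind(c(3, 0), c(3, 1)))
  p <- center_pair(cell_pair(tr, "a", "b"))
  expect_equal(p$xy_a[1, ], c(x = -1, y = 0))
  expect_equal(p$xy_b[1, ], c(x = 1, y = 0))
  expect_equal(p$xy_a + p$xy_b, matrix(0, 2, 2, dimnames = list(NULL, c("x", "y"))))

  # uniformly drifting pair centers to the same trajectory
  pars <- pair_synthesis_params(wobble_sd_deg = 0)
  pars_drift <- pair_synthesis_params(
    wobble_sd_deg = 0,
    drift_um_per_min = c(0.05, -0.02)
  )
  p0 <- center_pair(cell_pair(generate_pair_tracks(pars, 1), "cell_a", "cell_b"))
  p1 <- center_pair(cell_pair(generate_pair_tracks(pars_drift, 1), "cell_a", "cell_b"))
  expect_equal(p0$xy_a, p1$xy_a, tolerance = 1e-9)
})

test_that("frame-to-frame changes take the minimal wrapped representative", {
  # independent oracle: enumerate both candidate differences, keep |.| <= 180
  wrap_oracle <- function(d) {
    cand <- c(d %% 360, d %% 360 - 360)
    cand[abs(cand) <= 180][1]
  }
  set.seed(42)
  for (d in c(10, -10, 179, -179, 185, -185, 350, -350, runif(20, -720, 720))) {
    expect_equal(wrap_angle_180(d), wrap_oracle(d), info = paste("d =", d))
  }

  # crossing the branch: 175 -> -175 is +10, not -350
  p <- pair_from_angles(c(175, -175))
  ser <- angle_series(p)
  expect_equal(ser$dalpha_deg[2], 10)

  # simple CCW and CW sequences
  expect_equal(tail(angle_series(pair_from_angles(c(0, 10, 20)))$cum_deg, 1), 20)
  expect_equal(tail(angle_series(pair_from_angles(c(20, 10, 0)))$cum_deg, 1), -20)
})

test_that("turn never exceeds arc, with equality only for monotone series", {
  set.seed(7)
  for (i in 1:20) {
    alpha <- cumsum(runif(30, -40, 50))
    ser <- angle_series(pair_from_angles(alpha))
    expect_true(all(ser$turn_deg <= ser$arc_deg + 1e-9))
  }
  mono <- angle_series(pair_from_angles(seq(0, 170, by = 10)))
  expect_equal(mono$turn_deg, mono$arc_deg)
})

test_that("rigid rotation shifts angles but leaves rotation scalars invariant", {
  set.seed(11)
  alpha <- cumsum(c(30, runif(40, -10, 25)))
  base <- pair_from_angles(alpha)
  ser0 <- angle_series(base)
  m0 <- list(
    turn = tail(ser0$turn_deg, 1), wob = wobbling(ser0),
    over = overshoot(ser0),
    noise = trajectory_noise(base, min_displacement_um = 0)$noise
  )
  for (theta0 in c(33, 120, -77)) {
    rot <- pair_from_angles(alpha + theta0)
    ser <- angle_series(rot)
    expect_equal(tail(ser$turn_deg, 1), m0$turn, tolerance = 1e-9)
    expect_equal(wobbling(ser), m0$wob, tolerance = 1e-9)
    expect_equal(overshoot(ser), m0$over, tolerance = 1e-9)
    expect_equal(trajectory_noise(rot, min_displacement_um = 0)$noise,
      m0$noise,
      tolerance = 1e-9
    )
    d0 <- wrap_angle_180(ser$alpha_deg[1] - ser0$alpha_deg[1])
    expect_equal(d0, wrap_angle_180(theta0), tolerance = 1e-9)
  }
})

test_that("mirror reflection about the x axis negates the cumulative angle", {
  set.seed(13)
  alpha <- cumsum(c(20, runif(30, -15, 30)))
  p <- pair_from_angles(alpha)
  q <- p
  q$xy_a[, 2] <- -q$xy_a[, 2]
  q$xy_b[, 2] <- -q$xy_b[, 2]
  sp <- angle_series(p)
  sq <- angle_series(q)
  expect_equal(sq$cum_deg, -sp$cum_deg, tolerance = 1e-9)
  expect_equal(handedness(sq)$handedness, "CW")
  expect_equal(handedness(sp)$handedness, "CCW")
})

test_that("circular means are correct at the branch cut", {
  # oracle: explicit unit-vector averaging
  circ_oracle <- function(a) {
    v <- colMeans(cbind(cos(a * pi / 180), sin(a * pi / 180)))
    atan2(v[2], v[1]) * 180 / pi
  }
  angles <- c(178, -178, 179, -179, 177, -177, 178, -176, 179, -175)
  expect_equal(circular_mean_deg(angles), circ_oracle(angles))
  expect_gt(abs(circular_mean_deg(angles)), 170) # near 180, never near 0

  ser <- angle_series(pair_from_angles(c(angles, angles)))
  sf <- start_final_angles(ser)
  expect_gt(abs(sf$starting_angle_deg), 170)

  # constant series
  sf2 <- start_final_angles(angle_series(pair_from_angles(rep(30, 12))))
  expect_equal(sf2$starting_angle_deg, 30, tolerance = 1e-9)
  expect_equal(sf2$final_angle_deg, 30, tolerance = 1e-9)
  expect_false(sf2$short)
  # short series flagged
  expect_true(start_final_angles(angle_series(pair_from_angles(rep(10, 5))))$short)
})

test_that("axis-angle normalizations match their modular oracles", {
  set.seed(5)
  for (a in c(210, 350, 90, 180, 0, runif(20, -720, 720))) {
    expect_equal(normalize_angle_0_180(a), ((a %% 360) %% 180), info = a)
  }
  expect_equal(normalize_angle_0_180(210), 30)
  expect_equal(normalize_angle_0_180(350), 170)

  expect_equal(final_angle_first_quadrant(c(1, 0), c(-1, 0)), 0)
  expect_equal(final_angle_first_quadrant(c(0, 1), c(0, -1)), 90)
  expect_equal(final_angle_first_quadrant(c(1, 1), c(-1, -1)), 45)
  expect_error(final_angle_first_quadrant(c(1, 1), c(1, 1)), "coincident")
})
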