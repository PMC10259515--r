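#' Configuration of the two-cell Metropolis rotation model
#'
#' Each sibling is a particle on a circle, its angle to the A-P (x) axis the
#' only degree of freedom, moving on a `step_deg` lattice. The cells repel
#' through the repulsive r^-12 term of a Lennard-Jones potential on circular
#' distance, with maximum interaction distance `d_int = 180` degrees so the
#' pair interacts over the whole domain, and each cell is attracted by one
#' Gaussian well of depth `omega` centered at `mu`. Wells are switched off
#' during an initial breaking time. Sampling follows a Metropolis-Hastings
#' rule with Boltzmann acceptance at inverse temperature `beta`.
#'
#' Defaults: the well width `sigma = 240` degrees puts the attractors in the
#' wide-well (quasi-harmonic) regime, in which the stationary compromise of
#' two competing wells depends only on their relative depth - the regime the
#' empirical final-angle behaviour selects (see the methods vignette and
#' [calibrate_well_width()]); `beta = 2` and `n_steps = 200000` let a
#' half-domain rotation complete with margin at that width.
#'
#' @param rho repulsion strength (>= 0; overlap is rejected regardless).
#' @param omega1,omega2 well depths (>= 0).
#' @param mu1,mu2 well centers, degrees.
#' @param sigma well width (SD), degrees.
#' @param d_int maximum interaction distance, degrees, in (0, 180].
#' @param step_deg lattice interval, degrees (default 0.25).
#' @param beta inverse temperature of the Boltzmann acceptance.
#' @param n_steps total Metropolis steps.
#' @param breaking_steps steps before the wells are switched on.
#' @param init_mean_deg,init_sd_deg normal distribution of the initial
#'   inter-cell axis angle (default 180 +/- 50 degrees).
#' @param init_independent draw the two initial positions independently from
#'   the normal instead of placing the cells diametrically opposed on the
#'   drawn axis.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(rho = 1, omega1 = 50, omega2 = 0,
                       mu1 = 0, mu2 = 180,
                       sigma = 240, d_int = 180, step_deg = 0.25,
                       beta = 2, n_steps = 200000, breaking_steps = 2000,
                       init_mean_deg = 180, init_sd_deg = 50,
                       init_independent = FALSE) {
  stopifnot(
    rho >= 0, omega1 >= 0, omega2 >= 0, sigma > 0,
    d_int > 0, d_int <= 180, step_deg > 0, beta > 0,
    n_steps > breaking_steps, breaking_steps >= 0, init_sd_deg >= 0
  )
  structure(
    list(
      rho = rho, omega1 = omega1, omega2 = omega2, mu1 = mu1, mu2 = mu2,
      sigma = sigma, d_int = d_int, step_deg = step_deg, beta = beta,
      n_steps = as.integer(n_steps), breaking_steps = as.integer(breaking_steps),
      init_mean_deg = init_mean_deg, init_sd_deg = init_sd_deg,
      init_independent = init_independent
    ),
    class = "sim_config"
  )
}

#' Circular distance between two angles
#'
#' Shorter arc between two directions on the circle, in `[0, 180]` degrees.
#'
#' @param theta_a,theta_b angles in degrees (vectorized).
#' @return distances in degrees.
#' @export
circular_distance <- function(theta_a, theta_b) {
  d <- abs((theta_a - theta_b) %% 360)
  pmin(d, 360 - d)
}

#' Soft-sphere repulsion energy
#'
#' Repulsive r^-12 Lennard-Jones term on circular distance:
#' `U = (d_int / delta)^12`, unit at the maximum interaction distance,
#' strictly decreasing in the separation and symmetric under swapping the
#' cells. Coincident positions have infinite energy (their proposal is always
#' rejected).
#'
#' @param theta1,theta2 cell angles, degrees.
#' @param d_int maximum interaction distance, degrees.
#' @return energy (dimensionless).
#' @export
repulsion_energy <- function(theta1, theta2, d_int = 180) {
  delta <- circular_distance(theta1, theta2)
  ifelse(delta <= 0, Inf, (d_int / delta)^12)
}

#' Gaussian attractor well energy
#'
#' `V = -exp(-dist(theta, mu)^2 / (2 sigma^2))` on circular distance;
#' minimum -1 at the well center, tending to zero far away.
#'
#' @param theta cell angle, degrees.
#' @param mu well center, degrees.
#' @param sigma well width, degrees.
#' @return energy in `[-1, 0)`.
#' @export
well_energy <- function(theta, mu, sigma) {
  d <- circular_distance(theta, mu)
  -exp(-d^2 / (2 * sigma^2))
}

#' System Hamiltonian
#'
#' `H = rho U_rep + [wells_active] (omega1 V(theta1; mu1) +
#' omega2 V(theta2; mu2))`. Before the breaking time the wells are inactive.
#'
#' @param theta1,theta2 cell angles, degrees.
#' @param config a [sim_config()].
#' @param wells_active logical.
#' @return energy (dimensionless).
#' @export
hamiltonian <- function(theta1, theta2, config, wells_active = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  h <- config$rho * repulsion_energy(theta1, theta2, config$d_int)
  if (wells_active) {
    h <- h + config$omega1 * well_energy(theta1, config$mu1, config$sigma) +
      config$omega2 * well_energy(theta2, config$mu2, config$sigma)
  }
  h
}

#' One Metropolis-Hastings update (reference implementation)
#'
#' Chooses one cell uniformly, proposes a one-lattice-step move in a uniform
#' direction, and accepts with probability `min(1, exp(-beta dH))`; on
#' rejection the cell does not move. Draws exactly three uniforms in fixed
#' order, matching the compiled chain, so both engines are interchangeable
#' under a common seed.
#'
#' @param state list with `theta1`, `theta2`, `energy`.
#' @param config a [sim_config()].
#' @param wells_active logical.
#' @return updated state with an `accepted` flag.
#' @export
metropolis_step <- function(state, config, wells_active = TRUE) {
  u_cell <- runif(1)
  u_dir <- runif(1)
  u_acc <- runif(1)
  delta <- if (u_dir < 0.5) -config$step_deg else config$step_deg
  prop <- state
  if (u_cell < 0.5) {
    prop$theta1 <- (state$theta1 + delta) %% 360
  } else {
    prop$theta2 <- (state$theta2 + delta) %% 360
  }
  h_new <- hamiltonian(prop$theta1, prop$theta2, config, wells_active)
  dh <- h_new - state$energy
  acc <- is.finite(h_new) && (dh <= 0 || u_acc < exp(-config$beta * dh))
  if (acc) {
    state <- prop
    state$energy <- h_new
  }
  state$accepted <- acc
  state
}

snap_to_lattice <- function(theta, step_deg) {
  (round(theta / step_deg) * step_deg) %% 360
}

#' Run the two-cell Metropolis rotation model
#'
#' Initializes the inter-cell axis angle from
#' `Normal(init_mean_deg, init_sd_deg)` snapped to the lattice and places the
#' two cells diametrically opposed on that axis (siblings in contact on
#' opposite sides of the pair center); with `init_independent = TRUE` each
#' cell's angle is drawn independently instead. Runs `n_steps` updates with
#' the wells off for the first `breaking_steps`. Same seed, same trajectory.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param engine `"cpp"` (default) or the R reference loop `"r"` (slow; for
#'   cross-checks).
#' @return object of class `sim_trajectory`: list with per-step `theta1`,
#'   `theta2`, `energy`, `accepted`, and the `config` and `seed` used.
#' @export
run_simulation <- function(config, seed, engine = c("cpp", "r")) {
  stopifnot(inherits(config, "sim_config"))
  engine <- match.arg(engine)
  withr::with_seed(seed, {
    if (config$init_independent) {
      th1 <- snap_to_lattice(rnorm(1, config$init_mean_deg, config$init_sd_deg),
        config$step_deg)
      th2 <- snap_to_lattice(rnorm(1, config$init_mean_deg, config$init_sd_deg),
        config$step_deg)
    } else {
      phi <- snap_to_lattice(rnorm(1, config$init_mean_deg, config$init_sd_deg),
        config$step_deg)
      th1 <- phi
      th2 <- (phi - 180) %% 360
    }
    if (th1 == th2) th2 <- (th2 + config$step_deg) %% 360 # no superposition
    res <- if (engine == "cpp") {
      .mh_run_cpp(
        th1, th2, config$rho, config$omega1, config$omega2,
        config$mu1, config$mu2, config$sigma, config$d_int,
        config$step_deg, config$beta, config$n_steps, config$breaking_steps
      )
    } else {
      mh_run_r(th1, th2, config)
    }
    structure(
      c(res, list(config = config, seed = seed)),
      class = "sim_trajectory"
    )
  })
}

mh_run_r <- function(th1, th2, config) {
  n <- config$n_steps
  theta1 <- theta2 <- energy <- numeric(n + 1)
  accepted <- logical(n)
  active <- config$breaking_steps <= 0
  state <- list(
    theta1 = th1, theta2 = th2,
    energy = hamiltonian(th1, th2, config, active)
  )
  theta1[1] <- th1
  theta2[1] <- th2
  energy[1] <- state$energy
  for (i in seq_len(n)) {
    if (!active && i > config$breaking_steps) {
      active <- TRUE
      state$energy <- hamiltonian(state$theta1, state$theta2, config, active)
    }
    state <- metropolis_step(state, config, wells_active = active)
    theta1[i + 1] <- state$theta1
    theta2[i + 1] <- state$theta2
    energy[i + 1] <- state$energy
    accepted[i] <- state$accepted
  }
  list(theta1 = theta1, theta2 = theta2, energy = energy, accepted = accepted)
}

#' @export
print.sim_trajectory <- function(x, ...) {
  cat(sprintf(
    "sim_trajectory: %d steps (wells on after %d), final theta = (%.2f, %.2f) deg\n",
    x$config$n_steps, x$config$breaking_steps,
    tail(x$theta1, 1), tail(x$theta2, 1)
  ))
  invisible(x)
}

#' Convert a simulated trajectory to a cell-pair record
#'
#' Subsamples the chain to `n_frames` equally spaced "observations" and maps
#' the two angles to positions on a circle of radius `radius_um`, yielding a
#' [cell_pair()] on which the empirical pipeline (angle series, logistic fit,
#' noise) runs unchanged.
#'
#' @param sim a `sim_trajectory`.
#' @param n_frames observations to keep (default 150).
#' @param radius_um circle radius (default 4, matching the synthetic pairs).
#' @param frame_interval_s nominal acquisition interval for the time stamps.
#' @return a `cell_pair` (genotype `"synthetic"`).
#' @export
sim_to_pair <- function(sim, n_frames = 150, radius_um = 4,
                        frame_interval_s = 200) {
  stopifnot(inherits(sim, "sim_trajectory"))
  idx <- unique(round(seq(1, length(sim$theta1), length.out = n_frames)))
  t1 <- sim$theta1[idx] * pi / 180
  t2 <- sim$theta2[idx] * pi / 180
  n <- length(idx)
  dt <- frame_interval_s / 60
  structure(
    list(
      pair_id = sprintf("sim_seed%d", sim$seed),
      genotype = "synthetic",
      frames = seq_len(n) - 1L,
      times_min = (seq_len(n) - 1) * dt,
      xy_a = cbind(x = radius_um * cos(t1), y = radius_um * sin(t1)),
      xy_b = cbind(x = radius_um * cos(t2), y = radius_um * sin(t2)),
      birth_frame = 0L,
      centered = FALSE
    ),
    class = "cell_pair"
  )
}

#' Asymmetric-model configuration
#'
#' Both wells on opposite poles of the A-P axis (`mu1 = 0`, `mu2 = 180`): a
#' cell appearing anterior has its attractor at the posterior pole and vice
#' versa, so both attractions act in concert. Default depths 50 and
#' `50 * depth_ratio` with `depth_ratio = 0` (the one-well case).
#'
#' @param depth_ratio relative well depth (shallower / deeper) in `[0, 1]`.
#' @param reference_depth depth of the deeper well (default 50).
#' @param ... overrides passed to [sim_config()].
#' @return a `sim_config`.
#' @export
make_asymmetric_config <- function(depth_ratio = 0, reference_depth = 50, ...) {
  stopifnot(depth_ratio >= 0, depth_ratio <= 1)
  sim_config(
    omega1 = reference_depth, omega2 = reference_depth * depth_ratio,
    mu1 = 0, mu2 = 180, ...
  )
}

#' Symmetric-model configuration
#'
#' Both wells on the same pole (`mu1 = mu2 = 0`), so the siblings compete for
#' one location; the deeper well (depth `reference_depth`) belongs to the
#' cell that starts away from the pole. Default `depth_ratio = 0.4` (depths
#' 50 and 20).
#'
#' @inheritParams make_asymmetric_config
#' @return a `sim_config`.
#' @export
make_symmetric_config <- function(depth_ratio = 0.4, reference_depth = 50, ...) {
  stopifnot(depth_ratio >= 0, depth_ratio <= 1)
  sim_config(
    omega1 = reference_depth, omega2 = reference_depth * depth_ratio,
    mu1 = 0, mu2 = 0, ...
  )
}

#' Relative well depth of a configuration
#'
#' Ratio of the shallower to the deeper Gaussian well depth.
#'
#' @param config a [sim_config()].
#' @return number in `[0, 1]`.
#' @export
relative_well_depth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  depths <- c(config$omega1, config$omega2)
  if (max(depths) == 0) {
    return(NA_real_)
  }
  min(depths) / max(depths)
}

#' Replicate sweep over model type and relative well depth
#'
#' For each depth ratio, runs `n_reps` seeded replicates of the chosen model,
#' converts each trajectory to a pair record and computes the final-angle
#' deviation from the A-P axis (first-quadrant angle of the mean of the last
#' ten observed inter-cell axes) and the trajectory noise through the
#' empirical pipeline (no displacement exclusion: simulated cells live on the
#' circle).
#'
#' @param model `"asymmetric"` or `"symmetric"`.
#' @param depth_ratios numeric vector of relative well depths.
#' @param n_reps replicates per ratio.
#' @param seed base seed; replicate `i` at ratio index `j` uses
#'   `seed + 1000 * j + i`.
#' @param reference_depth depth of the deeper well.
#' @param n_frames observations per replicate for the readouts.
#' @param ... overrides passed to the config constructor.
#' @return data.frame with columns `model`, `depth_ratio`, `rep`, `seed`,
#'   `final_angle_dev_deg`, `noise`, `final_turn_deg`.
#' @export
sweep_replicates <- function(model = c("asymmetric", "symmetric"),
                             depth_ratios = c(0.2, 0.4, 0.6),
                             n_reps = 100, seed = 1, reference_depth = 50,
                             n_frames = 150, ...) {
  model <- match.arg(model)
  maker <- if (model == "asymmetric") make_asymmetric_config else make_symmetric_config
  rows <- list()
  for (j in seq_along(depth_ratios)) {
    cfg <- maker(
      depth_ratio = depth_ratios[j],
      reference_depth = reference_depth, ...
    )
    for (i in seq_len(n_reps)) {
      s <- seed + 1000L * j + i
      sim <- run_simulation(cfg, seed = s)
      pair <- sim_to_pair(sim, n_frames = n_frames)
      ser <- angle_series(center_pair(pair))
      k <- min(10, nrow(ser))
      fin <- circular_mean_deg(tail(ser$alpha_deg, k)) * pi / 180
      dev <- final_angle_first_quadrant(
        c(cos(fin), sin(fin)), c(0, 0)
      )
      nz <- trajectory_noise(pair,
        frame_cap = n_frames,
        min_displacement_um = 0
      )
      rows[[length(rows) + 1]] <- data.frame(
        model = model, depth_ratio = depth_ratios[j], rep = i, seed = s,
        final_angle_dev_deg = dev, noise = nz$noise,
        final_turn_deg = tail(ser$turn_deg, 1)
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Lattice Boltzmann density of a single particle in one well
#'
#' Normalized stationary density `p(theta) propto exp(-beta omega V(theta))`
#' on the `step_deg` lattice of the circle, for comparison with empirical
#' Metropolis occupancies.
#'
#' @param omega well depth.
#' @param mu well center, degrees.
#' @param sigma well width, degrees.
#' @param beta inverse temperature.
#' @param step_deg lattice interval.
#' @return data.frame with columns `theta` and `p` (sums to 1).
#' @export
lattice_boltzmann <- function(omega, mu, sigma, beta, step_deg = 0.25) {
  theta <- seq(0, 360 - step_deg, by = step_deg)
  logw <- -beta * omega * well_energy(theta, mu, sigma)
  w <- exp(logw - max(logw))
  data.frame(theta = theta, p = w / sum(w))
}

#' Total-variation distance between two discrete distributions
#'
#' @param p,q probability vectors on the same support.
#' @return `0.5 * sum(|p - q|)`.
#' @export
tv_distance <- function(p, q) {
  stopifnot(length(p) == length(q))
  0.5 * sum(abs(p - q))
}

#' Calibration sweep for the well width
#'
#' Runs the symmetric model at relative depth 0.5 across candidate well
#' widths and reports the median final-angle deviation, making explicit which
#' widths lie in the wide-well regime whose stationary compromise
#' `180 r / (1 + r)` (60 degrees at r = 0.5) depends only on the relative
#' depth.
#'
#' @param sigmas candidate widths, degrees.
#' @param n_reps replicates per width.
#' @param seed base seed.
#' @param ... overrides passed to [make_symmetric_config()].
#' @return data.frame with columns `sigma`, `median_final_angle_dev_deg`,
#'   `n_reps`.
#' @export
calibrate_well_width <- function(sigmas = c(120, 180, 240, 300), n_reps = 25,
                                 seed = 1, ...) {
  rows <- lapply(seq_along(sigmas), function(k) {
    sw <- sweep_replicates(
      model = "symmetric", depth_ratios = 0.5, n_reps = n_reps,
      seed = seed + 10000L * k, sigma = sigmas[k], ...
    )
    data.frame(
      sigma = sigmas[k],
      median_final_angle_dev_deg = median(sw$final_angle_dev_deg),
      n_reps = n_reps
    )
  })
  do.call(rbind, rows)
}
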