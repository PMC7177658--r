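#' Configure a synthetic platoon simulation
#'
#' The generator emulates congested single-lane car-following as observed on
#' an instrumented freeway segment at 0.1 s resolution: a scripted lead
#' vehicle drives a stop-and-go speed profile and a platoon of simulated
#' drivers follows it, each reacting only to its immediate predecessor.
#' A known minority of the drivers is aggressive (short desired time gaps and
#' minimum gaps), which is the ground truth every downstream stage is tested
#' against.
#'
#' @param n_drivers Number of simulated followers (the labeled population).
#' @param aggressive_fraction Proportion of aggressive drivers, in (0, 0.5).
#' @param duration Episode duration in seconds.
#' @param dt Sampling interval (s), 0.1 by convention.
#' @param lead_base_speed,lead_amplitude,lead_period,lead_noise_sd
#'   Stop-and-go lead profile: mean speed (m/s), oscillation amplitude (m/s),
#'   period (s) and white-noise sd (m/s).
#' @param accel_noise_sd Within-driver behavioural noise: white noise on the
#'   commanded acceleration (m/s^2), so a driver's risk varies around their
#'   trait level and the two populations' ACR distributions overlap.
#' @param obs_speed_sd,obs_gap_sd,obs_accel_sd Measurement noise added to
#'   the recorded series (m/s, m, m/s^2), emulating video-extracted
#'   trajectories; acceleration noise is largest because it is a double
#'   derivative of extracted position.
#' @param seed Integer seed; every draw in the simulation flows from it.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_drivers = 299,
                       aggressive_fraction = 0.144,
                       duration = 60,
                       dt = 0.1,
                       lead_base_speed = 8,
                       lead_amplitude = 6,
                       lead_period = 40,
                       lead_noise_sd = 0.3,
                       accel_noise_sd = 0.2,
                       obs_speed_sd = 0.2,
                       obs_gap_sd = 0.3,
                       obs_accel_sd = 0.4,
                       seed = 1L) {
  if (aggressive_fraction <= 0 || aggressive_fraction >= 0.5) {
    stop_acr("aggressive_fraction must lie in (0, 0.5)", class = "acr_config_error")
  }
  if (dt <= 0 || duration <= 0 || n_drivers < 1) {
    stop_acr("n_drivers, duration and dt must be positive", class = "acr_config_error")
  }
  structure(list(n_drivers = as.integer(n_drivers),
                 aggressive_fraction = aggressive_fraction,
                 duration = duration, dt = dt,
                 lead_base_speed = lead_base_speed,
                 lead_amplitude = lead_amplitude,
                 lead_period = lead_period,
                 lead_noise_sd = lead_noise_sd,
                 accel_noise_sd = accel_noise_sd,
                 obs_speed_sd = obs_speed_sd,
                 obs_gap_sd = obs_gap_sd,
                 obs_accel_sd = obs_accel_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Population parameters. Normal drivers keep ~1.5 s time gaps; the aggressive
# minority tailgates at ~0.6 s with smaller standstill gaps and harder
# accelerations, giving overlapping but separated crash-risk distributions.
POP_NORMAL <- list(time_gap_mean = 1.5, time_gap_sd = 0.2, time_gap_min = 0.8,
                   min_gap = 2.0, max_accel = 1.4, comfy_decel = 2.0)
POP_AGGR <- list(time_gap_mean = 0.6, time_gap_sd = 0.15, time_gap_min = 0.3,
                 min_gap = 0.8, max_accel = 2.2, comfy_decel = 2.8)
VEHICLE_LENGTH <- 5  # m, all simulated vehicles

rtruncnorm1 <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= lower)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Sample a driver population with a known aggressive minority
#'
#' Draws `round(n_drivers * aggressive_fraction)` aggressive profiles and the
#' rest normal, then shuffles their platoon order so that a driver's
#' aggressiveness is independent of its leader's.
#'
#' @param config A [sim_config()].
#' @return Data frame of driver profiles: `driver_id`, `is_aggressive`,
#'   `desired_time_gap` (s), `min_gap` (m), `max_accel` (m/s^2),
#'   `comfy_decel` (m/s^2), `desired_speed` (m/s).
#' @export
sample_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_drivers
  n_aggr <- round(n * config$aggressive_fraction)
  with_seed(child_seed(config$seed, 1L), {
    is_aggr <- sample(rep(c(TRUE, FALSE), c(n_aggr, n - n_aggr)))
    draw <- function(p, m) {
      data.frame(
        desired_time_gap = rtruncnorm1(m, p$time_gap_mean, p$time_gap_sd,
                                       p$time_gap_min),
        min_gap = pmax(0.3, stats::rnorm(m, p$min_gap, 0.1 * p$min_gap)),
        max_accel = pmax(0.5, stats::rnorm(m, p$max_accel, 0.15)),
        comfy_decel = pmax(1.0, stats::rnorm(m, p$comfy_decel, 0.2)),
        desired_speed = pmax(20, stats::rnorm(m, 32, 2)))
    }
    prof <- draw(POP_NORMAL, n)
    if (n_aggr > 0) prof[is_aggr, ] <- draw(POP_AGGR, n_aggr)
    cbind(data.frame(driver_id = seq_len(n) + 1L, is_aggressive = is_aggr),
          prof)
  })
}

# IDM acceleration. v: own speed, dv: closing speed (v - v_leader), d: gap.
idm_accel <- function(v, dv, d, p) {
  s_star <- p$min_gap + pmax(0, v * p$desired_time_gap +
                                  v * dv / (2 * sqrt(p$max_accel * p$comfy_decel)))
  p$max_accel * (1 - (v / p$desired_speed)^4 - (s_star / pmax(d, 0.1))^2)
}

#' Simulate a car-following platoon
#'
#' Integrates an Intelligent-Driver-Model platoon behind a scripted
#' stop-and-go lead vehicle (vehicle 1). Driver k follows vehicle k-1;
#' speeds are clamped at 0 and gaps at 0.1 m. Each driver yields exactly one
#' episode spanning the full configured duration.
#'
#' @param profiles Data frame from [sample_population()].
#' @param config The same [sim_config()].
#' @return List with `episodes` (list of [cf_episode], one per driver),
#'   `truth` (data frame `driver_id`, `is_aggressive`) and `records`
#'   (trajectory table in the canonical schema of
#'   [read_trajectory_table()], covering the lead vehicle and all drivers,
#'   for dog-fooding the reader).
#' @export
simulate_platoon <- function(profiles, config) {
  stopifnot(inherits(config, "sim_config"), nrow(profiles) >= 1)
  n <- nrow(profiles)
  steps <- round(config$duration / config$dt) + 1L
  dt <- config$dt
  tt <- seq(0, by = dt, length.out = steps)
  lead_v <- with_seed(child_seed(config$seed, 2L), {
    pmax(0, config$lead_base_speed +
            config$lead_amplitude * sin(2 * pi * tt / config$lead_period) +
            stats::rnorm(steps, 0, config$lead_noise_sd))
  })
  p <- list(min_gap = profiles$min_gap,
            desired_time_gap = profiles$desired_time_gap,
            max_accel = profiles$max_accel,
            comfy_decel = profiles$comfy_decel,
            desired_speed = profiles$desired_speed)

  v <- matrix(0, steps, n + 1L)  # column 1 = scripted lead
  x <- matrix(0, steps, n + 1L)
  a <- matrix(0, steps, n + 1L)
  v[1, 1] <- lead_v[1]
  v[1, -1] <- lead_v[1]
  # start near equilibrium spacing to avoid an artificial initial transient
  init_gap <- p$min_gap + p$desired_time_gap * lead_v[1] + 1
  x[1, ] <- c(0, -cumsum(init_gap + VEHICLE_LENGTH))
  with_seed(child_seed(config$seed, 3L), {
    for (i in seq_len(steps - 1L)) {
      v[i + 1L, 1] <- lead_v[i + 1L]
      x[i + 1L, 1] <- x[i, 1] + lead_v[i + 1L] * dt
      gap <- x[i, 1:n] - x[i, 2:(n + 1L)] - VEHICLE_LENGTH
      acc <- idm_accel(v[i, 2:(n + 1L)], v[i, 2:(n + 1L)] - v[i, 1:n], gap, p)
      if (config$accel_noise_sd > 0) {
        acc <- acc + stats::rnorm(n, 0, config$accel_noise_sd)
      }
      if (any(!is.finite(acc))) {
        bad <- which(!is.finite(acc))[1]
        stop_acr("simulation blow-up for driver ", profiles$driver_id[bad],
                 " at step ", i, class = "acr_sim_error")
      }
      a[i, 2:(n + 1L)] <- acc
      vn <- pmax(0, v[i, 2:(n + 1L)] + acc * dt)
      xn <- x[i, 2:(n + 1L)] + vn * dt
      # clamp gap at 0.1 m (front-to-back), processed upstream-to-downstream
      for (k in seq_len(n)) {
        lead_x <- if (k == 1) x[i + 1L, 1] else xn[k - 1L]
        if (xn[k] > lead_x - VEHICLE_LENGTH - 0.1) {
          xn[k] <- lead_x - VEHICLE_LENGTH - 0.1
          vn[k] <- max(0, (xn[k] - x[i, k + 1L]) / dt)
        }
      }
      v[i + 1L, 2:(n + 1L)] <- vn
      x[i + 1L, 2:(n + 1L)] <- xn
    }
  })
  a[steps, ] <- a[steps - 1L, ]

  # measurement noise on the recorded series (video-extraction emulation)
  vm <- v; am <- a
  gm <- x[, 1:n, drop = FALSE] - x[, 2:(n + 1L), drop = FALSE] - VEHICLE_LENGTH
  with_seed(child_seed(config$seed, 4L), {
    if (config$obs_speed_sd > 0) {
      vm <- pmax(v + stats::rnorm(length(v), 0, config$obs_speed_sd), 0)
    }
    if (config$obs_accel_sd > 0) {
      am <- a + stats::rnorm(length(a), 0, config$obs_accel_sd)
    }
    if (config$obs_gap_sd > 0) {
      gm <- pmax(gm + stats::rnorm(length(gm), 0, config$obs_gap_sd), 0)
    }
  })

  episodes <- lapply(seq_len(n), function(k) {
    cf_episode(follower_id = profiles$driver_id[k],
               leader_id = if (k == 1) 1L else profiles$driver_id[k - 1L],
               v_l = vm[, k], v_f = vm[, k + 1L], a_f = am[, k + 1L],
               d = gm[, k], dt = dt, start_frame = 0L)
  })
  ids <- c(1L, profiles$driver_id)
  records <- data.frame(
    vehicle_id = rep(ids, each = steps),
    frame_index = rep(seq_len(steps) - 1L, n + 1L),
    lane_id = 1L,
    preceding_id = rep(c(0L, ids[-length(ids)]), each = steps),
    position = as.vector(x),
    speed = as.vector(vm),
    acceleration = as.vector(am),
    space_headway = as.vector(cbind(0, gm + VEHICLE_LENGTH)),
    vehicle_length = VEHICLE_LENGTH)
  list(episodes = episodes,
       truth = profiles[, c("driver_id", "is_aggressive")],
       records = records)
}

#' Write a simulated platoon in the NGSIM CSV schema
#'
#' Emits the trajectory table with the standard I-80 headers (metric units)
#' plus a ground-truth label CSV, so the simulator's output can be fed back
#' through [read_trajectory_table()].
#'
#' @param platoon Result of [simulate_platoon()].
#' @param dir Output directory.
#' @return Paths of the two files, invisibly.
#' @export
write_platoon_csv <- function(platoon, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec <- platoon$records
  names(rec) <- ngsim_columns[names(rec)]
  traj <- file.path(dir, "trajectories.csv")
  truth <- file.path(dir, "ground_truth.csv")
  utils::write.csv(rec, traj, row.names = FALSE, quote = FALSE)
  utils::write.csv(platoon$truth, truth, row.names = FALSE, quote = FALSE)
  invisible(c(trajectories = traj, ground_truth = truth))
}
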