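test_that("population sampling hits the exact aggressive count, reproducibly", {
  cfg <- sim_config(n_drivers = 299, aggressive_fraction = 0.144, seed = 5)
  pop <- sample_population(cfg)
  expect_equal(sum(pop$is_aggressive), 43)
  expect_equal(nrow(pop), 299)
  expect_identical(pop, sample_population(cfg))
  expect_error(sim_config(n_drivers = 10, aggressive_fraction = 0),
               class = "acr_config_error")
  expect_error(sim_config(n_drivers = 10, aggressive_fraction = 0.6),
               class = "acr_config_error")
  # aggressive drivers tailgate: shorter desired time gaps and min gaps
  expect_lt(mean(pop$desired_time_gap[pop$is_aggressive]),
            mean(pop$desired_time_gap[!pop$is_aggressive]))
  expect_lt(mean(pop$min_gap[pop$is_aggressive]),
            mean(pop$min_gap[!pop$is_aggressive]))
})

test_that("platoon series have the configured length and stay physical", {
  cfg <- sim_config(n_drivers = 12, aggressive_fraction = 0.25,
                    duration = 30, seed = 9)
  pl <- simulate_platoon(sample_population(cfg), cfg)
  expect_length(pl$episodes, 12)
  for (e in pl$episodes) {
    expect_length(e$v_f, 301)
    expect_true(all(e$v_f >= 0) && all(e$v_l >= 0) && all(e$d >= 0))
  }
})

test_that("a follower equilibrates behind a constant-speed leader", {
  cfg <- sim_config(n_drivers = 1, aggressive_fraction = 0.4, duration = 120,
                    lead_amplitude = 0, lead_noise_sd = 0,
                    accel_noise_sd = 0, obs_speed_sd = 0, obs_gap_sd = 0,
                    obs_accel_sd = 0, seed = 3)
  pl <- simulate_platoon(sample_population(cfg), cfg)
  e <- pl$episodes[[1]]
  tail_v <- tail(e$v_f, 100)
  expect_lt(max(abs(tail_v - cfg$lead_base_speed)), 0.05)
})

test_that("aggressive followers keep smaller gaps than normal ones", {
  cfg <- sim_config(n_drivers = 40, aggressive_fraction = 0.3, duration = 40,
                    seed = 21)
  pl <- simulate_platoon(sample_population(cfg), cfg)
  mean_gap <- vapply(pl$episodes, function(e) mean(e$d), numeric(1))
  aggr <- pl$truth$is_aggressive[match(
    vapply(pl$episodes, `[[`, integer(1), "follower_id"),
    pl$truth$driver_id)]
  expect_lt(mean(mean_gap[aggr]), mean(mean_gap[!aggr]))
})

test_that("emitted CSV schema round-trips through the trajectory reader", {
  cfg <- sim_config(n_drivers = 6, aggressive_fraction = 0.3, duration = 15,
                    seed = 2)
  pl <- simulate_platoon(sample_population(cfg), cfg)
  dir <- tempfile()
  paths <- write_platoon_csv(pl, dir)
  rec <- read_trajectory_table(paths[["trajectories"]])
  eps <- extract_episodes(rec, min_duration = 10)
  expect_length(eps, length(pl$episodes))
  ids <- vapply(eps, `[[`, integer(1), "follower_id")
  for (i in seq_along(pl$episodes)) {
    j <- which(ids == pl$episodes[[i]]$follower_id)
    expect_equal(eps[[j]]$v_f, pl$episodes[[i]]$v_f, tolerance = 1e-10)
    expect_equal(eps[[j]]$d, pl$episodes[[i]]$d, tolerance = 1e-10)
  }
})

test_that("leader and follower ground truth are independent", {
  cfg <- sim_config(n_drivers = 400, aggressive_fraction = 0.3,
                    duration = 10, seed = 17)
  pop <- sample_population(cfg)
  # platoon order is shuffled, so adjacent pairs' traits are uncorrelated
  r <- cor(pop$is_aggressive[-1], pop$is_aggressive[-nrow(pop)])
  expect_lt(abs(r), 0.15)
})
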