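test_that("reader handles empty tables, converts units, and sorts", {
  hdr_only <- write_traj_csv(make_records(integer(0), integer(0)))
  expect_identical(nrow(read_trajectory_table(hdr_only)), 0L)

  one <- write_traj_csv(make_records(1L, 0L, speed = 10, position = 100,
                                     space_headway = 50, vehicle_length = 15))
  rec <- read_trajectory_table(one, unit_system = "us_customary")
  expect_equal(rec$speed, 3.048)
  expect_equal(rec$position, 30.48)
  expect_equal(rec$space_headway, 15.24)

  shuffled <- write_traj_csv(make_records(c(1L, 1L, 1L), c(2L, 0L, 1L),
                                          speed = c(12, 10, 11)))
  rec <- read_trajectory_table(shuffled)
  expect_equal(rec$frame_index, 0:2)
  expect_equal(rec$speed, c(10, 11, 12))
})

test_that("reader errors name the missing column and the bad row", {
  df <- make_records(1L, 0L)
  names(df) <- ngsim_columns[names(df)]
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df[, setdiff(names(df), "v_Vel")], path, row.names = FALSE)
  expect_error(read_trajectory_table(path), "v_Vel", class = "acr_schema_error")

  df2 <- make_records(c(1L, 1L), 0:1)
  df2$speed <- c("10", "oops")
  path2 <- write_traj_csv(df2)
  expect_error(read_trajectory_table(path2), "row 2", class = "acr_parse_error")
})

test_that("episode extraction splits on leader change and enforces duration", {
  # follower tracks leader 1 for 12 s then leader 3 for 12 s
  frames <- 0:239
  lead1 <- make_records(1L, frames, position = 40 + frames * 1)
  lead3 <- make_records(3L, frames, position = 45 + frames * 1)
  fol <- make_records(2L, frames, preceding_id = rep(c(1L, 3L), each = 120),
                      position = frames * 1,
                      space_headway = rep(c(40, 45), each = 120))
  eps <- extract_episodes(rbind(lead1, lead3, fol), min_duration = 10)
  expect_length(eps, 2)
  expect_equal(vapply(eps, `[[`, integer(1), "leader_id"), c(1L, 3L))

  # 8 s of tracking is below the 10 s minimum
  short <- leader_follower_records(80)
  expect_length(extract_episodes(short, min_duration = 10), 0)
  expect_length(extract_episodes(short, min_duration = 5), 1)

  # gap is space headway minus leader length
  rec <- leader_follower_records(105)
  ep <- extract_episodes(rec, min_duration = 10)[[1]]
  expect_equal(ep$d, rep(30 - 5, 105))
})

test_that("extraction is input-order invariant and conserves frames", {
  rec <- leader_follower_records(150)
  set.seed(4)
  shuf <- rec[sample(nrow(rec)), ]
  a <- extract_episodes(rec, min_duration = 10)
  b <- extract_episodes(shuf, min_duration = 10)
  expect_equal(a, b)
  # a follower's episodes cannot contain more frames than its records
  n_frames <- sum(vapply(a, function(e) length(e$t), integer(1)))
  expect_lte(n_frames, sum(rec$vehicle_id == 2L))
})

test_that("lane filter and preceding-id zero exclude frames", {
  rec <- leader_follower_records(150, follower_lane = 2L)
  expect_length(extract_episodes(rec, min_duration = 10, lane_ids = 1L), 0)
  expect_length(extract_episodes(rec, min_duration = 10, lane_ids = 2L), 1)
  rec0 <- leader_follower_records(150, follower_preceding = 0L)
  expect_length(extract_episodes(rec0, min_duration = 10), 0)
})

test_that("episode archive round-trips bit-exactly", {
  eps <- lapply(1:3, function(i) random_episode(60 + i, seed = i,
                                                follower = i + 10L))
  dir <- tempfile()
  write_episode_archive(eps, dir)
  back <- read_episode_archive(dir)
  expect_length(back, 3)
  for (i in 1:3) {
    expect_identical(back[[i]]$v_l, eps[[i]]$v_l)
    expect_identical(back[[i]]$v_f, eps[[i]]$v_f)
    expect_identical(back[[i]]$a_f, eps[[i]]$a_f)
    expect_identical(back[[i]]$d, eps[[i]]$d)
    expect_identical(back[[i]]$follower_id, eps[[i]]$follower_id)
  }
})
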