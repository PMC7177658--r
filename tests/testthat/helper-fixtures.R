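# Small programmatic fixtures shared across test files.

# A random but physically valid car-following episode.
random_episode <- function(n = 80, seed = NULL, follower = 2L, leader = 1L) {
  if (!is.null(seed)) set.seed(seed)
  v_l <- pmax(0, 10 + cumsum(rnorm(n, 0, 0.3)))
  v_f <- pmax(0, v_l + rnorm(n, 0, 1))
  d <- pmax(0, 15 + cumsum(rnorm(n, 0, 0.5)))
  cf_episode(follower, leader, v_l = v_l, v_f = v_f, d = d, dt = 0.1)
}

# Write a minimal NGSIM-schema CSV and return its path.
write_traj_csv <- function(df, path = tempfile(fileext = ".csv")) {
  names(df) <- ngsim_columns[names(df)]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# Canonical record data frame builder (metric units).
make_records <- function(vehicle_id, frame_index, lane_id = 1L,
                         preceding_id = 0L, position = 0, speed = 10,
                         acceleration = 0, space_headway = 20,
                         vehicle_length = 5) {
  n <- max(length(vehicle_id), length(frame_index))
  data.frame(vehicle_id = rep_len(vehicle_id, n),
             frame_index = rep_len(frame_index, n),
             lane_id = rep_len(lane_id, n),
             preceding_id = rep_len(preceding_id, n),
             position = rep_len(position, n),
             speed = rep_len(speed, n),
             acceleration = rep_len(acceleration, n),
             space_headway = rep_len(space_headway, n),
             vehicle_length = rep_len(vehicle_length, n))
}

# Leader at constant speed plus a follower tracking it; returns records for
# both vehicles over `n` frames.
leader_follower_records <- function(n, follower_preceding = 1L,
                                    follower_lane = 1L) {
  frames <- seq_len(n) - 1L
  rbind(
    make_records(1L, frames, position = 30 + 10 * frames * 0.1),
    make_records(2L, frames, lane_id = follower_lane,
                 preceding_id = follower_preceding,
                 position = 10 * frames * 0.1, space_headway = 30))
}

# Step-wise AUPRC by brute-force enumeration of every threshold (independent
# of the package's grouped-cumulative implementation).
auprc_bruteforce <- function(labels, scores) {
  ths <- sort(unique(scores), decreasing = TRUE)
  prev_r <- 0; area <- 0
  for (th in ths) {
    pred <- as.integer(scores >= th)
    tp <- sum(pred == 1 & labels == 1)
    r <- tp / sum(labels == 1)
    p <- tp / sum(pred == 1)
    area <- area + (r - prev_r) * p
    prev_r <- r
  }
  area
}

# A noisy two-Gaussian classification problem with controllable imbalance.
gaussian_mixture <- function(n_pos, n_neg, seed, sep = 1.5, p = 4) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_neg * p), n_neg),
             matrix(rnorm(n_pos * p, mean = sep / sqrt(p)), n_pos))
  list(x = x, y = rep(c(0L, 1L), c(n_neg, n_pos)))
}

# Within-cluster sum of squares of a 1-D two-set partition.
wss2 <- function(a, b) {
  ss <- function(v) if (length(v)) sum((v - mean(v))^2) else 0
  ss(a) + ss(b)
}

# Exhaustive optimal 2-partition of a numeric vector (all 2^(n-1)-1 splits).
best_2partition_wss <- function(x) {
  n <- length(x)
  best <- Inf
  for (mask in 1:(2^n - 2)) {
    sel <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    best <- min(best, wss2(x[sel], x[!sel]))
  }
  best
}
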