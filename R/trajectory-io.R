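#' NGSIM I-80 column schema
#'
#' Default mapping from canonical field names to the column headers of the
#' NGSIM I-80 trajectory release. Pass a modified copy to
#' [read_trajectory_table()] for files with different headers; matching is
#' case-insensitive.
#'
#' @format Named character vector (canonical name -> file header).
#' @export
ngsim_columns <- c(
  vehicle_id     = "Vehicle_ID",
  frame_index    = "Frame_ID",
  lane_id        = "Lane_ID",
  preceding_id   = "Preceding",
  position       = "Local_Y",
  speed          = "v_Vel",
  acceleration   = "v_Acc",
  space_headway  = "Space_Headway",
  vehicle_length = "v_length"
)

FT_PER_M <- 0.3048

#' Read an NGSIM-style vehicle trajectory table
#'
#' Reads a delimited trajectory table (one row per vehicle per 0.1 s frame)
#' into a canonical data frame with SI units, sorted by vehicle then frame.
#' NGSIM distributes lengths in feet and speeds in ft/s; `us_customary`
#' converts them to metres on ingest so every downstream computation is
#' unit-coherent.
#'
#' @param path Path to a delimited text file with a header row.
#' @param unit_system `"metric"` (already SI) or `"us_customary"` (feet).
#' @param column_map Named character vector mapping the canonical names of
#'   [ngsim_columns] to this file's headers.
#' @param sep Field delimiter.
#' @return A data frame of trajectory records with columns `vehicle_id`,
#'   `frame_index`, `lane_id`, `preceding_id`, `position`, `speed`,
#'   `acceleration`, `space_headway`, `vehicle_length`, sorted by
#'   `(vehicle_id, frame_index)`; lengths in m, speeds in m/s,
#'   accelerations in m/s^2.
#' @export
read_trajectory_table <- function(path,
                                  unit_system = c("metric", "us_customary"),
                                  column_map = ngsim_columns,
                                  sep = ",") {
  unit_system <- match.arg(unit_system)
  if (!file.exists(path)) {
    stop_acr("trajectory file not found: ", path, class = "acr_io_error")
  }
  raw <- utils::read.csv(path, sep = sep, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  hdr <- tolower(trimws(names(raw)))
  idx <- match(tolower(column_map), hdr)
  missing <- names(column_map)[is.na(idx)]
  if (length(missing)) {
    stop_acr("missing mandatory column(s): ",
             paste0(column_map[missing], collapse = ", "),
             class = "acr_schema_error")
  }
  out <- as.data.frame(lapply(seq_along(column_map), function(j) {
    col <- raw[[idx[j]]]
    val <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(val) & !(is.na(col) | col == ""))
    if (length(bad)) {
      stop_acr("non-numeric value '", col[bad[1]], "' in column ",
               column_map[j], " at data row ", bad[1],
               class = "acr_parse_error")
    }
    val
  }))
  names(out) <- names(column_map)
  if (unit_system == "us_customary") {
    for (col in c("position", "speed", "space_headway", "vehicle_length",
                  "acceleration")) {
      out[[col]] <- out[[col]] * FT_PER_M
    }
  }
  int_cols <- c("vehicle_id", "frame_index", "lane_id", "preceding_id")
  for (col in int_cols) out[[col]] <- as.integer(round(out[[col]]))
  out <- out[order(out$vehicle_id, out$frame_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct a car-following episode
#'
#' An episode is the aligned time series of one uninterrupted leader-follower
#' interaction: leader speed, follower speed, follower acceleration and
#' bumper-to-bumper gap on a common clock with fixed step `dt`.
#'
#' @param follower_id,leader_id Integer vehicle ids.
#' @param v_l,v_f Leader / follower speed series (m/s).
#' @param a_f Follower acceleration series (m/s^2); if `NULL`, the centred
#'   finite difference of `v_f` is used (one-sided at the ends).
#' @param d Gap series (m), bumper to bumper, non-negative.
#' @param dt Sampling interval in seconds.
#' @param start_frame First frame index of the run (bookkeeping only).
#' @return An object of class `cf_episode`.
#' @export
cf_episode <- function(follower_id, leader_id, v_l, v_f, d, a_f = NULL,
                       dt = 0.1, start_frame = 0L) {
  n <- length(v_f)
  if (is.null(a_f)) a_f <- centered_diff(v_f, dt)
  if (length(v_l) != n || length(a_f) != n || length(d) != n) {
    stop_acr("episode series must have equal length", class = "acr_episode_error")
  }
  if (n < 2) stop_acr("episode needs at least two samples", class = "acr_episode_error")
  if (any(d < 0)) stop_acr("negative gap in episode", class = "acr_episode_error")
  structure(
    list(follower_id = as.integer(follower_id),
         leader_id = as.integer(leader_id),
         dt = dt,
         t = seq(0, by = dt, length.out = n),
         v_l = as.numeric(v_l), v_f = as.numeric(v_f),
         a_f = as.numeric(a_f), d = as.numeric(d),
         start_frame = as.integer(start_frame)),
    class = "cf_episode")
}

#' @export
print.cf_episode <- function(x, ...) {
  cat(sprintf("<cf_episode> follower %d behind leader %d: %d samples @ %.1fs (%.1f s)\n",
              x$follower_id, x$leader_id, length(x$t), x$dt,
              (length(x$t) - 1) * x$dt))
  cat(sprintf("  gap %.1f-%.1f m, follower speed %.1f-%.1f m/s\n",
              min(x$d), max(x$d), min(x$v_f), max(x$v_f)))
  invisible(x)
}

centered_diff <- function(v, dt) {
  n <- length(v)
  if (n < 2) return(rep(0, n))
  a <- numeric(n)
  if (n > 2) a[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dt)
  a[1] <- (v[2] - v[1]) / dt
  a[n] <- (v[n] - v[n - 1]) / dt
  a
}

#' Extract uninterrupted car-following episodes
#'
#' Splits each follower's record stream into maximal runs over which the
#' follower stays in an allowed lane, keeps the same preceding vehicle, and
#' both vehicles are observed at every consecutive frame. The gap is the
#' bumper-to-bumper distance, `space_headway - leader length`, clamped at 0.
#' Runs shorter than `min_duration` are discarded.
#'
#' @param records Trajectory data frame from [read_trajectory_table()].
#' @param min_duration Minimum episode duration in seconds (span
#'   `(N - 1) * dt`); default 10 s.
#' @param lane_ids Integer lane ids to keep, or `NULL` for all lanes.
#' @param dt Sampling interval (s).
#' @return List of [cf_episode] objects.
#' @export
extract_episodes <- function(records, min_duration = 10, lane_ids = NULL,
                             dt = 0.1) {
  if (min_duration <= 0) stop_acr("min_duration must be positive",
                                  class = "acr_episode_error")
  records <- records[order(records$vehicle_id, records$frame_index), ,
                     drop = FALSE]
  n_min <- ceiling(min_duration / dt) + 1  # samples so that (N-1)*dt >= min_duration
  by_vehicle <- split(seq_len(nrow(records)), records$vehicle_id)
  episodes <- list()
  for (veh in names(by_vehicle)) {
    rows <- by_vehicle[[veh]]
    rec <- records[rows, , drop = FALSE]
    ok <- rec$preceding_id != 0L
    if (!is.null(lane_ids)) ok <- ok & rec$lane_id %in% lane_ids
    # leader must be observed at the same frame
    n <- nrow(rec)
    lead_rows <- rep(NA_integer_, n)
    for (pid in unique(rec$preceding_id[ok])) {
      lrows <- by_vehicle[[as.character(pid)]]
      if (is.null(lrows)) next
      sel <- which(ok & rec$preceding_id == pid)
      m <- match(rec$frame_index[sel], records$frame_index[lrows])
      lead_rows[sel] <- lrows[m]
    }
    ok <- ok & !is.na(lead_rows)
    if (!any(ok)) next
    # break runs at: not ok, preceding change, non-consecutive frames
    brk <- !ok
    new_run <- c(TRUE, diff(rec$frame_index) != 1L |
                       diff(rec$preceding_id) != 0L)
    run_id <- cumsum(new_run | brk | c(FALSE, brk[-n]))
    for (rid in unique(run_id[ok])) {
      sel <- which(run_id == rid & ok)
      if (length(sel) < n_min) next
      lr <- lead_rows[sel]
      gap <- pmax(0, rec$space_headway[sel] - records$vehicle_length[lr])
      a_f <- if (all(is.finite(rec$acceleration[sel]))) {
        rec$acceleration[sel]
      } else NULL
      episodes[[length(episodes) + 1L]] <- cf_episode(
        follower_id = rec$vehicle_id[1],
        leader_id = rec$preceding_id[sel[1]],
        v_l = records$speed[lr],
        v_f = rec$speed[sel],
        a_f = a_f,
        d = gap,
        dt = dt,
        start_frame = rec$frame_index[sel[1]])
    }
  }
  episodes
}

#' Write / read an episode archive
#'
#' Stores each episode as a plain CSV (`t, v_l, v_f, a_f, d` at full double
#' precision) plus a `manifest.csv` naming follower, leader, start frame,
#' sample count and step. `read_episode_archive` reproduces the series
#' bit-exactly.
#'
#' @param episodes List of [cf_episode] objects.
#' @param dir Directory to create/fill.
#' @return `write_episode_archive` returns `dir` invisibly;
#'   `read_episode_archive` returns a list of episodes.
#' @export
write_episode_archive <- function(episodes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(
    file = sprintf("episode_%04d.csv", seq_along(episodes)),
    follower_id = vapply(episodes, `[[`, integer(1), "follower_id"),
    leader_id = vapply(episodes, `[[`, integer(1), "leader_id"),
    start_frame = vapply(episodes, `[[`, integer(1), "start_frame"),
    n = vapply(episodes, function(e) length(e$t), integer(1)),
    dt = vapply(episodes, `[[`, numeric(1), "dt"))
  for (i in seq_along(episodes)) {
    e <- episodes[[i]]
    df <- data.frame(t = sprintf("%.17g", e$t),
                     v_l = sprintf("%.17g", e$v_l),
                     v_f = sprintf("%.17g", e$v_f),
                     a_f = sprintf("%.17g", e$a_f),
                     d = sprintf("%.17g", e$d))
    utils::write.csv(df, file.path(dir, manifest$file[i]), row.names = FALSE,
                     quote = FALSE)
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_episode_archive
#' @export
read_episode_archive <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  lapply(seq_len(nrow(manifest)), function(i) {
    df <- utils::read.csv(file.path(dir, manifest$file[i]))
    cf_episode(follower_id = manifest$follower_id[i],
               leader_id = manifest$leader_id[i],
               v_l = df$v_l, v_f = df$v_f, a_f = df$a_f, d = df$d,
               dt = manifest$dt[i], start_frame = manifest$start_frame[i])
  })
}
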