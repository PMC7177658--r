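#' Truncated DFT amplitude features of a time series
#'
#' Computes the discrete Fourier transform of a series and keeps the
#' amplitudes of the first `n_keep` coefficients, `|DFT_k| / N` for
#' k = 0..n_keep-1. The low-frequency coefficients carry the level, trend
#' and oscillation of the series; the discarded tail is treated as noise.
#' Division by N makes episodes of different durations comparable and makes
#' the k = 0 amplitude equal |mean(x)|.
#'
#' @param series Numeric vector of length at least `n_keep`.
#' @param n_keep Number of leading coefficients to keep (default 15).
#' @return Numeric vector of `n_keep` non-negative amplitudes.
#' @export
dft_amplitudes <- function(series, n_keep = 15) {
  x <- as.numeric(series)
  if (length(x) < n_keep) {
    stop_acr("series length ", length(x), " is shorter than n_keep = ", n_keep,
             class = "acr_length_error")
  }
  Mod(stats::fft(x))[seq_len(n_keep)] / length(x)
}

#' Band-limited DFT amplitudes
#'
#' Alternative truncation keeping every coefficient whose frequency
#' `k / (N * dt)` is at most `f_max` Hz. The number of retained coefficients
#' then grows with the series length, so this mode suits fixed-duration
#' episodes; the fixed-count truncation of [dft_amplitudes()] is the package
#' default.
#'
#' @param series Numeric vector.
#' @param dt Sampling interval (s).
#' @param f_max Highest retained frequency (Hz), default 1.5.
#' @return Amplitudes `|DFT_k| / N` for all k with `k / (N dt) <= f_max`.
#' @export
dft_band_amplitudes <- function(series, dt, f_max = 1.5) {
  x <- as.numeric(series)
  n <- length(x)
  k_max <- floor(f_max * n * dt)
  Mod(stats::fft(x))[seq_len(min(n, k_max + 1))] / n
}

#' Build a feature matrix from episodes
#'
#' One row per episode/driver: the concatenated DFT amplitude vectors of the
#' selected channels in the fixed order gap, speed, acceleration (the
#' follower's speed and acceleration, and the bumper gap). Labels are joined
#' by driver id.
#'
#' @param episodes List of [cf_episode] objects (one per driver).
#' @param labels [label_drivers()] output or a data frame with `driver_id`
#'   and `label` (`"aggressive"`/`"normal"`).
#' @param channels Subset of `c("gap", "speed", "acceleration")`.
#' @param n_keep Coefficients kept per channel (default 15).
#' @return Object of class `feature_matrix`: list with `x` (numeric matrix,
#'   `n_keep * length(channels)` columns named `<channel>_k<j>`, rownames =
#'   driver ids), `y` (integer 0/1, 1 = aggressive), `driver_id`,
#'   `channels`, `n_keep`.
#' @export
build_feature_matrix <- function(episodes, labels,
                                 channels = c("gap", "speed", "acceleration"),
                                 n_keep = 15) {
  channel_order <- c("gap", "speed", "acceleration")
  channels <- channel_order[channel_order %in% channels]
  if (!length(channels)) stop_acr("no valid channels", class = "acr_domain_error")
  series_of <- list(gap = function(e) e$d,
                    speed = function(e) e$v_f,
                    acceleration = function(e) e$a_f)
  ids <- vapply(episodes, `[[`, integer(1), "follower_id")
  m <- match(ids, labels$driver_id)
  if (anyNA(m)) {
    stop_acr("no label for driver id ", ids[which(is.na(m))[1]],
             class = "acr_join_error")
  }
  x <- do.call(rbind, lapply(episodes, function(e) {
    unlist(lapply(channels, function(ch) dft_amplitudes(series_of[[ch]](e), n_keep)))
  }))
  colnames(x) <- unlist(lapply(channels, function(ch)
    paste0(ch, "_k", seq_len(n_keep) - 1L)))
  rownames(x) <- ids
  structure(list(x = x,
                 y = as.integer(labels$label[m] == "aggressive"),
                 driver_id = ids, channels = channels, n_keep = n_keep),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d drivers x %d features (%s), %d aggressive\n",
              nrow(x$x), ncol(x$x), paste(x$channels, collapse = "+"),
              sum(x$y)))
  invisible(x)
}

#' Write a feature matrix as CSV
#'
#' @param fm A [build_feature_matrix()] result.
#' @param path Output file.
#' @export
write_feature_csv <- function(fm, path) {
  df <- data.frame(driver_id = fm$driver_id, label = fm$y,
                   fm$x, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
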