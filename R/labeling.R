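#' Aggressiveness threshold by exact two-cluster 1-D k-means
#'
#' Partitions the ACR values into two clusters minimising the within-cluster
#' sum of squares. In one dimension the optimal 2-clustering is contiguous in
#' sorted order, so the optimum is found exactly by scanning all `n - 1`
#' sorted split points — no iterative heuristic, no seed. The threshold is
#' the midpoint of the inter-cluster gap (any value in the open gap induces
#' the same partition).
#'
#' @param acr_values Numeric vector of per-driver ACR values (s), at least
#'   two distinct.
#' @return Object of class `acr_threshold` with `method = "kmeans"`,
#'   `threshold`, and `extras` (cluster means `mu`, sizes, within-cluster SS
#'   `E`).
#' @export
kmeans_threshold <- function(acr_values) {
  x <- sort(as.numeric(acr_values))
  n <- length(x)
  if (n < 2 || max(x) == min(x)) {
    stop_acr("need at least two distinct ACR values", class = "acr_degenerate_error")
  }
  # prefix sums give O(1) within-SS per candidate split
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  m <- seq_len(n - 1)
  ss_left <- cs2[m] - cs[m]^2 / m
  ss_right <- (cs2[n] - cs2[m]) - (cs[n] - cs[m])^2 / (n - m)
  E <- ss_left + ss_right
  best <- which.min(E)
  threshold <- (x[best] + x[best + 1]) / 2
  new_threshold("kmeans", threshold,
                extras = list(mu = c(cs[best] / best,
                                     (cs[n] - cs[best]) / (n - best)),
                              sizes = c(best, n - best),
                              E = E[best]))
}

#' Aggressiveness threshold by the interquartile-range outlier rule
#'
#' `threshold = Q3 + 1.5 * IQR`, with quartiles computed by
#' linear-interpolation quantiles (R's type 7, the convention this package
#' fixes because the rule's result depends on it).
#'
#' @param acr_values Numeric vector, at least 4 values.
#' @return `acr_threshold` with `extras` `Q1`, `Q3`, `IQR`.
#' @export
iqr_threshold <- function(acr_values) {
  x <- as.numeric(acr_values)
  if (length(x) < 4) stop_acr("need at least 4 values for the IQR rule",
                              class = "acr_domain_error")
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  new_threshold("iqr", q[2] + 1.5 * (q[2] - q[1]),
                extras = list(Q1 = q[1], Q3 = q[2], IQR = q[2] - q[1]))
}

#' Aggressiveness threshold at the Xth percentile
#'
#' Declares the top `(100 - X)%` of the ACR distribution aggressive by using
#' the Xth percentile (type-7 quantile) as threshold; default X = 94.
#'
#' @param acr_values Numeric vector.
#' @param X Percentile in (0, 100).
#' @return `acr_threshold` with `extras$X`.
#' @export
percentile_threshold <- function(acr_values, X = 94) {
  if (X <= 0 || X >= 100) stop_acr("X must lie in (0, 100)",
                                   class = "acr_domain_error")
  new_threshold("percentile",
                stats::quantile(as.numeric(acr_values), X / 100,
                                names = FALSE, type = 7),
                extras = list(X = X))
}

new_threshold <- function(method, threshold, extras) {
  structure(list(method = method, threshold = as.numeric(threshold),
                 extras = extras),
            class = "acr_threshold")
}

#' @export
print.acr_threshold <- function(x, ...) {
  cat(sprintf("<acr_threshold> %s: %.4f s\n", x$method, x$threshold))
  invisible(x)
}

#' Label drivers by an ACR threshold
#'
#' A driver is aggressive iff its ACR is strictly above the threshold.
#'
#' @param acr_tab Data frame with `follower_id` (or `driver_id`) and `acr`
#'   columns, e.g. from [acr_table()].
#' @param threshold An [kmeans_threshold()]-style object or a plain number
#'   (s), non-negative.
#' @param truth Optional data frame `driver_id`, `is_aggressive` with
#'   ground-truth labels (synthetic data).
#' @return Data frame of class `labeled_drivers`: `driver_id`, `acr`,
#'   `label` (`"aggressive"`/`"normal"`), optional `truth`; attributes
#'   `threshold`, `minority_fraction`, `imbalance_ratio`
#'   (majority / minority).
#' @export
label_drivers <- function(acr_tab, threshold, truth = NULL) {
  thr <- if (inherits(threshold, "acr_threshold")) threshold$threshold else threshold
  if (!is.numeric(thr) || thr < 0) stop_acr("threshold must be non-negative",
                                            class = "acr_domain_error")
  id <- acr_tab$driver_id %||% acr_tab$follower_id
  out <- data.frame(driver_id = id, acr = acr_tab$acr,
                    label = ifelse(acr_tab$acr > thr, "aggressive", "normal"))
  if (!is.null(truth)) {
    m <- match(out$driver_id, truth$driver_id)
    out$truth <- ifelse(truth$is_aggressive[m], "aggressive", "normal")
  }
  n_pos <- sum(out$label == "aggressive")
  attr(out, "threshold") <- thr
  attr(out, "minority_fraction") <- n_pos / nrow(out)
  attr(out, "imbalance_ratio") <- if (n_pos > 0) (nrow(out) - n_pos) / n_pos else Inf
  class(out) <- c("labeled_drivers", "data.frame")
  out
}

#' @export
print.labeled_drivers <- function(x, ...) {
  cat(sprintf("<labeled_drivers> %d drivers, %d aggressive (%.1f%%, imbalance %.1f:1) at ACR > %.4f s\n",
              nrow(x), sum(x$label == "aggressive"),
              100 * attr(x, "minority_fraction"),
              attr(x, "imbalance_ratio"), attr(x, "threshold")))
  invisible(as.data.frame(x))
}

#' Leader-follower ACR correlation
#'
#' For every episode whose leader also appears as a labeled follower, pairs
#' the leader's ACR with the follower's and returns the Pearson correlation.
#' Near-zero correlation supports reading a follower's ACR as its own
#' aggressiveness rather than inherited traffic state.
#'
#' @param labeled [label_drivers()] output (or any data frame with
#'   `driver_id` and `acr`).
#' @param episodes List of [cf_episode] objects defining the
#'   follower -> leader pairing.
#' @return List `r` (Pearson correlation) and `n_pairs`.
#' @export
leader_follower_correlation <- function(labeled, episodes) {
  fid <- vapply(episodes, `[[`, integer(1), "follower_id")
  lid <- vapply(episodes, `[[`, integer(1), "leader_id")
  acr_of <- function(ids) labeled$acr[match(ids, labeled$driver_id)]
  f_acr <- acr_of(fid)
  l_acr <- acr_of(lid)
  ok <- !is.na(f_acr) & !is.na(l_acr)
  if (sum(ok) < 3) stop_acr("need at least 3 leader-follower pairs with known ACR",
                            class = "acr_insufficient_data_error")
  list(r = stats::cor(l_acr[ok], f_acr[ok]), n_pairs = sum(ok))
}
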