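#' Resampling plan for imbalanced boosting
#'
#' Describes how the class balance of a training set is adjusted, either once
#' (resample-then-boost baselines) or inside every boosting round
#' (SMOTEBoost / RUSBoost / CUSBoost).
#'
#' @param method `"smote"`, `"rus"` or `"cus"`.
#' @param k_neighbors Nearest minority neighbours for SMOTE interpolation.
#' @param n_clusters Majority clusters for CUS.
#' @param target_ratio Desired minority:majority ratio after resampling, in
#'   (0, 1]; 1 = parity.
#' @return Object of class `resample_plan`.
#' @export
resample_plan <- function(method = c("smote", "rus", "cus"),
                          k_neighbors = 5, n_clusters = 3, target_ratio = 1) {
  method <- match.arg(method)
  stopifnot(k_neighbors >= 1, n_clusters >= 1,
            target_ratio > 0, target_ratio <= 1)
  structure(list(method = method, k_neighbors = as.integer(k_neighbors),
                 n_clusters = as.integer(n_clusters),
                 target_ratio = target_ratio),
            class = "resample_plan")
}

#' SMOTE: synthetic minority oversampling
#'
#' Generates `n_new` synthetic minority rows. Each is
#' `x + lambda * (x_nn - x)` for a uniformly chosen minority row `x`, one of
#' its `k` nearest minority neighbours (Euclidean) `x_nn`, and
#' `lambda ~ U(0, 1)`.
#'
#' @param minority_rows Numeric matrix of minority-class feature rows
#'   (at least 2 rows; `k` must be smaller than the row count).
#' @param n_new Number of synthetic rows.
#' @param k Nearest-neighbour count.
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @return `n_new x ncol` matrix; attributes `base`, `neighbor` (row indices
#'   into `minority_rows`) and `lambda` record the construction.
#' @export
smote_oversample <- function(minority_rows, n_new, k = 5, seed = NULL) {
  x <- as.matrix(minority_rows)
  n <- nrow(x)
  if (n < 2) stop_acr("SMOTE needs at least 2 minority rows",
                      class = "acr_resample_error")
  if (k >= n) stop_acr("k must be smaller than the minority count",
                       class = "acr_resample_error")
  if (n_new == 0) {
    out <- x[0, , drop = FALSE]
    attr(out, "base") <- integer(0); attr(out, "neighbor") <- integer(0)
    attr(out, "lambda") <- numeric(0)
    return(out)
  }
  dmat <- as.matrix(stats::dist(x))
  diag(dmat) <- Inf
  nn <- do.call(rbind, lapply(seq_len(n),
                              function(i) order(dmat[i, ])[seq_len(k)]))
  with_seed(seed, {
    base <- sample.int(n, n_new, replace = TRUE)
    pick <- sample.int(k, n_new, replace = TRUE)
    lambda <- stats::runif(n_new)
    nbr <- nn[cbind(base, pick)]
    out <- x[base, , drop = FALSE] +
      lambda * (x[nbr, , drop = FALSE] - x[base, , drop = FALSE])
    attr(out, "base") <- base; attr(out, "neighbor") <- nbr
    attr(out, "lambda") <- lambda
    out
  })
}

#' Random undersampling of the majority class
#'
#' Keeps a uniform subsample of `n_keep` rows without replacement.
#'
#' @param majority_rows Numeric matrix.
#' @param n_keep Rows to keep, `0 < n_keep <= nrow`.
#' @param seed Integer seed, or `NULL` for the current RNG stream.
#' @param weights Optional non-negative sampling weights (one per row); rows
#'   are then drawn without replacement proportionally to weight, as when
#'   undersampling the current distribution inside a boosting round. `NULL`
#'   = uniform.
#' @return The kept rows; attribute `idx` holds their original indices.
#' @export
random_undersample <- function(majority_rows, n_keep, seed = NULL,
                               weights = NULL) {
  x <- as.matrix(majority_rows)
  n <- nrow(x)
  if (n_keep <= 0 || n_keep > n) {
    stop_acr("n_keep must be in 1..", n, class = "acr_resample_error")
  }
  with_seed(seed, {
    idx <- sort(sample.int(n, n_keep, prob = weights))
    out <- x[idx, , drop = FALSE]
    attr(out, "idx") <- idx
    out
  })
}

# k-means++ seeding followed by Lloyd iterations (stats::kmeans).
kmeanspp <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  if (k > 1) {
    d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
    for (j in 2:k) {
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[j, ] <- x[sample.int(n, 1, prob = p), ]
      d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x),
                                         byrow = TRUE))^2))
    }
  }
  stats::kmeans(x, centers = centers, iter.max = 50, algorithm = "Lloyd")
}

#' Cluster-proportional undersampling of the majority class
#'
#' Clusters the majority rows by k-means (k-means++ seeding, Lloyd
#' iterations), then keeps `n_keep` rows allocated to clusters proportionally
#' to their sizes (largest-remainder rounding), drawn uniformly within each
#' cluster. Retains majority structure that plain random undersampling can
#' destroy.
#'
#' @param majority_rows Numeric matrix.
#' @param n_clusters Number of majority clusters.
#' @param n_keep Rows to keep.
#' @param seed Integer seed, or `NULL` for the current RNG stream.
#' @param max_retries Re-seeding attempts if a cluster comes back empty.
#' @param weights Optional non-negative sampling weights; clusters are then
#'   allocated by weight mass instead of size and rows drawn
#'   weight-proportionally within each cluster (boosting-round use). `NULL`
#'   = uniform.
#' @return Kept rows; attributes `idx` (original indices), `cluster_sizes`,
#'   `allocation`.
#' @export
cluster_undersample <- function(majority_rows, n_clusters = 3, n_keep,
                                seed = NULL, max_retries = 5,
                                weights = NULL) {
  x <- as.matrix(majority_rows)
  n <- nrow(x)
  if (n_clusters > n || n_keep > n || n_keep <= 0) {
    stop_acr("need n_keep, n_clusters <= majority count",
             class = "acr_resample_error")
  }
  with_seed(seed, {
    if (n_clusters == 1 || nrow(unique(x)) < n_clusters) {
      cl <- rep(1L, n)
    } else {
      cl <- NULL
      for (try in seq_len(max_retries)) {
        fit <- tryCatch(suppressWarnings(kmeanspp(x, n_clusters)),
                        error = function(e) NULL)
        if (!is.null(fit) && all(fit$size > 0)) { cl <- fit$cluster; break }
      }
      if (is.null(cl)) stop_acr("k-means produced an empty cluster repeatedly",
                                class = "acr_resample_error")
    }
    sizes <- tabulate(cl)
    mass <- if (is.null(weights)) sizes / n else
      vapply(seq_along(sizes), function(j) sum(weights[cl == j]), 0) /
        sum(weights)
    alloc <- largest_remainder(n_keep * mass, cap = sizes)
    idx <- sort(unlist(lapply(seq_along(sizes), function(j) {
      members <- which(cl == j)
      if (alloc[j] == 0) return(integer(0))
      if (alloc[j] == length(members)) return(members)
      members[sample.int(length(members), alloc[j],
                         prob = weights[members])]
    })))
    out <- x[idx, , drop = FALSE]
    attr(out, "idx") <- idx
    attr(out, "cluster_sizes") <- sizes
    attr(out, "allocation") <- alloc
    out
  })
}

# Round non-negative quotas to integers summing to round(sum(quota)),
# never exceeding cap, by largest remainder.
largest_remainder <- function(quota, cap) {
  total <- round(sum(quota))
  base <- pmin(floor(quota), cap)
  short <- total - sum(base)
  frac <- quota - floor(quota)
  ord <- order(frac, cap, decreasing = TRUE)
  while (short > 0) {
    progressed <- FALSE
    for (j in ord) {
      if (short == 0) break
      if (base[j] < cap[j]) { base[j] <- base[j] + 1; short <- short - 1
                              progressed <- TRUE }
    }
    if (!progressed) break
  }
  as.integer(base)
}
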