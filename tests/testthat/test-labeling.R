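test_that("two-cluster threshold splits at the widest sensible gap", {
  r <- kmeans_threshold(c(0, 0.01, 0.02, 0.5, 0.6))
  expect_equal(r$threshold, (0.02 + 0.5) / 2)
  expect_equal(kmeans_threshold(c(0, 1))$threshold, 0.5)
  # two tight separated clusters
  set.seed(2)
  x <- c(0.05 + runif(10, -0.001, 0.001), 0.30 + runif(10, -0.001, 0.001))
  r2 <- kmeans_threshold(x)
  expect_equal(r2$threshold, (max(x[x < 0.2]) + min(x[x > 0.2])) / 2,
               tolerance = 1e-12)
  expect_lt(r2$extras$E, wss2(x, numeric(0)))  # within < total SS
  # threshold lies strictly between the cluster means
  expect_true(r2$extras$mu[1] < r2$threshold && r2$threshold < r2$extras$mu[2])
  expect_error(kmeans_threshold(rep(0.3, 5)), class = "acr_degenerate_error")
})

test_that("sorted-split enumeration equals exhaustive 2-partition optimum", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(3:12, 1)
    x <- round(runif(n), 3)
    if (max(x) == min(x)) next
    r <- kmeans_threshold(x)
    expect_equal(r$extras$E, best_2partition_wss(x), tolerance = 1e-12)
  }
})

test_that("IQR rule and percentile use type-7 quantiles", {
  x <- c(1:8)
  r <- iqr_threshold(x)
  expect_equal(r$extras$Q1, 2.75)
  expect_equal(r$extras$Q3, 6.25)
  expect_equal(r$threshold, 6.25 + 1.5 * 3.5)  # 11.5
  expect_equal(iqr_threshold(rep(3, 6))$threshold, 3)
  expect_error(iqr_threshold(1:3), class = "acr_domain_error")

  expect_equal(percentile_threshold(0:100, 94)$threshold, 94)
  expect_equal(percentile_threshold(rep(2, 10), 94)$threshold, 2)
  expect_error(percentile_threshold(1:10, 0), class = "acr_domain_error")
  expect_error(percentile_threshold(1:10, 100), class = "acr_domain_error")
})

test_that("thresholds shift by c under a location shift", {
  set.seed(3)
  x <- rexp(40, 10)
  for (c0 in c(0.5, 2)) {
    expect_equal(kmeans_threshold(x + c0)$threshold,
                 kmeans_threshold(x)$threshold + c0, tolerance = 1e-12)
    expect_equal(iqr_threshold(x + c0)$threshold,
                 iqr_threshold(x)$threshold + c0, tolerance = 1e-12)
    expect_equal(percentile_threshold(x + c0)$threshold,
                 percentile_threshold(x)$threshold + c0, tolerance = 1e-12)
  }
})

test_that("labeling uses a strict inequality and reports imbalance", {
  tab <- data.frame(follower_id = 1:6,
                    acr = c(0, 0.14, 0.15, 0.2, 0.05, 0.14))
  lab <- label_drivers(tab, 0.14)
  expect_equal(lab$label, c("normal", "normal", "aggressive", "aggressive",
                            "normal", "normal"))
  expect_equal(attr(lab, "minority_fraction"), 2 / 6)
  expect_equal(attr(lab, "imbalance_ratio"), 2)
  # idempotent and deterministic
  expect_identical(label_drivers(lab, 0.14)$label, lab$label)
  zero <- label_drivers(data.frame(follower_id = 1:5, acr = rep(0, 5)), 0.14)
  expect_equal(sum(zero$label == "aggressive"), 0)
  # a 43-above-threshold population gives the 14.4% / ~6:1 bookkeeping
  acr <- c(rep(0.05, 256), rep(0.3, 43))
  lab2 <- label_drivers(data.frame(follower_id = seq_along(acr), acr = acr),
                        0.14)
  expect_equal(attr(lab2, "minority_fraction"), 43 / 299)
  expect_equal(round(attr(lab2, "imbalance_ratio")), 6)
})

test_that("leader-follower ACR correlation matches hand Pearson", {
  mk <- function(f, l) cf_episode(f, l, v_l = rep(10, 20), v_f = rep(10, 20),
                                  d = rep(20, 20))
  eps <- list(mk(2L, 1L), mk(3L, 2L), mk(4L, 3L))
  lab <- data.frame(driver_id = 1:4, acr = c(0, 0.2, 0.1, 0))
  # pairs: (leader, follower) = (0, 0.2), (0.2, 0.1), (0.1, 0)
  r <- leader_follower_correlation(lab, eps)
  expect_equal(r$n_pairs, 3)
  expect_equal(r$r, cor(c(0, 0.2, 0.1), c(0.2, 0.1, 0)))
  # identical series give r = 1, negated give r = -1
  lab_eq <- data.frame(driver_id = 1:4, acr = c(1, 2, 3, 4))
  expect_equal(leader_follower_correlation(lab_eq, eps)$r, 1)
  lab_neg <- data.frame(driver_id = 1:4, acr = c(4, 3, 2, 1))
  # follower acr = -leader acr + 5
  expect_equal(leader_follower_correlation(
    data.frame(driver_id = 1:4, acr = c(1, 4, 2, 3)),
    list(mk(2L, 1L), mk(3L, 2L), mk(4L, 3L)))$r,
    cor(c(1, 4, 2), c(4, 2, 3)))
  expect_error(leader_follower_correlation(lab[1:2, ], eps[1]),
               class = "acr_insufficient_data_error")
})
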