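test_that("a separable problem is solved in one round", {
  x <- matrix(seq(-1, 1, length.out = 60), ncol = 1)
  y <- as.integer(x[, 1] > 0.2)
  m <- boost_fit(x, y, "adaboost", rounds = 10, seed = 1)
  expect_equal(m$rounds, 1)          # eps = 0 ends boosting
  expect_equal(m$train_error, 0)
  expect_equal(m$epsilon, 0)
})

test_that("vote weights follow the weighted errors", {
  d <- gaussian_mixture(40, 60, seed = 2)
  m <- boost_fit(d$x, d$y, "adaboost", rounds = 15, seed = 3)
  expect_true(all(m$alpha > 0))
  expect_true(all(m$epsilon < 0.5))
  keep <- m$epsilon > 0
  expect_equal(m$alpha[keep], 0.5 * log((1 - m$epsilon[keep]) / m$epsilon[keep]))
})

test_that("boosting lifts depth-limited trees on an XOR pattern", {
  set.seed(12)
  n <- 200
  x <- matrix(runif(2 * n, -1, 1), n)
  y <- as.integer(xor(x[, 1] > 0, x[, 2] > 0))
  m <- boost_fit(x, y, "adaboost", rounds = 50, tree_depth = 2, seed = 4)
  acc <- mean(predict(m, x, type = "class") == y)
  expect_gt(acc, 0.95)
})

test_that("training error respects the exponential-loss bound", {
  for (s in 1:8) {
    d <- gaussian_mixture(30, 70, seed = 40 + s)
    m <- boost_fit(d$x, d$y, "adaboost", rounds = 12, seed = s)
    expect_lte(m$train_error, m$loss_bound + 1e-12)
  }
})

test_that("fits and scores are deterministic given data and seed", {
  d <- gaussian_mixture(25, 100, seed = 5)
  xt <- matrix(rnorm(40 * 4), 40)
  for (alg in c("adaboost", "smoteboost", "rusboost", "cusboost")) {
    m1 <- boost_fit(d$x, d$y, alg, rounds = 8, seed = 11)
    m2 <- boost_fit(d$x, d$y, alg, rounds = 8, seed = 11)
    expect_identical(predict(m1, xt), predict(m2, xt))
    expect_identical(m1$alpha, m2$alpha)
  }
})

test_that("with balanced data and parity target the resamplers are no-ops", {
  for (s in 1:10) {
    d <- gaussian_mixture(50, 50, seed = 60 + s)
    errs <- vapply(c("adaboost", "smoteboost", "rusboost", "cusboost"),
                   function(a) boost_fit(d$x, d$y, a, rounds = 6,
                                         cost_sensitive = FALSE,
                                         seed = s)$train_error,
                   numeric(1))
    expect_equal(unname(errs[-1]), rep(unname(errs[1]), 3))
  }
})

test_that("rebalanced boosters raise minority recall on 10:1 data", {
  d <- gaussian_mixture(20, 200, seed = 7, sep = 2)
  test <- gaussian_mixture(40, 400, seed = 8, sep = 2)
  recall_of <- function(alg) {
    m <- boost_fit(d$x, d$y, alg, rounds = 20,
                   cost_sensitive = FALSE, seed = 9)
    pred <- predict(m, test$x, type = "class")
    sum(pred == 1 & test$y == 1) / sum(test$y == 1)
  }
  base <- recall_of("adaboost")
  for (alg in c("smoteboost", "rusboost", "cusboost")) {
    expect_gte(recall_of(alg), base)
  }
})

test_that("scores are convex combinations of tree probabilities", {
  d <- gaussian_mixture(30, 60, seed = 3)
  m <- boost_fit(d$x, d$y, "smoteboost", rounds = 10, seed = 2)
  s <- predict(m, d$x)
  expect_true(all(s >= 0 & s <= 1))
  expect_identical(predict(m, d$x, type = "class"), as.integer(s >= 0.5))
  expect_true(all(m$alpha > 0))
  # a single-tree ensemble returns that tree's probability unchanged
  m1 <- boost_fit(matrix(seq(-1, 1, length.out = 50), ncol = 1),
                  as.integer(seq(-1, 1, length.out = 50) > 0),
                  "adaboost", rounds = 1, seed = 1)
  expect_equal(m1$rounds, 1)
  expect_setequal(round(unique(predict(m1, d$x[, 1, drop = FALSE])), 6),
                  c(0, 1))
})

test_that("degenerate and invalid inputs raise fit errors", {
  x <- matrix(rnorm(20), 10)
  expect_error(boost_fit(x, rep(1L, 10), "adaboost"), class = "acr_fit_error")
  expect_error(boost_fit(x, rep(0:1, 5), "smoteboost",
                         plan = resample_plan("rus")),
               class = "acr_fit_error")
})

test_that("each rebalanced round trains on (near-)balanced classes", {
  d <- gaussian_mixture(12, 88, seed = 21)
  df <- as.data.frame(d$x); names(df) <- paste0("f", 1:4)
  yf <- factor(d$y, levels = c(0, 1))
  w <- rep(1 / 100, 100)
  for (alg in c("smoteboost", "rusboost", "cusboost")) {
    plan <- resample_plan(switch(alg, smoteboost = "smote",
                                 rusboost = "rus", cusboost = "cus"))
    set.seed(5)
    rs <- acrboost:::make_round_sample(df, yf, w, alg, plan)
    counts <- table(rs$data$label)
    expect_lte(abs(counts[["1"]] - counts[["0"]]), 1)
  }
})
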