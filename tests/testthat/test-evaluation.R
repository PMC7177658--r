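test_that("precision/recall/F1 match the definitions, with 0/0 -> 0", {
  m <- classification_metrics(9, 1, 9)
  expect_equal(m$precision, 0.9)
  expect_equal(m$recall, 0.5)
  expect_equal(m$f1, 2 * 0.9 * 0.5 / 1.4)
  # harmonic-mean identity
  m2 <- classification_metrics(6, 2, 2)
  expect_equal(m2$precision, m2$recall)
  expect_equal(m2$f1, m2$precision)
  w <- capture_warnings(m3 <- classification_metrics(0, 0, 5))
  expect_true(any(grepl("precision", w)))
  expect_equal(m3$precision, 0)
  expect_equal(m3$f1, 0)
})

test_that("PR curve endpoints and simple areas are exact", {
  perfect <- pr_curve(c(0, 0, 0, 1, 1), c(0.1, 0.2, 0.3, 0.8, 0.9))
  expect_equal(perfect$auprc, 1)
  one_last <- pr_curve(c(rep(0, 9), 1), c(10:2, 1))
  expect_equal(one_last$auprc, 0.1)
  # all-tied scores collapse to a single point at the prevalence
  tied <- pr_curve(rep(c(0, 1), c(8, 2)), rep(0.5, 10))
  expect_equal(tied$auprc, 0.2)
  expect_equal(nrow(tied$points), 1)
  expect_error(pr_curve(rep(1, 5), runif(5)), class = "acr_eval_error")
})

test_that("grouped sweep equals brute-force threshold enumeration", {
  set.seed(14)
  for (i in 1:40) {
    n <- sample(5:30, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- round(runif(n), 2)  # coarse scores force ties
    expect_equal(pr_curve(y, s)$auprc, auprc_bruteforce(y, s),
                 tolerance = 1e-12)
  }
})

test_that("recall is non-decreasing along the sweep", {
  set.seed(15)
  for (i in 1:10) {
    y <- rbinom(50, 1, 0.3)
    if (length(unique(y)) < 2) next
    pc <- pr_curve(y, runif(50))
    expect_true(all(diff(pc$points$recall) >= 0))
    expect_true(all(pc$points$precision >= 0 & pc$points$precision <= 1))
  }
})

test_that("stratified folds preserve class counts within one", {
  y <- rep(c(1L, 0L), c(43, 256))
  fold <- acrboost:::stratified_folds(y, 5, seed = 2)
  pos_per_fold <- table(fold[y == 1])
  expect_setequal(as.integer(pos_per_fold), c(8, 9))
  expect_equal(sum(pos_per_fold), 43)
  expect_identical(fold, acrboost:::stratified_folds(y, 5, seed = 2))
})

test_that("repeated CV produces 25 fold rows and is seed-deterministic", {
  d <- gaussian_mixture(30, 120, seed = 31, sep = 2)
  fm <- list(x = d$x, y = d$y)
  spec <- model_spec("adaboost", rounds = 5)
  r1 <- repeated_stratified_cv(fm, spec, folds = 5, repeats = 5, seed = 8)
  expect_equal(nrow(r1$per_fold), 25)
  expect_equal(unname(r1$summary["auprc"]), mean(r1$per_fold$auprc))
  r2 <- repeated_stratified_cv(fm, spec, folds = 5, repeats = 5, seed = 8)
  expect_identical(r1$per_fold, r2$per_fold)
  expect_error(repeated_stratified_cv(list(x = d$x[1:10, ],
                                           y = c(1, rep(0, 9))), spec),
               class = "acr_cv_error")
})

test_that("training-fold row order does not leak into held-out predictions", {
  d <- gaussian_mixture(25, 75, seed = 33, sep = 2)
  xtr <- d$x[1:80, ]; ytr <- d$y[1:80]
  xte <- d$x[81:100, ]
  m1 <- fit_model(model_spec("adaboost", rounds = 6), xtr, ytr, seed = 3)
  perm <- sample(80)
  m2 <- fit_model(model_spec("adaboost", rounds = 6), xtr[perm, ],
                  ytr[perm], seed = 3)
  expect_identical(predict_score(m1, xte), predict_score(m2, xte))
})

test_that("grid search is exhaustive, idempotent, and prefers small ties", {
  d <- gaussian_mixture(30, 90, seed = 35, sep = 2)
  spec <- model_spec("adaboost", rounds = 5)
  single <- grid_search(d$x, d$y, spec, data.frame(rounds = 7), seed = 2)
  expect_equal(single$spec$rounds, 7)
  dup <- grid_search(d$x, d$y, spec,
                     data.frame(rounds = c(7, 7, 7)), seed = 2)
  expect_equal(dup$spec$rounds, single$spec$rounds)
  expect_equal(dup$mean_auprc, single$mean_auprc)
  # identical scores tie toward the smaller model
  d2 <- list(x = matrix(seq(-1, 1, length.out = 60), ncol = 1),
             y = as.integer(seq(-1, 1, length.out = 60) > 0))
  tie <- grid_search(d2$x, d2$y, spec, data.frame(rounds = c(20, 5)),
                     seed = 4)
  expect_equal(tie$spec$rounds, 5)
})

test_that("a constant scorer earns zero recall and prevalence-level AUPRC", {
  y <- rep(c(1, 0), c(10, 40))
  s <- rep(0.2, 50)
  cc <- acrboost:::confusion_counts(y, as.integer(s >= 0.5))
  met <- suppressWarnings(classification_metrics(cc$tp, cc$fp, cc$fn, cc$tn))
  expect_equal(met$recall, 0)
  expect_equal(pr_curve(y, s)$auprc, 0.2)
})
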