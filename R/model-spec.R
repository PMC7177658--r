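#' The nine benchmark algorithms
#'
#' Names accepted by [model_spec()] and the experiment runner:
#' cost-sensitive boosting (`adaboost`, `xgboost`), one-shot
#' resample-then-boost baselines (`smote_adaboost`, `smote_xgboost`,
#' `rus_adaboost`, `rus_xgboost`), and the imbalanced-class boosters that
#' rebalance inside every round (`smoteboost`, `rusboost`, `cusboost`).
#'
#' @export
ALGORITHMS <- c("adaboost", "xgboost",
                "smote_adaboost", "smote_xgboost",
                "rus_adaboost", "rus_xgboost",
                "smoteboost", "rusboost", "cusboost")

#' Specify a model for evaluation
#'
#' @param algorithm One of [ALGORITHMS].
#' @param rounds Boosting rounds (AdaBoost variants) / `nrounds` (xgboost).
#' @param tree_depth Weak-learner / tree depth.
#' @param plan [resample_plan()] for any resampling the algorithm performs;
#'   defaults to the algorithm's canonical plan.
#' @param eta Learning rate (xgboost only).
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(algorithm, rounds = 50, tree_depth = 2, plan = NULL,
                       eta = 0.3) {
  if (!algorithm %in% ALGORITHMS) {
    stop_acr("unknown algorithm '", algorithm, "'; expected one of: ",
             paste(ALGORITHMS, collapse = ", "), class = "acr_config_error")
  }
  if (is.null(plan)) {
    plan <- switch(algorithm,
                   smoteboost = , smote_adaboost = , smote_xgboost =
                     resample_plan("smote"),
                   rusboost = , rus_adaboost = , rus_xgboost =
                     resample_plan("rus"),
                   cusboost = resample_plan("cus"),
                   NULL)
  }
  structure(list(algorithm = algorithm, rounds = rounds,
                 tree_depth = tree_depth, plan = plan, eta = eta),
            class = "model_spec")
}

# One-shot resampling of a training set (resample-then-boost baselines).
resample_once <- function(x, y01, plan) {
  pos <- which(y01 == 1); neg <- which(y01 == 0)
  minority <- if (length(pos) <= length(neg)) pos else neg
  majority <- setdiff(seq_along(y01), minority)
  if (plan$method == "smote") {
    n_new <- max(0, ceiling(plan$target_ratio * length(majority)) -
                      length(minority))
    k <- min(plan$k_neighbors, length(minority) - 1L)
    if (n_new == 0 || k < 1) return(list(x = x, y = y01))
    synth <- smote_oversample(x[minority, , drop = FALSE], n_new, k,
                              seed = NULL)
    list(x = rbind(x, synth), y = c(y01, rep(y01[minority[1]], n_new)))
  } else {
    n_keep <- min(length(majority),
                  max(1L, ceiling(length(minority) / plan$target_ratio)))
    kept <- if (plan$method == "rus") {
      attr(random_undersample(x[majority, , drop = FALSE], n_keep,
                              seed = NULL), "idx")
    } else {
      attr(cluster_undersample(x[majority, , drop = FALSE],
                               plan$n_clusters, n_keep, seed = NULL), "idx")
    }
    idx <- sort(c(minority, majority[kept]))
    list(x = x[idx, , drop = FALSE], y = y01[idx])
  }
}

#' Fit a model described by a [model_spec()]
#'
#' Dispatches to [boost_fit()] for the AdaBoost family and to the
#' gradient-boosted-tree library for the `xgboost` family (with
#' `scale_pos_weight` carrying the class cost). The `smote_*`/`rus_*`
#' baselines resample the training set once, then fit without class costs.
#'
#' @param spec A [model_spec()].
#' @param x,y Training features and 0/1 labels.
#' @param seed Integer seed.
#' @return A fitted model usable with [predict_score()].
#' @export
fit_model <- function(spec, x, y, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  x <- as.matrix(x)
  y01 <- to_binary(y)
  alg <- spec$algorithm
  if (alg %in% c("smoteboost", "rusboost", "cusboost", "adaboost")) {
    return(boost_fit(x, y01, algorithm = alg, rounds = spec$rounds,
                     tree_depth = spec$tree_depth, plan = spec$plan,
                     seed = seed))
  }
  pre <- !is.null(spec$plan)
  with_seed(seed, {
    if (pre) {
      rs <- resample_once(x, y01, spec$plan)
      x <- rs$x; y01 <- rs$y
    }
    if (grepl("adaboost$", alg)) {
      boost_fit(x, y01, algorithm = "adaboost", rounds = spec$rounds,
                tree_depth = spec$tree_depth, cost_sensitive = !pre,
                seed = NULL)
    } else {
      fit_xgboost(x, y01, rounds = spec$rounds, depth = spec$tree_depth,
                  eta = spec$eta, cost_sensitive = !pre)
    }
  })
}

fit_xgboost <- function(x, y01, rounds, depth, eta, cost_sensitive) {
  spw <- if (cost_sensitive && sum(y01 == 1) > 0) {
    sum(y01 == 0) / sum(y01 == 1)
  } else 1
  dtrain <- xgboost::xgb.DMatrix(x, label = y01, nthread = 1)
  bst <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = depth,
                  eta = eta, scale_pos_weight = spw, nthread = 1),
    data = dtrain, nrounds = rounds, verbose = 0)
  structure(list(bst = bst, feature_names = colnames(x)),
            class = "acr_xgb")
}

#' @export
predict_score.acr_xgb <- function(model, x) {
  as.numeric(predict(model$bst,
                     xgboost::xgb.DMatrix(as.matrix(x), nthread = 1)))
}

#' @export
print.acr_xgb <- function(x, ...) {
  cat("<acr_xgb> gradient-boosted-tree baseline\n")
  invisible(x)
}
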