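#' Fit an (imbalanced-class) boosting ensemble
#'
#' AdaBoost.M1 over depth-limited CART weak learners, with optional
#' per-round rebalancing of the training sample:
#' \describe{
#'   \item{`adaboost`}{plain cost-sensitive AdaBoost; no resampling.}
#'   \item{`smoteboost`}{fresh SMOTE synthetic minority rows in every round.}
#'   \item{`rusboost`}{fresh random majority undersample in every round.}
#'   \item{`cusboost`}{fresh cluster-proportional majority undersample in
#'     every round.}
#' }
#' In the three rebalanced variants the weak learner is fitted on the
#' rebalanced sample, while the weighted error `eps_t`, the vote weight
#' `alpha_t = 0.5 * log((1 - eps_t) / eps_t)` and the weight update are
#' always computed on the original (un-resampled) samples, following the
#' published SMOTEBoost/RUSBoost formulations. SMOTE's synthetic rows carry
#' the mean weight of the real minority rows during learner fitting and are
#' discarded afterwards. Rounds with `eps_t >= 0.5` are discarded and stop
#' boosting; a perfect round (`eps_t = 0`) dominates the vote and stops
#' boosting.
#'
#' Initial sample weights are proportional to class costs: with
#' `cost_sensitive = TRUE` each class gets the inverse of its frequency, so
#' the minority carries the imbalance ratio relative to the majority;
#' otherwise weights start uniform. The default is cost-sensitive for plain
#' AdaBoost and uniform for the three rebalanced variants, which counter the
#' imbalance by resampling instead (combining both over-corrects).
#'
#' @param x Numeric feature matrix (rows = samples).
#' @param y Labels: 0/1 integer, logical, or a factor whose second level is
#'   the positive (aggressive) class.
#' @param algorithm One of `"adaboost"`, `"smoteboost"`, `"rusboost"`,
#'   `"cusboost"`.
#' @param rounds Maximum boosting rounds `T`.
#' @param tree_depth Maximum depth of each CART weak learner.
#' @param cost_sensitive Start from inverse-class-frequency weights?
#' @param class_costs Optional explicit costs `c(negative, positive)`
#'   overriding the default.
#' @param plan [resample_plan()] for the rebalanced variants; its `method`
#'   must match the algorithm. Defaults to the algorithm's canonical plan.
#' @param seed Integer seed; fixes the per-round resampling draws.
#' @return Object of class `acr_boost`: weak learners (`rpart` trees), vote
#'   weights `alpha`, per-round weighted errors `epsilon`, the training
#'   exponential-loss bound `prod(2 sqrt(eps (1 - eps)))`, and the training
#'   error at score threshold 0.5.
#' @seealso [predict.acr_boost()], [predict_score()]
#' @export
boost_fit <- function(x, y,
                      algorithm = c("adaboost", "smoteboost", "rusboost",
                                    "cusboost"),
                      rounds = 50, tree_depth = 2,
                      cost_sensitive = NULL, class_costs = NULL,
                      plan = NULL, seed = 1L) {
  algorithm <- match.arg(algorithm)
  x <- as.matrix(x)
  y01 <- to_binary(y)
  n <- length(y01)
  if (length(unique(y01)) < 2) stop_acr("both classes must be present",
                                        class = "acr_fit_error")
  stopifnot(rounds >= 1, nrow(x) == n)
  if (is.null(plan) && algorithm != "adaboost") {
    plan <- switch(algorithm,
                   smoteboost = resample_plan("smote"),
                   rusboost = resample_plan("rus"),
                   cusboost = resample_plan("cus"))
  }
  if (algorithm != "adaboost") {
    want <- c(smoteboost = "smote", rusboost = "rus", cusboost = "cus")[algorithm]
    if (plan$method != want) stop_acr("plan method '", plan$method,
                                      "' does not match ", algorithm,
                                      class = "acr_fit_error")
  }

  if (is.null(cost_sensitive)) cost_sensitive <- algorithm == "adaboost"
  if (is.null(class_costs)) {
    class_costs <- if (cost_sensitive) {
      c(n / (2 * sum(y01 == 0)), n / (2 * sum(y01 == 1)))
    } else c(1, 1)
  }
  w <- class_costs[y01 + 1L]
  w <- w / sum(w)

  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_len(ncol(x)))
  yf <- factor(y01, levels = c(0, 1))
  ypm <- 2 * y01 - 1

  fit_tree <- function(data, wts) {
    rpart::rpart(
      label ~ ., data = data, weights = wts, method = "class",
      control = rpart::rpart.control(maxdepth = tree_depth, cp = 0,
                                     minsplit = 10, minbucket = 3,
                                     maxcompete = 0, maxsurrogate = 0,
                                     xval = 0))
  }
  trees <- list(); alphas <- numeric(0); epsilons <- numeric(0)
  with_seed(seed, {
    for (t in seq_len(rounds)) {
      # a resampled round whose learner is no better than chance on the
      # original distribution is redrawn a few times before giving up
      retries <- if (algorithm == "adaboost") 1L else 5L
      for (attempt in seq_len(retries)) {
        fit_data <- make_round_sample(df, yf, w, algorithm, plan)
        tree <- fit_tree(fit_data$data, fit_data$w)
        h <- as.integer(as.character(predict(tree, df, type = "class")))
        miss <- h != y01
        eps <- sum(w[miss])
        if (eps < 0.5) break
      }
      if (eps >= 0.5) break  # weak learner no better than chance: discard, stop
      if (eps <= 0) {
        trees[[length(trees) + 1L]] <- tree
        alphas <- c(alphas, 0.5 * log((1 - 1e-12) / 1e-12))
        epsilons <- c(epsilons, 0)
        break
      }
      alpha <- 0.5 * log((1 - eps) / eps)
      trees[[length(trees) + 1L]] <- tree
      alphas <- c(alphas, alpha)
      epsilons <- c(epsilons, eps)
      w <- w * exp(-alpha * ypm * (2 * h - 1))
      w <- w / sum(w)
    }
  })
  if (!length(trees)) {
    # degenerate data for the resampled variant: fall back to one weak
    # learner on the original weighted sample so a usable (if weak) scorer
    # is always returned
    tree <- fit_tree(cbind(df, label = yf), w * n)
    h <- as.integer(as.character(predict(tree, df, type = "class")))
    eps <- sum(w[h != y01])
    if (eps >= 0.5) stop_acr("no weak learner beats chance on these data",
                             class = "acr_fit_error")
    trees <- list(tree)
    alphas <- 0.5 * log((1 - eps) / eps)
    epsilons <- eps
  }
  obj <- structure(
    list(trees = trees, alpha = alphas, epsilon = epsilons,
         algorithm = algorithm, plan = plan, rounds = length(trees),
         rounds_requested = rounds, tree_depth = tree_depth,
         class_costs = class_costs,
         loss_bound = prod(2 * sqrt(epsilons * (1 - epsilons))),
         feature_names = names(df), n_train = n,
         seed = seed, call = match.call()),
    class = "acr_boost")
  obj$train_error <- mean((predict(obj, x) >= 0.5) != y01)
  obj
}

# Per-round training sample for the weak learner.
make_round_sample <- function(df, yf, w, algorithm, plan) {
  y01 <- as.integer(as.character(yf))
  pos <- which(y01 == 1); neg <- which(y01 == 0)
  minority <- if (length(pos) <= length(neg)) pos else neg
  majority <- setdiff(seq_along(y01), minority)
  if (algorithm == "adaboost") {
    return(list(data = cbind(df, label = yf), w = w * length(w)))
  }
  if (algorithm == "smoteboost") {
    n_new <- max(0, ceiling(plan$target_ratio * length(majority)) -
                      length(minority))
    k <- min(plan$k_neighbors, length(minority) - 1L)
    if (n_new == 0 || k < 1) {
      return(list(data = cbind(df, label = yf), w = w * length(w)))
    }
    synth <- smote_oversample(as.matrix(df[minority, , drop = FALSE]),
                              n_new = n_new, k = k, seed = NULL)
    sdf <- as.data.frame(synth)
    names(sdf) <- names(df)
    data <- rbind(cbind(df, label = yf),
                  cbind(sdf, label = factor(yf[minority[1]],
                                            levels = levels(yf))))
    ws <- c(w, rep(mean(w[minority]), n_new))
    return(list(data = data, w = ws / sum(ws) * length(ws)))
  }
  # undersampling variants: keep all minority, reduce majority
  n_keep <- min(length(majority),
                max(1L, ceiling(length(minority) / plan$target_ratio)))
  kept <- if (algorithm == "rusboost") {
    attr(random_undersample(as.matrix(df[majority, , drop = FALSE]),
                            n_keep, seed = NULL, weights = w[majority]),
         "idx")
  } else {
    attr(cluster_undersample(as.matrix(df[majority, , drop = FALSE]),
                             n_clusters = plan$n_clusters, n_keep = n_keep,
                             seed = NULL, weights = w[majority]), "idx")
  }
  idx <- sort(c(minority, majority[kept]))  # original order: rpart split
  ws <- w[idx]                              # tie-breaks are order-sensitive
  list(data = cbind(df[idx, , drop = FALSE], label = yf[idx]),
       w = ws / sum(ws) * length(ws))
}

to_binary <- function(y) {
  if (is.factor(y)) as.integer(y == levels(y)[2])
  else if (is.logical(y)) as.integer(y)
  else if (is.character(y)) as.integer(y == "aggressive")
  else as.integer(y)
}

#' Predict from a boosting ensemble
#'
#' The score is the vote-weighted mean of the weak learners' positive-class
#' probabilities, `sum(alpha_t p_t(x)) / sum(alpha_t)`, a value in [0, 1];
#' `type = "class"` thresholds it at 0.5.
#'
#' @param object An [boost_fit()] ensemble.
#' @param newdata Feature matrix with the training columns.
#' @param type `"score"` (default) or `"class"`.
#' @param ... Unused.
#' @return Numeric scores in [0, 1], or integer 0/1 labels.
#' @export
predict.acr_boost <- function(object, newdata, type = c("score", "class"),
                              ...) {
  type <- match.arg(type)
  if (!length(object$trees)) stop_acr("empty ensemble", class = "acr_predict_error")
  df <- as.data.frame(as.matrix(newdata))
  names(df) <- object$feature_names
  probs <- vapply(object$trees,
                  function(tr) predict(tr, df, type = "prob")[, "1"],
                  numeric(nrow(df)))
  probs <- matrix(probs, nrow = nrow(df))
  score <- as.numeric(probs %*% object$alpha) / sum(object$alpha)
  if (type == "class") as.integer(score >= 0.5) else score
}

#' Score samples with a fitted model
#'
#' Generic positive-class scoring interface shared by the hand-written
#' boosting ensembles and the gradient-boosted baseline.
#'
#' @param model A fitted model object.
#' @param x Feature matrix.
#' @return Numeric vector of scores in [0, 1].
#' @export
predict_score <- function(model, x) UseMethod("predict_score")

#' @export
predict_score.acr_boost <- function(model, x) predict(model, x, type = "score")

#' @export
print.acr_boost <- function(x, ...) {
  cat(sprintf("<acr_boost> %s: %d/%d rounds kept, depth-%d trees\n",
              x$algorithm, x$rounds, x$rounds_requested, x$tree_depth))
  cat(sprintf("  training error %.4f (exp-loss bound %.4f)\n",
              x$train_error, x$loss_bound))
  invisible(x)
}

#' @export
summary.acr_boost <- function(object, ...) {
  out <- list(algorithm = object$algorithm, rounds = object$rounds,
              tree_depth = object$tree_depth,
              epsilon = object$epsilon, alpha = object$alpha,
              train_error = object$train_error,
              loss_bound = object$loss_bound,
              class_costs = object$class_costs)
  class(out) <- "summary.acr_boost"
  out
}

#' @export
print.summary.acr_boost <- function(x, ...) {
  cat(sprintf("Boosting ensemble (%s), %d rounds of depth-%d trees\n",
              x$algorithm, x$rounds, x$tree_depth))
  cat(sprintf("  class costs (neg, pos): %.3f, %.3f\n",
              x$class_costs[1], x$class_costs[2]))
  cat(sprintf("  weighted errors: min %.3f, median %.3f, max %.3f\n",
              min(x$epsilon), stats::median(x$epsilon), max(x$epsilon)))
  cat(sprintf("  training error %.4f <= exponential-loss bound %.4f\n",
              x$train_error, x$loss_bound))
  invisible(x)
}
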