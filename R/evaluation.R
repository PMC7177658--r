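#' Precision, recall and F1 from confusion counts
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `F1 = 2 * precision * recall / (precision + recall)`. Any 0/0 is defined
#' as 0 with a warning.
#'
#' @param tp,fp,fn,tn Non-negative integer counts (`tn` is only used for the
#'   total).
#' @return Named list `precision`, `recall`, `f1`.
#' @export
classification_metrics <- function(tp, fp, fn, tn = 0) {
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " is 0/0; defined as 0", call. = FALSE)
      0
    } else num / den
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) {
    warning("F1 is 0/0; defined as 0", call. = FALSE)
    0
  } else 2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1)
}

confusion_counts <- function(truth01, pred01) {
  list(tp = sum(truth01 == 1 & pred01 == 1),
       fp = sum(truth01 == 0 & pred01 == 1),
       fn = sum(truth01 == 1 & pred01 == 0),
       tn = sum(truth01 == 0 & pred01 == 0))
}

#' Precision-recall curve and AUPRC
#'
#' Sweeps every distinct score as a threshold (descending, ties grouped) and
#' accumulates step-wise average precision:
#' `AUPRC = sum (R_i - R_{i-1}) * P_i`. No linear interpolation is applied in
#' PR space (interpolation there is known to be optimistic).
#'
#' @param labels 0/1 labels (both classes must be present).
#' @param scores Numeric scores, higher = more positive.
#' @return Object of class `pr_curve`: data frame `points`
#'   (`threshold`, `recall`, `precision`) and scalar `auprc`.
#' @export
pr_curve <- function(labels, scores) {
  y <- to_binary(labels)
  if (length(unique(y)) < 2) stop_acr("both classes required for a PR curve",
                                      class = "acr_eval_error")
  stopifnot(length(y) == length(scores))
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]; s <- scores[ord]
  grp_last <- which(!duplicated(s, fromLast = TRUE))  # last index of each tie group
  tp <- cumsum(y)[grp_last]
  pp <- grp_last  # predicted positive count at each cut
  n_pos <- sum(y)
  recall <- tp / n_pos
  precision <- tp / pp
  auprc <- sum(diff(c(0, recall)) * precision)
  structure(list(points = data.frame(threshold = s[grp_last],
                                     recall = recall,
                                     precision = precision),
                 auprc = auprc, n_pos = n_pos, n = length(y)),
            class = "pr_curve")
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("<pr_curve> %d points, AUPRC = %.4f (prevalence %.3f)\n",
              nrow(x$points), x$auprc, x$n_pos / x$n))
  invisible(x)
}

#' @export
plot.pr_curve <- function(x, ...) {
  plot(c(0, x$points$recall), c(1, x$points$precision), type = "s",
       xlab = "Recall", ylab = "Precision", xlim = c(0, 1), ylim = c(0, 1),
       main = sprintf("PR curve (AUPRC = %.3f)", x$auprc), ...)
  abline(h = x$n_pos / x$n, lty = 3)
  invisible(x)
}

# Stratified fold assignment: per class, shuffle then deal round-robin.
# Fold sizes per class differ by at most one.
stratified_folds <- function(y01, k, seed = NULL) {
  with_seed(seed, {
    fold <- integer(length(y01))
    for (cls in unique(y01)) {
      idx <- which(y01 == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Repeated stratified k-fold cross-validation
#'
#' Per repeat, a seeded stratified partition preserves the class proportions
#' in every fold. All resampling and any grid search happen inside the
#' training folds only; the held-out fold is scored once. Hard-label metrics
#' use the 0.5 score threshold; AUPRC comes from the fold's PR curve.
#'
#' @param fm A [build_feature_matrix()] result (or list with `x`, `y`).
#' @param spec A [model_spec()].
#' @param folds,repeats CV geometry (default 5 x 5).
#' @param seed Integer master seed.
#' @param grid Optional hyperparameter grid (data frame with columns among
#'   `rounds`, `tree_depth`, `eta`) searched by [grid_search()] inside each
#'   training set.
#' @return Object of class `eval_report`: `per_fold` data frame
#'   (`repeat`, `fold`, `precision`, `recall`, `f1`, `auprc`) and `summary`
#'   (their unweighted means).
#' @export
repeated_stratified_cv <- function(fm, spec, folds = 5, repeats = 5,
                                   seed = 1L, grid = NULL) {
  x <- fm$x; y01 <- to_binary(fm$y)
  if (sum(y01 == 1) < folds || sum(y01 == 0) < folds) {
    stop_acr("each class needs at least `folds` members",
             class = "acr_cv_error")
  }
  rows <- vector("list", folds * repeats)
  assignments <- matrix(NA_integer_, length(y01), repeats)
  i <- 0
  for (r in seq_len(repeats)) {
    fold <- stratified_folds(y01, folds, seed = child_seed(seed, r))
    assignments[, r] <- fold
    for (f in seq_len(folds)) {
      test <- fold == f
      xtr <- x[!test, , drop = FALSE]; ytr <- y01[!test]
      fit_seed <- child_seed(seed, 100L * r + f)
      use_spec <- spec
      if (!is.null(grid)) {
        best <- grid_search(xtr, ytr, spec, grid, inner_folds = 3,
                            seed = fit_seed)
        use_spec <- best$spec
      }
      model <- fit_model(use_spec, xtr, ytr, seed = fit_seed)
      sc <- predict_score(model, x[test, , drop = FALSE])
      cc <- confusion_counts(y01[test], as.integer(sc >= 0.5))
      met <- suppressWarnings(classification_metrics(cc$tp, cc$fp, cc$fn, cc$tn))
      auprc <- if (length(unique(y01[test])) == 2) {
        pr_curve(y01[test], sc)$auprc
      } else NA_real_
      i <- i + 1
      rows[[i]] <- data.frame(rep = r, fold = f,
                              precision = met$precision, recall = met$recall,
                              f1 = met$f1, auprc = auprc)
    }
  }
  per_fold <- do.call(rbind, rows)
  structure(list(
    per_fold = per_fold,
    summary = colMeans(per_fold[, c("precision", "recall", "f1", "auprc")],
                       na.rm = TRUE),
    algorithm = spec$algorithm, folds = folds, repeats = repeats,
    seed = seed, fold_assignments = assignments),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s, %dx%d-fold CV (seed %d)\n", x$algorithm,
              x$repeats, x$folds, x$seed))
  s <- x$summary
  cat(sprintf("  precision %.3f  recall %.3f  F1 %.3f  AUPRC %.3f\n",
              s["precision"], s["recall"], s["f1"], s["auprc"]))
  invisible(x)
}

#' Exhaustive grid search by inner stratified CV
#'
#' Evaluates every grid point with `inner_folds`-fold stratified CV on the
#' supplied training data, maximising mean AUPRC. Ties break toward the
#' smaller model: fewer rounds first, then shallower trees.
#'
#' @param x,y Training data (never the held-out fold).
#' @param spec Base [model_spec()]; grid columns override its fields.
#' @param grid Data frame whose columns are a subset of
#'   `c("rounds", "tree_depth", "eta")`.
#' @param inner_folds Inner CV folds.
#' @param seed Integer seed.
#' @return List `spec` (best model spec), `mean_auprc`, `results` (grid with
#'   scores).
#' @export
grid_search <- function(x, y, spec, grid, inner_folds = 3, seed = 1L) {
  stopifnot(nrow(grid) >= 1)
  grid <- unique(grid)
  y01 <- to_binary(y)
  fold <- stratified_folds(y01, inner_folds, seed = child_seed(seed, 999L))
  scores <- vapply(seq_len(nrow(grid)), function(g) {
    sp <- spec
    for (col in names(grid)) sp[[col]] <- grid[[col]][g]
    aucs <- vapply(seq_len(inner_folds), function(f) {
      test <- fold == f
      if (length(unique(y01[test])) < 2 || length(unique(y01[!test])) < 2) {
        return(NA_real_)
      }
      model <- fit_model(sp, x[!test, , drop = FALSE], y01[!test],
                         seed = child_seed(seed, 1000L + f))
      pr_curve(y01[test], predict_score(model, x[test, , drop = FALSE]))$auprc
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }, numeric(1))
  size_rounds <- if ("rounds" %in% names(grid)) grid$rounds else rep(0, nrow(grid))
  size_depth <- if ("tree_depth" %in% names(grid)) grid$tree_depth else rep(0, nrow(grid))
  ord <- order(-scores, size_rounds, size_depth)
  best <- ord[1]
  sp <- spec
  for (col in names(grid)) sp[[col]] <- grid[[col]][best]
  list(spec = sp, mean_auprc = scores[best],
       results = cbind(grid, mean_auprc = scores))
}
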