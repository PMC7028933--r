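# Gradient-boosted response classifier and its evaluation protocol:
# stage-wise regression trees on the binomial deviance (src/boost.cpp),
# tuned and assessed by repeated stratified k-fold cross-validation with
# all held-out predictions pooled and compared against the no-information
# rate by an exact one-sided binomial test.

#' Gradient-boosting configuration
#'
#' @param n_trees Number of boosting iterations.
#' @param max_depth Maximum tree depth (1 = stumps).
#' @param shrinkage Learning rate in (0, 1].
#' @param min_node Minimum observations per terminal node.
#' @return Object of class `boost_config`.
#' @export
boost_config <- function(n_trees = 100, max_depth = 2, shrinkage = 0.1,
                         min_node = 10) {
  stopifnot(n_trees >= 0, max_depth >= 1, shrinkage > 0, shrinkage <= 1,
            min_node >= 1)
  structure(list(n_trees = as.integer(n_trees),
                 max_depth = as.integer(max_depth),
                 shrinkage = shrinkage, min_node = as.integer(min_node)),
            class = "boost_config")
}

#' Default tuning grid
#'
#' Boosting iterations 50/100/150, depth 1/2/3, shrinkage 0.1 and minimum
#' node size 5/10 — the conventional small grid for gradient boosting on
#' cohort-sized data.
#'
#' @return Tibble with one row per candidate configuration.
#' @export
default_tuning_grid <- function() {
  tidyr::expand_grid(n_trees = c(50L, 100L, 150L), max_depth = 1:3,
                     shrinkage = 0.1, min_node = c(5L, 10L))
}

#' Cross-validation configuration
#'
#' @param k Number of folds (>= 2).
#' @param repeats Number of repeats (>= 1).
#' @param stratified Stratify folds by class (default TRUE).
#' @param seed Integer seed controlling the fold assignments.
#' @return Object of class `cv_config`.
#' @export
cv_config <- function(k = 5, repeats = 2, stratified = TRUE, seed = 1) {
  stopifnot(k >= 2, repeats >= 1)
  structure(list(k = as.integer(k), repeats = as.integer(repeats),
                 stratified = isTRUE(stratified), seed = as.integer(seed)),
            class = "cv_config")
}

as_feature_matrix <- function(features) {
  if (is.data.frame(features)) {
    num <- vapply(features, is.numeric, logical(1))
    features <- as.matrix(features[num])
  }
  storage.mode(features) <- "double"
  features
}

check_labels <- function(y, n) {
  if (is.logical(y)) y <- as.integer(y)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  stopifnot(length(y) == n, all(y %in% c(0, 1)))
  if (length(unique(y)) < 2) {
    stop("labels contain a single class (degenerate)", call. = FALSE)
  }
  y
}

#' Fit a gradient-boosted tree classifier
#'
#' An additive model of depth-limited regression trees fit stage-wise on
#' the binomial log-loss: the initial score is the prevalence log-odds, and
#' each stage fits a tree to the current residual `y - p` (squared-error
#' split search honoring `min_node`), takes a Newton leaf step
#' `sum(r) / sum(p (1 - p))`, and adds it scaled by the shrinkage. No rows
#' or columns are subsampled, so the fit is deterministic; `seed` is kept
#' in the interface (and recorded) for forward compatibility with
#' stochastic variants.
#'
#' @param features Data frame or numeric matrix of predictors (data-frame
#'   first: non-numeric columns such as `animal_id` are dropped).
#' @param y Binary labels (0/1, logical, or 2-level factor; 1 = positive
#'   class = responder by convention).
#' @param config A [boost_config()].
#' @param seed Integer, recorded in the model.
#' @return Object of class `icb_boost` with [predict()][predict.icb_boost],
#'   [tidy()] (feature importances) and [glance()] methods.
#' @examples
#' fit <- fit_boosted_trees(data.frame(x = c(0, 1, 2, 3)), c(0, 0, 1, 1),
#'                          boost_config(n_trees = 50, max_depth = 1,
#'                                       shrinkage = 0.5, min_node = 1))
#' predict(fit, data.frame(x = c(0, 3)))
#' @export
fit_boosted_trees <- function(features, y, config = boost_config(),
                              seed = 1L) {
  stopifnot(inherits(config, "boost_config"))
  x <- as_feature_matrix(features)
  if (anyNA(x)) stop("missing values in features", call. = FALSE)
  y <- check_labels(y, nrow(x))
  fit <- .gbm_fit_cpp(x, y, config$n_trees, config$max_depth,
                      config$shrinkage, config$min_node)
  fit$shrinkage <- config$shrinkage
  imp <- fit$importance
  total <- sum(imp)
  structure(list(
    fit = fit,
    config = config,
    feature_names = colnames(x),
    importance = if (total > 0) imp / total else imp,
    train_logloss = fit$train_logloss,
    seed = as.integer(seed)
  ), class = "icb_boost")
}

#' @export
print.icb_boost <- function(x, ...) {
  cat(sprintf("<icb_boost> %d trees, depth %d, shrinkage %g, min node %d, %d features\n",
              x$config$n_trees, x$config$max_depth, x$config$shrinkage,
              x$config$min_node, length(x$feature_names)))
  invisible(x)
}

#' Predicted response probabilities from a boosted model
#'
#' @param object An `icb_boost` fit.
#' @param newdata Data frame or matrix with the training feature columns.
#' @param n_trees Use only the first `n_trees` stages (default: all).
#' @param ... Unused.
#' @return Numeric vector of probabilities for the positive class.
#' @export
predict.icb_boost <- function(object, newdata, n_trees = -1L, ...) {
  x <- as_feature_matrix(newdata)
  if (!is.null(object$feature_names) && !is.null(colnames(x))) {
    missing <- setdiff(object$feature_names, colnames(x))
    if (length(missing)) {
      stop("missing feature columns: ", paste(head(missing, 3), collapse = ", "),
           call. = FALSE)
    }
    x <- x[, object$feature_names, drop = FALSE]
  }
  as.numeric(.gbm_predict_cpp(object$fit, x, as.integer(n_trees)))
}

#' Per-feature importance of a boosted model
#'
#' Total squared-error reduction accumulated over all splits using the
#' feature, normalized to sum to one, in descending order. Features never
#' used in a split have importance zero.
#'
#' @param model An `icb_boost` fit.
#' @return Tibble with columns `feature` and `importance`.
#' @export
feature_importance <- function(model) {
  if (!inherits(model, "icb_boost")) stop("need an icb_boost fit", call. = FALSE)
  nm <- model$feature_names
  if (is.null(nm)) nm <- paste0("x", seq_along(model$importance))
  tibble::tibble(feature = nm, importance = model$importance) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' @exportS3Method generics::tidy
tidy.icb_boost <- function(x, ...) {
  feature_importance(x)
}

#' @exportS3Method generics::glance
glance.icb_boost <- function(x, ...) {
  tibble::tibble(
    n_trees = x$config$n_trees,
    max_depth = x$config$max_depth,
    shrinkage = x$config$shrinkage,
    min_node = x$config$min_node,
    final_train_logloss = utils::tail(x$train_logloss, 1)
  )
}

stratified_folds <- function(y, k, stratified = TRUE) {
  n <- length(y)
  fold <- integer(n)
  if (stratified) {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    fold[sample(n)] <- rep_len(seq_len(k), n)
  }
  fold
}

#' Tune the boosting configuration by inner cross-validation
#'
#' Evaluates every grid row by `cv`-fold cross-validated accuracy and
#' returns the winner; ties are broken toward fewer boosting iterations,
#' then shallower trees.
#'
#' @param features,y As in [fit_boosted_trees()].
#' @param grid Data frame of candidate configurations (columns `n_trees`,
#'   `max_depth`, `shrinkage`, `min_node`); default [default_tuning_grid()].
#' @param cv A [cv_config()] (its `repeats` applies here too).
#' @return The winning [boost_config()], with the per-candidate accuracies
#'   in the attribute `tuning_results`.
#' @export
tune_boost <- function(features, y, grid = default_tuning_grid(),
                       cv = cv_config(repeats = 1)) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1)
  x <- as_feature_matrix(features)
  y <- check_labels(y, nrow(x))
  acc <- vapply(seq_len(nrow(grid)), function(i) {
    cfg <- boost_config(grid$n_trees[i], grid$max_depth[i], grid$shrinkage[i],
                        grid$min_node[i])
    preds <- repeated_cv_predict(x, y, config = cfg, cv = cv,
                                 normalize = "none")
    mean((preds$prob > 0.5) == preds$truth)
  }, numeric(1))
  ord <- order(-acc, grid$n_trees, grid$max_depth)
  best <- ord[1]
  out <- boost_config(grid$n_trees[best], grid$max_depth[best],
                      grid$shrinkage[best], grid$min_node[best])
  attr(out, "tuning_results") <- dplyr::mutate(tibble::as_tibble(grid),
                                               accuracy = acc)
  out
}

#' Pooled held-out predictions from repeated stratified k-fold CV
#'
#' For each repeat the data are partitioned into `k` stratified folds; the
#' model is fit on k - 1 folds and predicts the held-out fold. All held-out
#' predictions are pooled, so each row is predicted `repeats` times.
#' Feature normalization is fit on the training folds only and applied to
#' the held-out fold (`normalize = "fold"`, the default, avoids
#' leakage); `"global"` reproduces whole-table z-scoring before splitting,
#' and `"none"` disables scaling.
#'
#' If a training split loses a class (possible only for tiny strata), the
#' fold assignment is redrawn with a shifted seed and a message is emitted.
#'
#' @param features,y As in [fit_boosted_trees()].
#' @param config A [boost_config()].
#' @param cv A [cv_config()].
#' @param normalize One of "fold", "global", "none".
#' @return Tibble with columns `row`, `repeat_id`, `fold`, `prob`, `pred`,
#'   `truth`.
#' @export
repeated_cv_predict <- function(features, y, config = boost_config(),
                                cv = cv_config(), normalize = "fold") {
  normalize <- match.arg(normalize, c("fold", "global", "none"))
  x <- as_feature_matrix(features)
  y <- check_labels(y, nrow(x))
  n <- nrow(x)
  if (n < cv$k) stop("need at least k rows", call. = FALSE)
  xg <- x
  if (normalize == "global") {
    xg <- as_feature_matrix(zscore_normalize(as.data.frame(x)))
  }
  out <- vector("list", cv$repeats * cv$k)
  slot <- 1
  for (rep_i in seq_len(cv$repeats)) {
    seed_i <- cv$seed + 1000L * (rep_i - 1L)
    repeat {
      set.seed(seed_i)
      fold <- stratified_folds(y, cv$k, cv$stratified)
      ok <- all(vapply(seq_len(cv$k), function(f) {
        length(unique(y[fold != f])) == 2
      }, logical(1)))
      if (ok) break
      seed_i <- seed_i + 1L
      message("refolding: a training split lost a class (new seed ", seed_i, ")")
    }
    for (f in seq_len(cv$k)) {
      tr <- fold != f
      if (normalize == "fold") {
        xtr <- x[tr, , drop = FALSE]
        mu <- colMeans(xtr)
        sdv <- sqrt(colSums(sweep(xtr, 2, mu)^2) / (nrow(xtr) - 1))
        sdv[sdv == 0] <- Inf # constant columns map to 0, as in zscore_normalize
        xtr <- sweep(sweep(xtr, 2, mu), 2, sdv, `/`)
        xte <- sweep(sweep(x[!tr, , drop = FALSE], 2, mu), 2, sdv, `/`)
      } else {
        xtr <- xg[tr, , drop = FALSE]
        xte <- xg[!tr, , drop = FALSE]
      }
      fit <- fit_boosted_trees(xtr, y[tr], config, seed = seed_i)
      prob <- predict(fit, xte)
      out[[slot]] <- tibble::tibble(
        row = which(!tr), repeat_id = rep_i, fold = f,
        prob = prob, pred = as.integer(prob > 0.5), truth = y[!tr]
      )
      slot <- slot + 1
    }
  }
  dplyr::bind_rows(out)
}

#' Rank-statistic AUROC with tie correction
#'
#' @param prob Predicted scores.
#' @param truth Binary labels.
#' @return The area under the ROC curve, or `NA` when only one class is
#'   present.
#' @export
auroc <- function(prob, truth) {
  n1 <- sum(truth == 1)
  n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(prob) # midranks handle ties
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate pooled held-out predictions against the no-information rate
#'
#' Accuracy at the 0.5 probability cutoff with an exact (Clopper-Pearson)
#' 95% confidence interval, sensitivity and specificity (positive class =
#' responder = 1), rank-statistic AUROC, the no-information rate (largest
#' class proportion), and a one-sided exact binomial test of whether the
#' accuracy exceeds the NIR. Rates are reported in percent.
#'
#' @param predictions Tibble from [repeated_cv_predict()] (columns `prob`,
#'   `truth`; `pred` is recomputed from `prob` at 0.5).
#' @return Object of class `evaluation_report`.
#' @export
evaluate_predictions <- function(predictions) {
  stopifnot(all(c("prob", "truth") %in% names(predictions)))
  prob <- predictions$prob
  truth <- predictions$truth
  pred <- as.integer(prob > 0.5)
  n <- length(truth)
  correct <- sum(pred == truth)
  accuracy <- correct / n
  ci <- as.numeric(binom.test(correct, n)$conf.int)
  nir <- max(mean(truth == 1), mean(truth == 0))
  p_nir <- binom.test(correct, n, p = nir, alternative = "greater")$p.value
  sens <- if (sum(truth == 1) > 0) sum(pred == 1 & truth == 1) / sum(truth == 1) else NA_real_
  spec <- if (sum(truth == 0) > 0) sum(pred == 0 & truth == 0) / sum(truth == 0) else NA_real_
  structure(list(
    n = n,
    accuracy = 100 * accuracy,
    ci_low = 100 * ci[1],
    ci_high = 100 * ci[2],
    sensitivity = 100 * sens,
    specificity = 100 * spec,
    auroc = auroc(prob, truth),
    no_information_rate = 100 * nir,
    binomial_p = p_nir,
    predictions = tibble::as_tibble(predictions)
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    paste0("Held-out evaluation (n = %d pooled predictions)\n",
           "  accuracy    %.1f%% (95%% CI %.1f-%.1f%%)\n",
           "  sensitivity %.1f%%  specificity %.1f%%\n",
           "  AUROC       %.3f\n",
           "  NIR         %.1f%%  (one-sided binomial p = %.3g)\n"),
    x$n, x$accuracy, x$ci_low, x$ci_high, x$sensitivity, x$specificity,
    x$auroc, x$no_information_rate, x$binomial_p))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.evaluation_report <- function(x, ...) {
  tibble::tibble(
    metric = c("accuracy", "ci_low", "ci_high", "sensitivity", "specificity",
               "auroc", "no_information_rate", "binomial_p"),
    value = c(x$accuracy, x$ci_low, x$ci_high, x$sensitivity, x$specificity,
              x$auroc, x$no_information_rate, x$binomial_p)
  )
}

#' @exportS3Method generics::glance
glance.evaluation_report <- function(x, ...) {
  tibble::tibble(
    n = x$n, accuracy = x$accuracy, ci_low = x$ci_low, ci_high = x$ci_high,
    sensitivity = x$sensitivity, specificity = x$specificity,
    auroc = x$auroc, no_information_rate = x$no_information_rate,
    binomial_p = x$binomial_p
  )
}

#' Train and evaluate the response classifier end to end
#'
#' Convenience wrapper: optional tuning, repeated stratified CV with
#' fold-wise normalization, pooled evaluation against the NIR, and feature
#' importances from a final fit on all data.
#'
#' @param features Feature data frame (e.g. baseline + delta radiomics).
#' @param labels Data frame with a `responder` column (or a bare vector).
#' @param config A [boost_config()], or `NULL` to tune over `grid`.
#' @param grid Tuning grid used when `config` is NULL.
#' @param cv A [cv_config()].
#' @param normalize Passed to [repeated_cv_predict()].
#' @return List with `report` (an `evaluation_report`), `config`,
#'   `importance` and `model` (the final all-data fit).
#' @export
train_evaluate <- function(features, labels, config = boost_config(),
                           grid = default_tuning_grid(), cv = cv_config(),
                           normalize = "fold") {
  y <- if (is.data.frame(labels)) labels$responder else labels
  if (is.null(config)) config <- tune_boost(features, y, grid, cv)
  preds <- repeated_cv_predict(features, y, config, cv, normalize)
  report <- evaluate_predictions(preds)
  x <- as_feature_matrix(features)
  model <- fit_boosted_trees(if (normalize == "none") x else
    as_feature_matrix(zscore_normalize(as.data.frame(x))),
    check_labels(y, nrow(x)), config, seed = cv$seed)
  list(report = report, config = config,
       importance = feature_importance(model), model = model)
}
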