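# The gradient-boosted learner, its resampling protocol and the
# NIR-referenced evaluation.

test_that("boosting separates a trivial 1D problem and honors the prior", {
  x <- data.frame(x = c(0, 1, 2, 3))
  y <- c(0, 0, 1, 1)
  fit <- fit_boosted_trees(x, y, boost_config(n_trees = 50, max_depth = 1,
                                              shrinkage = 0.5, min_node = 1))
  expect_equal(as.integer(predict(fit, x) > 0.5), y)
  # zero iterations: predicted probability is the class prevalence
  fit0 <- fit_boosted_trees(x, y, boost_config(n_trees = 0, max_depth = 1,
                                               shrinkage = 0.5, min_node = 1))
  expect_equal(predict(fit0, x), rep(0.5, 4))
  expect_error(fit_boosted_trees(x, c(1, 1, 1, 1), boost_config()),
               "single class")
})

test_that("training log-loss is non-increasing across stages", {
  set.seed(42)
  n <- 80
  X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- as.integer(X$a + 0.5 * X$b + rnorm(n, 0, 0.7) > 0)
  fit <- fit_boosted_trees(X, y, boost_config(n_trees = 80, max_depth = 2,
                                              shrinkage = 0.05))
  expect_true(all(diff(fit$train_logloss) <= 1e-10))
})

test_that("feature importance is normalized and identifies the signal", {
  set.seed(1)
  n <- 120
  X <- data.frame(noise1 = rnorm(n), signal = rnorm(n), noise2 = rnorm(n))
  y <- as.integer(X$signal > 0)
  fit <- fit_boosted_trees(X, y, boost_config(n_trees = 40, max_depth = 1))
  imp <- feature_importance(fit)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-12)
  expect_equal(imp$feature[1], "signal")
  expect_true(imp$importance[1] > 0.9)
  expect_identical(tidy(fit), imp)
})

test_that("repeated stratified CV predicts every row `repeats` times", {
  set.seed(2)
  n <- 40
  X <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- rep(c(0, 1), n / 2)
  preds <- repeated_cv_predict(X, y, boost_config(n_trees = 20),
                               cv_config(k = 5, repeats = 2, seed = 3))
  expect_equal(nrow(preds), 2 * n)
  expect_equal(as.integer(table(preds$row)), rep(2L, n))
  # leave-one-out, one repeat: each row exactly once
  loo <- repeated_cv_predict(X, y, boost_config(n_trees = 5),
                             cv_config(k = n, repeats = 1, seed = 3,
                                       stratified = FALSE))
  expect_equal(sort(loo$row), 1:n)
  # determinism
  preds2 <- repeated_cv_predict(X, y, boost_config(n_trees = 20),
                                cv_config(k = 5, repeats = 2, seed = 3))
  expect_identical(preds$prob, preds2$prob)
})

test_that("separable data are recovered and label-free data stay at NIR", {
  set.seed(5)
  n <- 80
  # wide margin
  Xs <- data.frame(f = c(rnorm(n / 2, -3), rnorm(n / 2, 3)))
  ys <- rep(c(0, 1), each = n / 2)
  ps <- repeated_cv_predict(Xs, ys, boost_config(n_trees = 40),
                            cv_config(seed = 7))
  expect_gte(mean((ps$prob > 0.5) == ps$truth), 0.95)
  # label-free features: pooled accuracy within binomial noise of the NIR
  hits <- 0
  for (s in 1:5) {
    set.seed(100 + s)
    Xn <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
    yn <- rbinom(n, 1, 0.5)
    if (length(unique(yn)) < 2) next
    pn <- repeated_cv_predict(Xn, yn, boost_config(n_trees = 30),
                              cv_config(seed = s))
    rep <- evaluate_predictions(pn)
    if (rep$binomial_p < 0.05) hits <- hits + 1
  }
  expect_lte(hits, 1)
})

test_that("evaluation metrics match their oracles", {
  # perfect predictions
  perfect <- tibble::tibble(prob = c(0.9, 0.8, 0.1, 0.2),
                            truth = c(1, 1, 0, 0))
  r <- evaluate_predictions(perfect)
  expect_equal(r$accuracy, 100)
  expect_equal(r$auroc, 1)
  expect_equal(r$sensitivity, 100)
  expect_equal(r$specificity, 100)
  # 9 of 10 correct vs NIR 0.5: exact binomial tail 11/1024
  nine <- tibble::tibble(prob = c(rep(0.9, 4), 0.1, rep(0.1, 5)),
                         truth = c(rep(1, 5), rep(0, 5)))
  r9 <- evaluate_predictions(nine)
  expect_equal(r9$no_information_rate, 50)
  expect_equal(r9$binomial_p, 11 / 1024, tolerance = 1e-12)
  expect_equal(r9$binomial_p, binom_tail_oracle(9, 10, 0.5), tolerance = 1e-12)
  # constant majority-class predictions never beat the NIR
  maj <- tibble::tibble(prob = rep(0.9, 20), truth = rep(c(1, 0), c(14, 6)))
  rm <- evaluate_predictions(maj)
  expect_equal(rm$accuracy, rm$no_information_rate)
  expect_gte(rm$binomial_p, 0.5)
})

test_that("AUROC equals brute-force pairwise concordance, ties included", {
  set.seed(9)
  for (i in 1:5) {
    n <- 200
    prob <- round(runif(n), 2) # deliberate ties
    truth <- rbinom(n, 1, 0.4)
    expect_equal(auroc(prob, truth), concordance_oracle(prob, truth),
                 tolerance = 1e-7)
  }
  expect_true(is.na(auroc(runif(5), rep(1, 5))))
})

test_that("Clopper-Pearson CI matches direct beta-quantile evaluation", {
  for (cs in list(c(83, 100), c(248, 300), c(0, 20), c(20, 20))) {
    x <- cs[1]; n <- cs[2]
    ci <- binom.test(x, n)$conf.int
    lo <- if (x == 0) 0 else qbeta(0.025, x, n - x + 1)
    hi <- if (x == n) 1 else qbeta(0.975, x + 1, n - x)
    expect_equal(as.numeric(ci), c(lo, hi), tolerance = 1e-9)
    preds <- tibble::tibble(prob = c(rep(0.9, x), rep(0.1, n - x)),
                            truth = rep(1, n))
    # evaluation reports the same interval (in percent)
    if (x > 0 && x < n) {
      r <- evaluate_predictions(preds)
      expect_equal(c(r$ci_low, r$ci_high) / 100, c(lo, hi), tolerance = 1e-9)
    }
  }
})

test_that("tuning picks the dominating point and breaks ties as documented", {
  set.seed(3)
  n <- 60
  X <- data.frame(f = c(rnorm(n / 2, -2), rnorm(n / 2, 2)))
  y <- rep(c(0, 1), each = n / 2)
  one <- data.frame(n_trees = 30L, max_depth = 1L, shrinkage = 0.1,
                    min_node = 5L)
  expect_equal(tune_boost(X, y, one, cv_config(k = 3, repeats = 1))$n_trees, 30L)
  # a configuration that cannot learn (min_node = n) loses to one that can
  grid <- data.frame(n_trees = c(30L, 30L), max_depth = c(1L, 1L),
                     shrinkage = 0.1, min_node = c(5L, 60L))
  best <- tune_boost(X, y, grid, cv_config(k = 3, repeats = 1, seed = 2))
  expect_equal(best$min_node, 5L)
  # exact tie on accuracy: fewer iterations win
  tie <- data.frame(n_trees = c(50L, 10L), max_depth = 1L, shrinkage = 0.1,
                    min_node = 5L)
  best2 <- tune_boost(X, y, tie, cv_config(k = 3, repeats = 1, seed = 2))
  acc <- attr(best2, "tuning_results")$accuracy
  if (acc[1] == acc[2]) expect_equal(best2$n_trees, 10L)
})
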