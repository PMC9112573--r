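# A small stack/store where the outcome depends on x1 only and x2 is pure
# noise, built on the toy 3-predictor schema.
toy_store <- function(n = 800, seed = 31, task = "continuous") {
  withr::with_seed(seed, {
    d <- tibble::tibble(
      patient_id = sprintf("p%04d", 1:n),
      region = sample(region_levels()[1:3], n, replace = TRUE),
      x1 = rnorm(n), x2 = rnorm(n), b1 = rbinom(n, 1, 0.5)
    )
    if (task == "continuous") {
      d$y_cont <- round(pmin(27, pmax(0, 10 + 4 * d$x1 + rnorm(n, 0, 1))))
      d$y_bin <- rbinom(n, 1, 0.4)
    } else {
      d$y_bin <- rbinom(n, 1, plogis(2 * d$x1))
      d$y_cont <- 10L
    }
  })
  stack <- structure(list(datasets = list(d), m = 1L, seed = seed),
                     class = "imputation_stack")
  elig <- seq_len(n)
  plans <- make_bootstrap_plans(n, 1, 4, seed = seed)
  store <- generate_oob_predictions(
    stack, plans, task, schema = toy_schema(),
    learners = "ridge", ridge_lambda = 0.1, keep_models = 3, seed = seed)
  list(stack = stack, store = store, data = d)
}

test_that("null predictors score near zero; signal predictors dominate", {
  fx <- toy_store()
  rec <- permutation_importance(fx$store, fx$stack,
                                features = c("x1", "x2"), metric = "MAE",
                                n_models = 3, n_shuffles = 30,
                                schema = toy_schema(), seed = 1)
  imp_x1 <- rec$pct_change[rec$feature == "x1"]
  imp_x2 <- rec$pct_change[rec$feature == "x2"]
  per_model <- attr(rec, "per_model")$ridge
  se_x2 <- sd(per_model[, "x2"]) / sqrt(nrow(per_model))
  expect_lt(abs(imp_x2), 2 * max(se_x2, 0.2))
  expect_gt(imp_x1, 20)
  expect_gt(imp_x1, 10 * abs(imp_x2))
})

test_that("importance runs are reproducible and never corrupt the eval data", {
  fx <- toy_store(n = 400, seed = 37)
  before <- fx$stack$datasets[[1]]
  r1 <- permutation_importance(fx$store, fx$stack, features = "x1",
                               metric = "MAE", n_models = 2, n_shuffles = 10,
                               schema = toy_schema(), seed = 5)
  r2 <- permutation_importance(fx$store, fx$stack, features = "x1",
                               metric = "MAE", n_models = 2, n_shuffles = 10,
                               schema = toy_schema(), seed = 5)
  expect_identical(r1$pct_change, r2$pct_change)
  expect_identical(fx$stack$datasets[[1]], before)

  # unpermuted score unchanged after the run
  k <- fx$store$kept[[1]]
  eval_data <- fx$stack$datasets[[k$imputation]][k$oob, ]
  s1 <- mae(eval_data$y_cont, predict(k$model, eval_data))
  invisible(permutation_importance(fx$store, fx$stack, features = "x2",
                                   metric = "MAE", n_models = 1,
                                   n_shuffles = 5, schema = toy_schema(),
                                   seed = 9))
  s2 <- mae(eval_data$y_cont, predict(k$model, eval_data))
  expect_identical(s1, s2)
})

test_that("metric/task mismatches and unknown features raise typed errors", {
  fx <- toy_store(n = 200, seed = 41)
  expect_error(permutation_importance(fx$store, fx$stack, features = "x1",
                                      metric = "AUC", schema = toy_schema()),
               class = "metastackr_invalid_argument")
  expect_error(permutation_importance(fx$store, fx$stack,
                                      features = "nope", metric = "MAE",
                                      schema = toy_schema()),
               class = "metastackr_invalid_argument")
})

test_that("identical meta inputs share importance; removing both kills discrimination", {
  withr::with_seed(43, {
    n <- 600
    a <- runif(n)
    y <- rbinom(n, 1, plogis(4 * a - 2))
  })
  f <- tibble::tibble(pred_ridge = a, pred_mlp = a)
  fit <- suppressWarnings(fit_meta_linear(f, y, "binary"))
  rec <- meta_importance(list(meta_linear = fit), f, y, metric = "AUC",
                         n_shuffles = 40, seed = 3)
  v <- rec$pct_change
  expect_lt(abs(v[1] - v[2]), 1.5)  # symmetry within permutation noise
  expect_gt(min(v), 0)

  # shuffling BOTH prediction columns destroys all information: AUC ~ 0.5
  withr::with_seed(44, {
    shuffled <- f
    shuffled$pred_ridge <- sample(shuffled$pred_ridge)
    shuffled$pred_mlp <- sample(shuffled$pred_mlp)
  })
  expect_lt(abs(auc(y, predict(fit, shuffled)) - 0.5), 0.06)
})

test_that("meta importance mirrors which base-learner carries the signal", {
  withr::with_seed(47, {
    n <- 800
    good <- rnorm(n)
    y <- 3 * good + rnorm(n, 0, 0.5)
    f <- tibble::tibble(pred_ridge = good, pred_mlp = rnorm(n))
  })
  fit <- fit_meta_linear(f, y, "continuous")
  rec <- meta_importance(list(meta_linear = fit), f, y, metric = "MAE",
                         n_shuffles = 30, seed = 7)
  ridge_imp <- rec$pct_change[rec$feature == "pred_ridge"]
  mlp_imp <- rec$pct_change[rec$feature == "pred_mlp"]
  expect_gt(ridge_imp, 100)
  expect_lt(abs(mlp_imp), 2)
  expect_gt(abs(attr(rec, "ratio")$meta_linear), 10)
})
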