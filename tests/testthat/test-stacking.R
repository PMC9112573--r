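test_that("bootstrap plans have exact counts, sizes and complements", {
  plans <- make_bootstrap_plans(50, m = 10, B = 20, seed = 1)
  expect_equal(nrow(plans), 200)
  expect_equal(unique(lengths(plans$in_sample)), 50L)
  for (i in sample(200, 20)) {
    ins <- plans$in_sample[[i]]
    oob <- plans$oob[[i]]
    expect_length(intersect(oob, unique(ins)), 0)
    expect_setequal(union(oob, unique(ins)), 1:50)
  }
  expect_identical(plans, make_bootstrap_plans(50, 10, 20, seed = 1))

  p1 <- make_bootstrap_plans(1, 1, 1, seed = 2)
  expect_identical(p1$in_sample[[1]], 1L)
  expect_length(p1$oob[[1]], 0)
  expect_error(make_bootstrap_plans(0, 1, 1),
               class = "metastackr_invalid_argument")
})

test_that("mean unique in-sample fraction approaches 1 - 1/e", {
  plans <- make_bootstrap_plans(1000, m = 10, B = 20, seed = 3)
  frac <- mean(vapply(plans$in_sample,
                      function(s) length(unique(s)) / 1000, numeric(1)))
  expect_lt(abs(frac - 0.632), 0.01)
})

test_that("OOB store passes the structural leakage audit and recount", {
  fx <- small_binary_store(store_predictions = TRUE)
  store <- fx$store
  expect_true(audit_oob(store))

  # per-patient counts re-derived from the plans match the store exactly
  expected <- integer(nrow(store$count))
  for (i in seq_len(nrow(store$plans))) {
    oob <- store$plans$oob[[i]]
    expected[oob] <- expected[oob] + 1L
  }
  expect_identical(as.integer(store$count[, "ridge"]), expected)
  expect_identical(as.integer(store$count[, "mlp"]), expected)

  # grand replay from the raw per-plan prediction log equals the averages
  feats <- average_oob(store)
  replay <- store$raw_predictions |>
    dplyr::group_by(learner, index) |>
    dplyr::summarise(avg = mean(pred), .groups = "drop")
  for (l in c("ridge", "mlp")) {
    sub <- replay[replay$learner == l, ]
    sub <- sub[match(feats$row, sub$index), ]
    expect_equal(feats[[paste0("pred_", l)]], sub$avg, tolerance = 1e-12)
  }
})

test_that("averaging is the arithmetic mean of out-of-sample contributions", {
  fake <- structure(list(
    sum = cbind(ridge = c(0.6, 0.2, 0), mlp = c(1.0, 0.4, 0)),
    count = cbind(ridge = c(2L, 1L, 0L), mlp = c(2L, 1L, 0L)),
    patient_id = c("a", "b", "c")
  ), class = "oob_store")
  expect_warning(f <- average_oob(fake), "never out-of-sample")
  expect_equal(f$pred_ridge, c(0.3, 0.2))
  expect_equal(f$pred_mlp, c(0.5, 0.4))
  expect_equal(f$patient_id, c("a", "b"))

  none <- structure(list(sum = cbind(ridge = 0), count = cbind(ridge = 0L),
                         patient_id = "a"), class = "oob_store")
  expect_error(average_oob(none), class = "metastackr_empty_meta_features")
})

test_that("linear meta-learner recovers a perfect base-learner", {
  withr::with_seed(1, {
    y <- rnorm(200)
    f <- tibble::tibble(pred_ridge = y, pred_mlp = rnorm(200))
  })
  fit <- fit_meta_linear(f, y, "continuous")
  expect_lt(mae(y, predict(fit, f)), 1e-10)
  expect_equal(unname(fit$theta["pred_ridge"]), 1, tolerance = 1e-8)
  expect_equal(unname(fit$theta["pred_mlp"]), 0, tolerance = 1e-8)
})

test_that("collinear meta features collapse to a univariate fit with a warning", {
  withr::with_seed(2, {
    a <- rnorm(100)
    y <- 2 * a + rnorm(100, 0, 0.3)
  })
  f <- tibble::tibble(pred_ridge = a, pred_mlp = a)
  expect_warning(fit <- fit_meta_linear(f, y, "continuous"), "ollinear")
  uni <- lm(y ~ a)
  expect_equal(unname(predict(fit, f)), unname(fitted(uni)), tolerance = 1e-8)
})

test_that("logistic meta-learner is calibrated-in-the-large by construction", {
  withr::with_seed(3, {
    n <- 500
    f <- tibble::tibble(pred_ridge = runif(n), pred_mlp = runif(n))
    y <- rbinom(n, 1, plogis(2 * f$pred_ridge - 1))
  })
  fit <- fit_meta_linear(f, y, "binary")
  expect_lt(abs(mean(predict(fit, f)) - mean(y)), 1e-6)
})

test_that("perceptron meta-learner captures a nonlinear combiner", {
  withr::with_seed(4, {
    n <- 5000
    f <- tibble::tibble(pred_ridge = runif(n, 0, 10),
                        pred_mlp = runif(n, 0, 10))
    y <- pmax(f$pred_ridge, f$pred_mlp) + rnorm(n, 0, 0.1)
  })
  lin <- fit_meta_linear(f, y, "continuous")
  mlp <- fit_meta_mlp(f, y, "continuous",
                      control = tiny_mlp(hidden = c(16, 16), epochs = 60),
                      seed = 1)
  expect_lt(mae(y, predict(mlp, f)), mae(y, predict(lin, f)))
  # determinism of the meta perceptron
  mlp2 <- fit_meta_mlp(f, y, "continuous",
                       control = tiny_mlp(hidden = c(16, 16), epochs = 60),
                       seed = 1)
  expect_identical(predict(mlp, f), predict(mlp2, f))
})

test_that("covariate augmentation appends columns without changing contracts", {
  fx <- small_binary_store()
  feats <- average_oob(fx$store)
  expect_identical(augment_with_covariates(feats, fx$stack$datasets[[1]],
                                           character(), fx$store),
                   feats)
  all31 <- default_schema()$name
  aug <- augment_with_covariates(feats, fx$stack$datasets[[1]], all31,
                                 fx$store)
  drop_cols <- c("patient_id", "row", "never_oob")
  expect_equal(length(setdiff(names(aug), drop_cols)), 33)  # 2 preds + 31
  expect_error(augment_with_covariates(feats, fx$stack$datasets[[1]],
                                       "no_such_cov", fx$store),
               class = "metastackr_invalid_argument")
  # appending a covariate identical to an existing feature column warns
  d2 <- fx$stack$datasets[[1]]
  d2$age[fx$store$eligible[feats$row]] <- feats$pred_ridge
  expect_warning(augment_with_covariates(feats, d2, "age", fx$store),
                 "collinear")
})

test_that("meta-training rows restrict to outcome-observed patients", {
  fx <- small_binary_store()
  feats <- average_oob(fx$store)
  elig <- outcome_availability_mask(fx$stack$datasets[[1]], "binary")
  expect_true(all(fx$store$eligible %in% elig))
  expect_equal(nrow(feats) + sum(rowSums(fx$store$count == 0) > 0),
               length(elig))
})
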