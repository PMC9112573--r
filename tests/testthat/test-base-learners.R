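test_that("zero penalty reproduces ordinary least squares exactly", {
  d <- toy_linear_data(120, seed = 1)
  fit <- fit_ridge(d, "y", toy_schema(), "continuous", lambda = 0, seed = 1)
  ref <- lm(y ~ x1 + x2 + b1, data = d)
  expect_equal(unname(fit$intercept), unname(coef(ref)[1]), tolerance = 1e-8)
  expect_equal(unname(fit$coefficients[c("x1", "x2", "b1")]),
               unname(coef(ref)[c("x1", "x2", "b1")]), tolerance = 1e-8)
})

test_that("zero penalty reproduces the logistic MLE", {
  d <- toy_linear_data(400, seed = 2, binary = TRUE)
  fit <- fit_ridge(d, "y", toy_schema(), "binary", lambda = 0, seed = 1)
  ref <- glm(y ~ x1 + x2 + b1, data = d, family = binomial())
  expect_equal(unname(c(fit$intercept, fit$coefficients[c("x1", "x2", "b1")])),
               unname(coef(ref)), tolerance = 1e-6)
})

test_that("infinite-penalty limit shrinks to the training mean / event rate", {
  d <- toy_linear_data(150, seed = 3)
  fit <- fit_ridge(d, "y", toy_schema(), "continuous", lambda = 1e12, seed = 1)
  expect_lt(max(abs(fit$coefficients)), 1e-6)
  expect_equal(unique(round(predict(fit, d), 8)), round(mean(d$y), 8))

  db <- toy_linear_data(300, seed = 4, binary = TRUE)
  fitb <- fit_ridge(db, "y", toy_schema(), "binary", lambda = 1e12, seed = 1)
  expect_equal(mean(predict(fitb, db)), mean(db$y), tolerance = 1e-4)
  expect_lt(diff(range(predict(fitb, db))), 1e-4)
})

test_that("ridge agrees with an independent penalized-regression implementation", {
  skip_if_not_installed("glmnet")
  d <- toy_linear_data(200, seed = 5)
  lam <- 3
  X <- as.matrix(d[c("x1", "x2", "b1")])
  # glmnet rescales the gaussian response internally, so its lambda_g maps to
  # a raw L2 penalty of n * lambda_g / sd_pop(y)
  sd_pop <- sqrt(mean((d$y - mean(d$y))^2))
  fit <- fit_ridge(d, "y", toy_schema(), "continuous", lambda = lam / sd_pop,
                   seed = 1)
  g <- glmnet::glmnet(X, d$y, alpha = 0, lambda = lam / nrow(d),
                      standardize = FALSE, intercept = TRUE, thresh = 1e-16,
                      maxit = 1e7)
  expect_equal(unname(fit$coefficients),
               unname(as.numeric(coef(g))[-1]), tolerance = 1e-6)
  expect_equal(unname(fit$intercept), unname(as.numeric(coef(g))[1]),
               tolerance = 1e-6)
})

test_that("training loss is non-decreasing in the penalty", {
  d <- toy_linear_data(100, seed = 6)
  lams <- 10^seq(-3, 4, length.out = 10)
  losses <- sapply(lams, function(l) {
    f <- fit_ridge(d, "y", toy_schema(), "continuous", lambda = l, seed = 1)
    mean((d$y - predict(f, d))^2)
  })
  expect_true(all(diff(losses) >= -1e-10))
})

test_that("ridge prediction equals hand-recomputed matrix arithmetic", {
  d <- toy_linear_data(80, seed = 7)
  fit <- fit_ridge(d, "y", toy_schema(), "continuous", lambda = 2, seed = 1)
  newd <- d[1:5, ]
  X <- cbind(newd$x1, newd$x2, as.numeric(newd$b1))
  by_hand <- drop(X %*% unname(fit$coefficients[c("x1", "x2", "b1")])) +
    fit$intercept
  expect_equal(unname(predict(fit, newd)), by_hand, tolerance = 1e-12)
})

test_that("spline terms capture a cubic bend that a linear design misses", {
  withr::with_seed(8, {
    n <- 2000
    d <- tibble::tibble(
      x1 = runif(n, 0, 10), x2 = rnorm(n), b1 = rbinom(n, 1, 0.5)
    )
    d$y <- 2 * pmax(d$x1 - 6, 0)^2 + 0.3 * d$x2 + rnorm(n, 0, 0.5)
  })
  train <- d[1:1500, ]
  test <- d[1501:2000, ]
  sch_lin <- toy_schema()
  sch_spl <- toy_schema()
  sch_spl$spline[1] <- TRUE
  f_lin <- fit_ridge(train, "y", sch_lin, "continuous", seed = 1)
  f_spl <- fit_ridge(train, "y", sch_spl, "continuous", seed = 1)
  expect_lt(mae(test$y, predict(f_spl, test)),
            mae(test$y, predict(f_lin, test)))
})

test_that("perceptron reports its architecture and trains deterministically", {
  d <- toy_linear_data(60, seed = 9)
  fit <- fit_mlp(d, "y", toy_schema(), "continuous",
                 control = mlp_control(epochs = 2, batch_size = 32), seed = 3)
  arch <- tidy(fit)
  expect_equal(arch$units, c(256, 256, 256, 1))
  expect_equal(glance(fit)$hidden, "256x256x256")

  small <- tiny_mlp(epochs = 10)
  f1 <- fit_mlp(d, "y", toy_schema(), "continuous", control = small, seed = 5)
  f2 <- fit_mlp(d, "y", toy_schema(), "continuous", control = small, seed = 5)
  expect_identical(predict(f1, d), predict(f2, d))
  f3 <- fit_mlp(d, "y", toy_schema(), "continuous", control = small, seed = 6)
  expect_false(identical(predict(f1, d), predict(f3, d)))
})

test_that("perceptron learns an XOR interaction that the linear family cannot", {
  withr::with_seed(10, {
    n <- 4000
    d <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n),
                        a = rbinom(n, 1, 0.5), b = rbinom(n, 1, 0.5))
    d$y <- as.integer(xor(d$a == 1, d$b == 1))
    d$y <- ifelse(runif(n) < 0.05, 1L - d$y, d$y)  # 5% label noise
  })
  schema <- tibble::tibble(name = c("x1", "x2", "a", "b"),
                           kind = c("continuous", "continuous", "binary",
                                    "binary"),
                           levels = vector("list", 4), spline = rep(FALSE, 4))
  train <- d[1:3000, ]
  test <- d[3001:4000, ]
  f_mlp <- fit_mlp(train, "y", schema, "binary",
                   control = tiny_mlp(hidden = c(16, 16), epochs = 40),
                   seed = 2)
  f_rdg <- fit_ridge(train, "y", schema, "binary", seed = 2)
  auc_mlp <- auc(test$y, predict(f_mlp, test))
  auc_rdg <- auc(test$y, predict(f_rdg, test))
  expect_gt(auc_mlp, 0.85)
  expect_lt(auc_rdg, 0.6)
})

test_that("binary predictions are probabilities and preprocessing never leaks", {
  d <- toy_linear_data(300, seed = 11, binary = TRUE)
  fit <- fit_ridge(d, "y", toy_schema(), "binary", lambda = 0.5,
                   preprocess = "standardize", seed = 1)
  p <- predict(fit, d)
  expect_true(all(p >= 0 & p <= 1))

  # frozen preprocessing: parameters derive from training rows only, so
  # altering "test" data leaves the fitted state bit-identical
  train <- d[1:200, ]
  f1 <- fit_ridge(train, "y", toy_schema(), "binary", lambda = 0.5,
                  preprocess = "standardize", seed = 1)
  expect_identical(f1$preprocess$center,
                   colMeans(metastackr:::build_design(f1$design, train)))
  d_perturbed <- d
  d_perturbed[201:300, c("x1", "x2")] <- 999
  f2 <- fit_ridge(d_perturbed[1:200, ], "y", toy_schema(), "binary",
                  lambda = 0.5, preprocess = "standardize", seed = 1)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(f1$preprocess, f2$preprocess)
})

test_that("degenerate fits raise typed errors", {
  d <- toy_linear_data(50, seed = 12)
  d$y <- 1
  expect_error(fit_ridge(d, "y", toy_schema(), "continuous"),
               class = "metastackr_degenerate_fit")
  expect_error(fit_ridge(d[0, ], "y", toy_schema(), "continuous"),
               class = "metastackr_invalid_argument")
})

test_that("preprocessing sensitivity harness reports comparable errors", {
  coh <- complete_cohort(1200, seed = 14)$cohort
  out <- preprocess_sensitivity(coh, seed = 2)
  expect_equal(out$preprocess, c("none", "standardize", "normalize"))
  expect_true(all(is.finite(out$mae)))
  # the three modes should give very similar errors on near-linear data
  expect_lt(max(out$mae) / min(out$mae), 1.25)
})
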