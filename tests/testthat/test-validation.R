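test_that("base-learner reports aggregate the per-plan metric log", {
  fx <- small_binary_store(n = 300, m = 2, B = 3)
  rep <- evaluate_base_learners(fx$store)
  expect_s3_class(rep, "metric_report")
  expect_true(all(rep$n_replicates == 6))
  expect_setequal(unique(rep$model), c("base_ridge", "base_mlp"))

  # replay: report equals grouped means of the raw log to 1e-12
  log <- fx$store$plan_log
  for (i in seq_len(nrow(rep))) {
    lrn <- sub("^base_", "", rep$model[i])
    vals <- log$value[log$learner == lrn & log$metric == rep$metric[i]]
    expect_equal(rep$estimate[i], mean(vals), tolerance = 1e-12)
    ci <- percentile_ci(vals)
    expect_equal(rep$ci_low[i], ci[["low"]], tolerance = 1e-12)
    expect_equal(rep$ci_high[i], ci[["high"]], tolerance = 1e-12)
  }
})

test_that("constant per-plan values give a degenerate point and interval", {
  fake <- structure(list(
    task = "continuous",
    plan_log = tibble::tibble(metric = "MAE", value = rep(4.2, 8),
                              learner = "ridge", imputation = 1,
                              replicate = 1:8, n_oob = 10)
  ), class = "oob_store")
  rep <- evaluate_base_learners(fake)
  expect_equal(rep$estimate, 4.2)
  expect_equal(rep$ci_low, 4.2)
  expect_equal(rep$ci_high, 4.2)

  fake$plan_log <- NULL
  expect_error(evaluate_base_learners(fake),
               class = "metastackr_protocol_error")
})

test_that("meta-learner bootstrap produces reports for both models", {
  withr::with_seed(5, {
    n <- 300
    f <- tibble::tibble(pred_ridge = runif(n), pred_mlp = runif(n))
    y <- rbinom(n, 1, plogis(3 * f$pred_ridge - 1.5))
  })
  rep <- evaluate_meta_learners(f, y, "binary", R = 25,
                                mlp_control = tiny_mlp(epochs = 5), seed = 2)
  expect_setequal(unique(rep$model), c("meta_linear", "meta_mlp"))
  expect_true(all(c("AUC", "calib_in_large") %in% rep$metric))
  expect_true(all(rep$ci_low <= rep$ci_high))
  expect_error(evaluate_meta_learners(f, y, "binary", R = 1),
               class = "metastackr_invalid_argument")
})

test_that("degenerate constant meta features give chance-level AUC", {
  withr::with_seed(6, y <- rbinom(200, 1, 0.4))
  f <- tibble::tibble(pred_ridge = rep(0.4, 200), pred_mlp = rep(0.4, 200))
  rep <- suppressWarnings(
    evaluate_meta_learners(f, y, "binary", R = 20,
                           mlp_control = tiny_mlp(epochs = 3), seed = 3))
  a <- rep$estimate[rep$model == "meta_linear" & rep$metric == "AUC"]
  expect_lt(abs(a - 0.5), 0.05)
})

make_iecv_cohort <- function(n = 900, seed = 19, regions = 4) {
  sim <- simulate_cohort(generator_config(n = n, seed = seed,
                                          cont_subset_fraction = 1))
  keep <- sim$cohort$region %in% region_levels()[seq_len(regions)]
  sim$cohort[keep, , drop = FALSE]
}

test_that("internal-external validation scores every model in every region", {
  coh <- make_iecv_cohort()
  rep <- suppressWarnings(internal_external_cv(
    coh, "binary", m = 2, B = 2, mlp_control = tiny_mlp(epochs = 5),
    ridge_lambda = 1, seed = 4, imputation_cycles = 2))
  regions <- sort(unique(coh$region))
  models <- c("base_ridge", "base_mlp", "meta_linear", "meta_mlp")
  aucs <- rep[rep$metric == "AUC", ]
  expect_equal(nrow(aucs), (length(regions) + 1) * length(models))
  for (m in models) {
    per_region <- aucs$value[aucs$model == m & aucs$region != "(average)"]
    avg <- aucs$value[aucs$model == m & aucs$region == "(average)"]
    expect_equal(avg, mean(per_region), tolerance = 1e-12)
  }
})

test_that("fold state is invariant to arbitrary held-out-region perturbation", {
  coh <- make_iecv_cohort(n = 700, seed = 23, regions = 3)
  target <- sort(unique(coh$region))[1]
  run_fold <- function(data) {
    suppressWarnings(internal_external_cv(
      data, "binary", m = 2, B = 2, mlp_control = tiny_mlp(epochs = 4),
      ridge_lambda = 1, seed = 8, imputation_cycles = 2,
      return_fold_state = TRUE))
  }
  r1 <- run_fold(coh)
  perturbed <- coh
  rows <- perturbed$region == target
  withr::with_seed(99, {
    perturbed$age[rows] <- runif(sum(rows), 18, 90)
    perturbed$base_severity[rows] <- sample(0:27, sum(rows), replace = TRUE)
    perturbed$y_bin[rows] <- rbinom(sum(rows), 1, 0.5)
    perturbed$smoker[rows] <- rbinom(sum(rows), 1, 0.9)
  })
  r2 <- run_fold(perturbed)
  # every frozen quantity of the target fold is bit-identical
  expect_identical(r1$fold_state[[target]], r2$fold_state[[target]])
  # but the held-out metrics do respond to the data change
  a1 <- r1$report[r1$report$region == target & r1$report$metric == "AUC", ]
  a2 <- r2$report[r2$report$region == target & r2$report$metric == "AUC", ]
  expect_false(isTRUE(all.equal(a1$value, a2$value)))
})

test_that("regions lacking an outcome class are skipped with a warning", {
  coh <- make_iecv_cohort(n = 400, seed = 29, regions = 3)
  bad <- sort(unique(coh$region))[2]
  coh$y_bin[coh$region == bad] <- 1L
  expect_warning(
    rep <- internal_external_cv(coh, "binary", m = 1, B = 2,
                                mlp_control = tiny_mlp(epochs = 3),
                                ridge_lambda = 1, seed = 5,
                                imputation_cycles = 1),
    "lacks both outcome classes")
  expect_false(bad %in% rep$region)
})
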