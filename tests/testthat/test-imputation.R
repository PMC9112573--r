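test_that("complete data yields value-identical copies (no-op)", {
  coh <- complete_cohort(150, seed = 4)$cohort
  st <- impute_cohort(coh, m = 3, seed = 1)
  expect_equal(st$m, 3)
  expect_length(st$datasets, 3)
  for (d in st$datasets) expect_identical(d, coh)
})

test_that("m = 10 on a masked cohort returns exactly 10 completed datasets", {
  sim <- simulate_cohort(generator_config(n = 250, seed = 6))
  st <- impute_cohort(sim$cohort, m = 10, seed = 2, cycles = 2)
  expect_length(st$datasets, 10)
  preds <- default_schema()$name
  for (d in st$datasets) {
    expect_false(anyNA(d[preds]))
    expect_identical(d$patient_id, sim$cohort$patient_id)
  }
})

test_that("observed cells are preserved exactly; imputed cells vary across copies", {
  sim <- simulate_cohort(generator_config(n = 400, seed = 8))
  st <- impute_cohort(sim$cohort, m = 4, seed = 3, cycles = 2)
  obs <- !is.na(sim$cohort$base_severity)
  for (d in st$datasets) {
    expect_identical(d$base_severity[obs], sim$cohort$base_severity[obs])
  }
  # >= 20% missingness => the m imputed vectors are stochastic, not identical
  imp_mat <- sapply(st$datasets, function(d) d$base_severity[!obs])
  expect_gt(sum(apply(imp_mat, 1, function(r) length(unique(r)) > 1)), 0)
  expect_false(identical(imp_mat[, 1], imp_mat[, 2]))
})

test_that("imputed outcomes are never exposed downstream", {
  sim <- simulate_cohort(generator_config(n = 300, seed = 12))
  st <- impute_cohort(sim$cohort, m = 2, seed = 1, cycles = 2)
  for (d in st$datasets) {
    expect_identical(is.na(d$y_cont), is.na(sim$cohort$y_cont))
  }
})

test_that("degenerate inputs raise typed errors", {
  coh <- complete_cohort(50, seed = 2)$cohort
  coh$bmi[] <- NA
  expect_error(impute_cohort(coh, m = 2),
               class = "metastackr_unimputable_column")
  expect_error(impute_cohort(complete_cohort(50)$cohort, m = 0),
               class = "metastackr_invalid_argument")
})

test_that("outcome availability mask restricts to observed outcomes", {
  coh <- complete_cohort(100, seed = 3)$cohort
  expect_identical(outcome_availability_mask(coh, "binary"), 1:100)
  expect_identical(outcome_availability_mask(coh, "continuous"), 1:100)

  coh2 <- coh
  coh2$y_cont[seq(1, 100, by = 2)] <- NA
  expect_identical(outcome_availability_mask(coh2, "continuous"),
                   as.integer(seq(2, 100, by = 2)))
  expect_identical(outcome_availability_mask(coh2, "binary"), 1:100)
  expect_error(outcome_availability_mask(coh, "hazard"),
               class = "metastackr_invalid_argument")

  # severity-subcohort fraction matches the configured rate at scale
  sim <- simulate_cohort(generator_config(n = 5000, seed = 13))
  frac <- length(outcome_availability_mask(sim$cohort, "continuous")) / 5000
  expect_lt(abs(frac - 16384 / 187757), 0.02)
})

test_that("imputation recovers the distribution of masked severity values", {
  cfg <- generator_config(n = 4000, seed = 31, cont_subset_fraction = 1)
  out <- generate_cohort(cfg)
  masked <- apply_missingness(out$cohort, cfg)
  st <- impute_cohort(masked, m = 5, seed = 7, cycles = 3)
  mis <- is.na(masked$base_severity)
  truth <- out$cohort$base_severity[mis]
  imp_mean <- rowMeans(sapply(st$datasets,
                              function(d) d$base_severity[mis]))
  # unbiased against the oracle values of the masked cells
  expect_lt(abs(mean(imp_mean) - mean(truth)), 0.5)
  # derived oracle bound: the best any imputer could do is the conditional
  # mean given the observed columns; require the stochastic PMM average to
  # attain a substantial fraction of that correlation
  obs <- !mis
  oracle_fit <- lm(base_severity ~ y_cont + y_bin + age + bmi + anxiety +
                     sleep_disorder + self_harm_hist,
                   data = out$cohort[obs, ])
  oracle_cor <- cor(predict(oracle_fit, out$cohort[mis, ]), truth)
  expect_gt(cor(imp_mean, truth), 0.5 * oracle_cor)
})

test_that("across-imputation spread shrinks as missingness vanishes", {
  coef_spread <- function(rate, seed) {
    cfg <- generator_config(n = 1500, seed = seed,
                            missing_rates = c(base_severity = rate),
                            cont_subset_fraction = 1)
    sim <- simulate_cohort(cfg)
    st <- impute_cohort(sim$cohort, m = 5, seed = 11, cycles = 2)
    betas <- sapply(st$datasets, function(d) {
      coef(lm(d$y_cont ~ d$base_severity))[2]
    })
    sd(betas)
  }
  hi <- coef_spread(0.7, 41)
  lo <- coef_spread(0.1, 41)
  expect_gt(hi, 0)
  expect_gt(hi, lo)
})

test_that("frozen imputer completes new data from training models only", {
  sim <- simulate_cohort(generator_config(n = 600, seed = 17))
  train <- sim$cohort[1:450, ]
  test <- sim$cohort[451:600, ]
  st <- impute_cohort(train, m = 2, seed = 5, cycles = 2,
                      return_models = TRUE)
  expect_s3_class(st$imputer, "metastack_imputer")
  done <- apply_imputer(st$imputer, test, seed = 9)
  expect_false(anyNA(done[default_schema()$name]))
  obs <- !is.na(test$base_severity)
  expect_identical(done$base_severity[obs], test$base_severity[obs])
  # deterministic given the seed
  expect_identical(done, apply_imputer(st$imputer, test, seed = 9))
})
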