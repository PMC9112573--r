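#' Summarize base-learner performance over the bootstrap plans
#'
#' Point estimate = mean of the per-plan out-of-sample metric values (one per
#' bootstrap replicate per imputed dataset, m x B in total); uncertainty =
#' percentile interval of the same values.
#'
#' @param store An `oob_store` from [generate_oob_predictions()].
#' @return Tibble (`metric_report`): `model`, `task`, `metric`, `estimate`,
#'   `ci_low`, `ci_high`, `n_replicates`.
#' @export
evaluate_base_learners <- function(store) {
  stopifnot(inherits(store, "oob_store"))
  if (is.null(store$plan_log) || !nrow(store$plan_log)) {
    abort("The store carries no per-plan metric log.",
          class = "metastackr_protocol_error")
  }
  rep <- store$plan_log |>
    filter(.data$metric %in% c("MAE", "AUC", "calib_in_large")) |>
    group_by(.data$learner, .data$metric) |>
    summarise(
      estimate = mean(.data$value, na.rm = TRUE),
      ci_low = percentile_ci(.data$value)[["low"]],
      ci_high = percentile_ci(.data$value)[["high"]],
      n_replicates = dplyr::n(),
      .groups = "drop"
    ) |>
    mutate(model = paste0("base_", .data$learner), task = store$task) |>
    select("model", "task", "metric", "estimate", "ci_low", "ci_high",
           "n_replicates")
  class(rep) <- c("metric_report", class(rep))
  rep
}

#' Bootstrap evaluation of the meta-learners
#'
#' Resamples the meta-feature rows with replacement `R` times; on each
#' resample both meta-learners are refit and scored on the resample's
#' out-of-sample complement. Point estimate = mean over the R replicate
#' values, uncertainty = percentile interval.
#'
#' @param features Meta-features from [average_oob()] (optionally augmented).
#' @param y Outcome aligned with `features` rows.
#' @param task `"continuous"` or `"binary"`.
#' @param R Bootstrap replicates (default 200).
#' @param mlp_control Control for the perceptron meta-learner.
#' @param seed Integer seed.
#' @param schema Schema for augmented covariates.
#' @return A `metric_report` tibble covering `meta_linear` and `meta_mlp`.
#' @export
evaluate_meta_learners <- function(features, y, task, R = 200L,
                                   mlp_control = metastackr::mlp_control(),
                                   seed = 1L, schema = default_schema()) {
  task <- check_task(task)
  R <- check_count(R, "R", min = 2L)
  n <- nrow(features)
  logs <- vector("list", 2L * R)
  li <- 0L
  for (r in seq_len(R)) {
    ins <- with_stream(seed, sprintf("meta_boot_%d", r),
                       sample.int(n, n, replace = TRUE))
    oob <- which(!seq_len(n) %in% ins)
    if (!length(oob)) next
    ftr <- features[ins, , drop = FALSE]
    ytr <- y[ins]
    if (length(unique(ytr)) < 2L) next
    fte <- features[oob, , drop = FALSE]
    yte <- y[oob]
    fits <- list(
      meta_linear = suppressWarnings(
        fit_meta_linear(ftr, ytr, task, schema)),
      meta_mlp = fit_meta_mlp(ftr, ytr, task, control = mlp_control,
                              seed = seed_stream(seed, sprintf("meta_mlp_%d", r)),
                              schema = schema)
    )
    for (nm in names(fits)) {
      li <- li + 1L
      logs[[li]] <- task_metrics(task, yte, predict(fits[[nm]], fte)) |>
        mutate(model = nm, replicate = r)
    }
  }
  rep <- dplyr::bind_rows(logs[seq_len(li)]) |>
    filter(.data$metric %in% c("MAE", "AUC", "calib_in_large")) |>
    group_by(.data$model, .data$metric) |>
    summarise(
      estimate = mean(.data$value, na.rm = TRUE),
      ci_low = percentile_ci(.data$value)[["low"]],
      ci_high = percentile_ci(.data$value)[["high"]],
      n_replicates = dplyr::n(),
      .groups = "drop"
    ) |>
    mutate(task = task) |>
    select("model", "task", "metric", "estimate", "ci_low", "ci_high",
           "n_replicates")
  class(rep) <- c("metric_report", class(rep))
  rep
}

# Fit both base-learners once per imputed dataset on the full (training)
# data; prediction on new data is the average over the m per-imputation fits.
fit_full_base_learners <- function(stack, task, schema, preprocess,
                                   mlp_control, ridge_lambda, seed) {
  ocol <- outcome_col(task)
  eligible <- outcome_availability_mask(stack$datasets[[1L]], task)
  lapply(seq_len(stack$m), function(j) {
    data_j <- stack$datasets[[j]][eligible, , drop = FALSE]
    list(
      ridge = fit_ridge(data_j, ocol, schema, task, preprocess = preprocess,
                        lambda = ridge_lambda,
                        seed = seed_stream(seed, sprintf("full_ridge_%d", j))),
      mlp = fit_mlp(data_j, ocol, schema, task, control = mlp_control,
                    seed = seed_stream(seed, sprintf("full_mlp_%d", j)))
    )
  })
}

predict_full_base <- function(full_fits, newdata) {
  preds <- lapply(c(ridge = "ridge", mlp = "mlp"), function(l) {
    rowMeans(vapply(full_fits, function(f) predict(f[[l]], newdata),
                    numeric(nrow(newdata))))
  })
  tibble(pred_ridge = preds$ridge, pred_mlp = preds$mlp)
}

#' Internal-external cross-validation by region
#'
#' Leave-one-region-out validation of the whole pipeline: for each region,
#' imputation models, spline knots, preprocessing parameters, base-learners
#' and meta-learners are all developed on the remaining regions only; the
#' held-out region's missing predictors are completed with a single seeded
#' draw from the frozen training imputer, and all four models are scored on
#' the held-out patients with an observed outcome. Test-side base-learner
#' predictions average one full-data fit per imputed training dataset and
#' also serve as the meta-learners' inputs.
#'
#' @param cohort Cohort tibble with a `region` column.
#' @param task `"continuous"` or `"binary"`.
#' @param m,B Imputations and bootstrap replicates per training fold.
#' @param schema Predictor schema.
#' @param preprocess Ridge preprocessing mode.
#' @param mlp_control Control for both perceptron learners.
#' @param ridge_lambda Optional fixed ridge penalty.
#' @param seed Integer master seed (fanned out per region).
#' @param imputation_cycles Chained-equation cycles per training fold.
#' @param return_fold_state Also return each fold's frozen training state
#'   (knots, imputer coefficients, learner parameters) for leakage audits.
#' @return A `region_report` tibble: per-region metric rows for all four
#'   models plus `"(average)"` rows (unweighted mean across regions). With
#'   `return_fold_state = TRUE`, a list with `report` and `fold_state`.
#' @export
internal_external_cv <- function(cohort, task, m = 10L, B = 20L,
                                 schema = default_schema(),
                                 preprocess = "none",
                                 mlp_control = metastackr::mlp_control(),
                                 ridge_lambda = NULL, seed = 1L,
                                 imputation_cycles = 5L,
                                 return_fold_state = FALSE) {
  task <- check_task(task)
  ocol <- outcome_col(task)
  regions <- sort(unique(cohort$region))
  if (length(regions) < 2L) {
    abort("Internal-external validation needs at least 2 regions.",
          class = "metastackr_invalid_argument")
  }
  rows <- list()
  fold_state <- list()
  for (r in regions) {
    test_raw <- cohort[cohort$region == r, , drop = FALSE]
    y_test <- test_raw[[ocol]]
    keep <- !is.na(y_test)
    if (!any(keep) ||
        (task == "binary" && length(unique(y_test[keep])) < 2L)) {
      warn(sprintf("Region %s lacks both outcome classes; skipped.", r))
      next
    }
    fold_seed <- seed_stream(seed, paste0("iecv_", r))
    train <- cohort[cohort$region != r, , drop = FALSE]

    stack <- impute_cohort(train, m = m, seed = fold_seed, schema = schema,
                           cycles = imputation_cycles, return_models = TRUE)
    n_elig <- length(outcome_availability_mask(stack$datasets[[1L]], task))
    plans <- make_bootstrap_plans(n_elig, m, B, seed = fold_seed)
    store <- generate_oob_predictions(
      stack, plans, task, schema, preprocess = preprocess,
      mlp_control = mlp_control, ridge_lambda = ridge_lambda,
      keep_models = 0L, seed = fold_seed)
    features <- average_oob(store)
    elig_rows <- store$eligible[features$row]
    y_meta <- as.numeric(stack$datasets[[1L]][[ocol]][elig_rows])
    meta_lin <- suppressWarnings(
      fit_meta_linear(features, y_meta, task, schema))
    meta_mlp <- fit_meta_mlp(features, y_meta, task, control = mlp_control,
                             seed = seed_stream(fold_seed, "meta_mlp"),
                             schema = schema)
    full_fits <- fit_full_base_learners(stack, task, schema, preprocess,
                                        mlp_control, ridge_lambda, fold_seed)

    # test side: single seeded draw from the frozen training imputer
    test <- test_raw[keep, , drop = FALSE]
    if (!is.null(stack$imputer)) {
      test <- apply_imputer(stack$imputer, test,
                            seed = seed_stream(fold_seed, "test_impute"))
    }
    yte <- as.numeric(test[[ocol]])
    base_pred <- predict_full_base(full_fits, test)
    preds <- list(
      base_ridge = base_pred$pred_ridge,
      base_mlp = base_pred$pred_mlp,
      meta_linear = predict(meta_lin, base_pred),
      meta_mlp = predict(meta_mlp, base_pred)
    )
    for (nm in names(preds)) {
      rows[[length(rows) + 1L]] <-
        task_metrics(task, yte, preds[[nm]]) |>
        mutate(model = nm, region = r, n_test = length(yte))
    }
    if (return_fold_state) {
      fold_state[[r]] <- list(
        knots = lapply(full_fits[[1L]]$ridge$design$specs,
                       function(s) s$spec$knots),
        ridge_theta = lapply(full_fits, function(f)
          c(f$ridge$intercept, f$ridge$coefficients)),
        mlp_par = lapply(full_fits, function(f) f$mlp$net$par),
        imputer_coefs = lapply(
          if (is.null(stack$imputer)) list() else stack$imputer$models,
          function(mo) mo$coef %||% stats::coef(mo$fit)),
        meta_theta = meta_lin$theta,
        meta_mlp_par = meta_mlp$net$par
      )
    }
  }
  report <- dplyr::bind_rows(rows) |>
    filter(.data$metric %in% c("MAE", "AUC", "calib_in_large")) |>
    select("region", "model", "metric", "value", "n_test")
  avg <- report |>
    group_by(.data$model, .data$metric) |>
    summarise(value = mean(.data$value, na.rm = TRUE),
              n_test = sum(.data$n_test), .groups = "drop") |>
    mutate(region = "(average)") |>
    select("region", "model", "metric", "value", "n_test")
  out <- dplyr::bind_rows(report, avg) |> mutate(task = task)
  class(out) <- c("region_report", class(out))
  if (return_fold_state) list(report = out, fold_state = fold_state) else out
}
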