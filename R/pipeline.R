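#' Write a cohort to CSV with a JSON sidecar schema
#'
#' Comma-separated, UTF-8, header row, empty cells for missing values. The
#' sidecar records each predictor's kind/levels and names the outcome and
#' region columns, so the file round-trips through [read_cohort()] including
#' its missingness pattern.
#'
#' @param cohort Cohort tibble.
#' @param csv_path Output CSV path.
#' @param schema_path Output JSON path (default: `csv_path` with `.json`).
#' @param schema Predictor schema.
#' @return Invisibly, `csv_path`.
#' @export
write_cohort <- function(cohort, csv_path,
                         schema_path = sub("\\.csv$", ".json", csv_path),
                         schema = default_schema()) {
  utils::write.csv(cohort, csv_path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  sidecar <- list(
    predictors = lapply(seq_len(nrow(schema)), function(i) {
      list(name = schema$name[i], kind = schema$kind[i],
           levels = schema$levels[[i]], spline = schema$spline[i])
    }),
    id_column = "patient_id", region_column = "region",
    outcome_continuous = "y_cont", outcome_binary = "y_bin",
    region_levels = region_levels(), y_cont_range = c(0, 27)
  )
  jsonlite::write_json(sidecar, schema_path, auto_unbox = TRUE, null = "null")
  invisible(csv_path)
}

#' Read a cohort CSV validated against its sidecar schema
#'
#' @param csv_path Cohort CSV (empty cells = missing).
#' @param schema_path Sidecar JSON written by [write_cohort()].
#' @return A validated cohort tibble; the reconstructed schema is attached as
#'   attribute `"schema"`.
#' @export
read_cohort <- function(csv_path, schema_path) {
  if (!file.exists(csv_path) || !file.exists(schema_path)) {
    abort("Cohort CSV or schema JSON not found.",
          class = "metastackr_invalid_argument")
  }
  sc <- jsonlite::read_json(schema_path, simplifyVector = FALSE)
  raw <- utils::read.csv(csv_path, stringsAsFactors = FALSE, na.strings = "",
                         fileEncoding = "UTF-8")
  preds <- sc$predictors
  schema <- tibble(
    name = vapply(preds, `[[`, character(1), "name"),
    kind = vapply(preds, `[[`, character(1), "kind"),
    levels = lapply(preds, function(p) {
      l <- p$levels
      if (is.null(l) || (is.atomic(l) && !length(l))) NULL else unlist(l)
    }),
    spline = vapply(preds, function(p) isTRUE(p$spline), logical(1))
  )
  validate_schema(schema)
  sc$id_column <- unlist(sc$id_column)
  sc$region_column <- unlist(sc$region_column)
  sc$outcome_continuous <- unlist(sc$outcome_continuous)
  sc$outcome_binary <- unlist(sc$outcome_binary)
  needed <- c(sc$id_column, sc$region_column, schema$name,
              sc$outcome_continuous, sc$outcome_binary)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "metastackr_parse_error")
  }
  out <- as_tibble(raw[needed])
  names(out)[1:2] <- c("patient_id", "region")
  out$patient_id <- as.character(out$patient_id)
  if (anyDuplicated(out$patient_id)) {
    dup <- which(duplicated(out$patient_id))[1L]
    abort(sprintf("Duplicate patient_id at row %d.", dup),
          class = "metastackr_parse_error")
  }
  ycol <- sc$outcome_continuous
  rng <- unlist(sc$y_cont_range) %||% c(0, 27)
  yc <- out[[ycol]]
  bad <- which(!is.na(yc) & (yc < rng[1] | yc > rng[2] | yc != floor(yc)))
  if (length(bad)) {
    abort(sprintf("Continuous outcome out of range [%g, %g] at row %d.",
                  rng[1], rng[2], bad[1L]),
          class = "metastackr_parse_error")
  }
  bad_reg <- which(is.na(out$region))
  if (length(bad_reg)) {
    abort(sprintf("Missing region label at row %d.", bad_reg[1L]),
          class = "metastackr_parse_error")
  }
  yb <- out[[sc$outcome_binary]]
  bad_b <- which(!is.na(yb) & !yb %in% c(0, 1))
  if (length(bad_b)) {
    abort(sprintf("Binary outcome not 0/1 at row %d.", bad_b[1L]),
          class = "metastackr_parse_error")
  }
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    if (schema$kind[i] %in% c("categorical")) {
      lev <- schema$levels[[i]]
      bad_l <- which(!is.na(out[[nm]]) & !out[[nm]] %in% lev)
      if (length(bad_l)) {
        abort(sprintf("Unknown level `%s` in `%s` at row %d.",
                      out[[nm]][bad_l[1L]], nm, bad_l[1L]),
              class = "metastackr_parse_error")
      }
    }
  }
  names(out)[names(out) == ycol] <- "y_cont"
  names(out)[names(out) == sc$outcome_binary] <- "y_bin"
  out$y_cont <- as.integer(out$y_cont)
  out$y_bin <- as.integer(out$y_bin)
  attr(out, "schema") <- schema
  out
}

#' Pipeline run configuration
#'
#' Bundles every pipeline constant. The defaults instantiate the reference
#' protocol exactly: m = 10 imputations, B = 20 bootstrap replicates (200
#' base fits), 4-knot splines, perceptrons with three hidden layers of 256
#' units, meta-learners on the 2 averaged prediction columns, R = 200
#' meta-bootstrap replicates, importance over 10 models x 100 shuffles.
#'
#' @param m Imputed datasets.
#' @param B Bootstrap replicates per imputed dataset.
#' @param R Meta-learner bootstrap replicates.
#' @param knots Spline knots per continuous predictor.
#' @param mlp_base,mlp_meta [mlp_control()] for base and meta perceptrons.
#' @param n_importance_models Trained models sampled per learner for
#'   permutation importance.
#' @param n_shuffles Permutations per (model, feature).
#' @param preprocess Ridge preprocessing mode.
#' @param tasks Outcomes to run (`"continuous"`, `"binary"` or both).
#' @param ridge_lambda Optional fixed ridge penalty (NULL = internal CV).
#' @param imputation_cycles Chained-equation cycles.
#' @param run_importance Whether the pipeline runs the importance protocol.
#' @param importance_features Predictors assessed by base-learner importance
#'   (default: all 31).
#' @param augment_covariates Optional covariates appended to the meta inputs.
#' @param seed Master seed fanned out to named per-stage streams.
#' @return An object of class `run_config`.
#' @export
run_config <- function(m = 10L, B = 20L, R = 200L, knots = 4L,
                       mlp_base = mlp_control(), mlp_meta = mlp_control(),
                       n_importance_models = 10L, n_shuffles = 100L,
                       preprocess = "none",
                       tasks = c("continuous", "binary"),
                       ridge_lambda = NULL, imputation_cycles = 5L,
                       run_importance = TRUE, importance_features = NULL,
                       augment_covariates = character(), seed = 1L) {
  tasks <- match.arg(tasks, c("continuous", "binary"), several.ok = TRUE)
  structure(list(
    m = check_count(m, "m", 1L), B = check_count(B, "B", 1L),
    R = check_count(R, "R", 2L), knots = check_count(knots, "knots", 3L),
    mlp_base = mlp_base, mlp_meta = mlp_meta,
    n_importance_models = check_count(n_importance_models,
                                      "n_importance_models", 1L),
    n_shuffles = check_count(n_shuffles, "n_shuffles", 1L),
    preprocess = preprocess, tasks = tasks, ridge_lambda = ridge_lambda,
    imputation_cycles = check_count(imputation_cycles, "imputation_cycles", 1L),
    run_importance = isTRUE(run_importance),
    importance_features = importance_features,
    augment_covariates = augment_covariates,
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Run the full stacking pipeline on a cohort
#'
#' Imputation, bootstrap out-of-sample prediction generation, per-patient
#' averaging, meta-learner fitting, bootstrap evaluation of all four models,
#' and (optionally) the permutation-importance protocol, for each requested
#' task. Every stage draws from a named stream of the master seed, and the
#' returned manifest records all constants and seeds, so a rerun with the
#' same cohort and config reproduces every number exactly.
#'
#' @param cohort Cohort tibble (from [simulate_cohort()] or [read_cohort()]).
#' @param config A [run_config()].
#' @param schema Predictor schema.
#' @return A `metastack_run` list: `manifest`, per-task `reports`
#'   (`metric_report` rows for base and meta learners), `meta_features`,
#'   `meta_models`, `importance` (base and meta records), `calibration`.
#' @export
run_pipeline <- function(cohort, config = run_config(),
                         schema = default_schema()) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  stack <- impute_cohort(cohort, m = config$m,
                         seed = seed_stream(seed, "imputation"),
                         schema = schema, cycles = config$imputation_cycles)
  results <- list()
  for (task in config$tasks) {
    ocol <- outcome_col(task)
    eligible <- outcome_availability_mask(stack$datasets[[1L]], task)
    plans <- make_bootstrap_plans(length(eligible), config$m, config$B,
                                  seed = seed_stream(seed, paste0("plans_", task)))
    store <- generate_oob_predictions(
      stack, plans, task, schema,
      preprocess = config$preprocess, mlp_control = config$mlp_base,
      ridge_lambda = config$ridge_lambda,
      keep_models = if (config$run_importance) config$n_importance_models else 0L,
      seed = seed_stream(seed, paste0("oob_", task)))
    features <- average_oob(store)
    if (length(config$augment_covariates)) {
      features <- augment_with_covariates(features, stack$datasets[[1L]],
                                          config$augment_covariates, store)
    }
    y <- as.numeric(stack$datasets[[1L]][[ocol]][store$eligible[features$row]])
    meta_models <- list(
      meta_linear = suppressWarnings(fit_meta_linear(features, y, task, schema)),
      meta_mlp = fit_meta_mlp(features, y, task, control = config$mlp_meta,
                              seed = seed_stream(seed, paste0("meta_mlp_", task)),
                              schema = schema)
    )
    base_report <- evaluate_base_learners(store)
    meta_report <- evaluate_meta_learners(
      features, y, task, R = config$R, mlp_control = config$mlp_meta,
      seed = seed_stream(seed, paste0("meta_eval_", task)), schema = schema)
    calib <- if (task == "binary") {
      dplyr::bind_rows(lapply(names(meta_models), function(nm) {
        p <- pmin(pmax(predict(meta_models[[nm]], features), 0), 1)
        calibration_in_the_large(y, p) |> mutate(model = nm)
      }))
    } else {
      NULL
    }
    importance <- NULL
    if (config$run_importance) {
      metric <- if (task == "continuous") "MAE" else "AUC"
      base_imp <- permutation_importance(
        store, stack, features = config$importance_features, metric = metric,
        n_models = config$n_importance_models,
        n_shuffles = config$n_shuffles, schema = schema,
        seed = seed_stream(seed, paste0("importance_", task)))
      meta_imp <- meta_importance(
        meta_models, features, y, metric = metric,
        n_shuffles = config$n_shuffles,
        seed = seed_stream(seed, paste0("meta_importance_", task)))
      importance <- list(base = base_imp, meta = meta_imp)
    }
    results[[task]] <- list(
      store = store, features = features, y = y, meta_models = meta_models,
      report = dplyr::bind_rows(base_report, meta_report),
      calibration = calib, importance = importance,
      n_eligible = length(eligible), n_plans = nrow(plans))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("metastackr")),
    seed = seed, n = nrow(cohort),
    m = config$m, B = config$B, total_base_fits = config$m * config$B,
    R = config$R, knots = config$knots,
    mlp_base_hidden = config$mlp_base$hidden,
    mlp_meta_hidden = config$mlp_meta$hidden,
    n_spline_predictors = sum(schema$spline),
    n_predictors = nrow(schema),
    n_meta_prediction_columns = 2L,
    n_importance_models = config$n_importance_models,
    n_shuffles = config$n_shuffles,
    n_regions = length(unique(cohort$region)),
    preprocess = config$preprocess, tasks = config$tasks,
    imputation_cycles = config$imputation_cycles,
    n_eligible = vapply(results, `[[`, integer(1), "n_eligible")
  )
  structure(list(manifest = manifest, tasks = results, config = config,
                 stack = stack),
            class = "metastack_run")
}

#' @export
print.metastack_run <- function(x, ...) {
  cat("<metastack_run>\n")
  cat(sprintf("  n = %d patients, m = %d imputations, B = %d bootstraps (%d base fits)\n",
              x$manifest$n, x$manifest$m, x$manifest$B,
              x$manifest$total_base_fits))
  for (task in names(x$tasks)) {
    cat(sprintf("  task %s (%d outcome-observed patients):\n", task,
                x$tasks[[task]]$n_eligible))
    rep <- x$tasks[[task]]$report
    key <- if (task == "continuous") "MAE" else "AUC"
    sub <- rep[rep$metric == key, ]
    for (i in seq_len(nrow(sub))) {
      cat(sprintf("    %-12s %s = %.3f [%.3f, %.3f]\n", sub$model[i], key,
                  sub$estimate[i], sub$ci_low[i], sub$ci_high[i]))
    }
  }
  invisible(x)
}

#' Sensitivity of the ridge pipeline to design preprocessing
#'
#' Runs the continuous-outcome ridge base-learner under the three
#' preprocessing modes (none, standardization, min-max normalization) on a
#' common train/test split and reports the test MAEs side by side.
#'
#' @param data Complete-cohort tibble (post-imputation) with `y_cont`.
#' @param schema Predictor schema.
#' @param test_fraction Held-out fraction.
#' @param seed Integer seed.
#' @return Tibble with `preprocess` and `mae` columns.
#' @export
preprocess_sensitivity <- function(data, schema = default_schema(),
                                   test_fraction = 0.3, seed = 1L) {
  data <- data[!is.na(data$y_cont), , drop = FALSE]
  n <- nrow(data)
  test <- with_stream(seed, "preprocess_split",
                      sample.int(n, floor(test_fraction * n)))
  train_d <- data[-test, , drop = FALSE]
  test_d <- data[test, , drop = FALSE]
  purrr::map_dfr(c("none", "standardize", "normalize"), function(mode) {
    fit <- fit_ridge(train_d, "y_cont", schema, "continuous",
                     preprocess = mode,
                     seed = seed_stream(seed, paste0("pp_", mode)))
    tibble(preprocess = mode,
           mae = mae(as.numeric(test_d$y_cont), predict(fit, test_d)))
  })
}
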