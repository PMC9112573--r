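# Predict straight from a raw (untransformed-by-preprocess) design matrix.
predict_design <- function(model, X) {
  Xp <- apply_preprocess(model$preprocess, X)
  if (inherits(model, "mlp_learner")) {
    out <- drop(mlp_forward(model$net$par, Xp)[[length(model$net$par$W) + 1L]])
  } else {
    out <- drop(Xp %*% model$coefficients) + model$intercept
  }
  if (model$task == "binary") stats::plogis(out) else out
}

# Design-matrix columns contributed by one schema predictor.
feature_columns <- function(dspec, nm) {
  s <- dspec$specs[[nm]]
  if (is.null(s)) return(character())
  switch(s$type,
         rcs = paste0(nm, "_rcs", seq_len(length(s$spec$knots) - 1L)),
         onehot = paste0(nm, "_", s$keep),
         nm)
}

#' Permutation feature importance for base-learners
#'
#' For each retained fitted model (by default 10 per learner, sampled from the
#' trained bootstrap replicates) and each feature, the feature's column in the
#' model's own out-of-sample data is randomly shuffled `n_shuffles` times
#' (default 100) with all other columns fixed; the model is rescored after
#' each shuffle and the percent change versus the unshuffled score is
#' recorded. For MAE the change is `100 * (MAE_shuf - MAE_orig) / MAE_orig`,
#' for AUC `100 * (AUC_orig - AUC_shuf) / AUC_orig`, so larger values always
#' mean a more important feature. Percent changes are averaged over shuffles
#' within a model, then across models.
#'
#' @param store An `oob_store` produced with `keep_models > 0`.
#' @param stack The [impute_cohort()] stack the store was built from.
#' @param features Predictor names to assess (default: all schema predictors).
#' @param metric `"MAE"` or `"AUC"` (must match the store's task).
#' @param n_models Number of retained models to use per learner.
#' @param n_shuffles Shuffles per (model, feature).
#' @param schema Predictor schema.
#' @param seed Integer seed (one stream per model x feature).
#' @return Tibble (`importance_record`): `model`, `feature`, `metric`,
#'   `pct_change`, `n_models`, `n_shuffles`; per-model values in attribute
#'   `"per_model"`.
#' @export
permutation_importance <- function(store, stack,
                                   features = NULL,
                                   metric = c("MAE", "AUC"),
                                   n_models = 10L, n_shuffles = 100L,
                                   schema = default_schema(), seed = 1L) {
  stopifnot(inherits(store, "oob_store"), inherits(stack, "imputation_stack"))
  metric <- match.arg(metric)
  if ((metric == "MAE") != (store$task == "continuous")) {
    abort("Metric does not match the store's task.",
          class = "metastackr_invalid_argument")
  }
  features <- features %||% schema$name
  unknown <- setdiff(features, schema$name)
  if (length(unknown)) {
    abort(paste0("Unknown feature(s): ", paste(unknown, collapse = ", ")),
          class = "metastackr_invalid_argument")
  }
  if (!length(store$kept)) {
    abort("The store retained no fitted models (keep_models = 0).",
          class = "metastackr_protocol_error")
  }
  ocol <- outcome_col(store$task)
  score <- function(y, pred) {
    if (metric == "MAE") mae(y, pred) else auc(y, pred)
  }
  kept_by_learner <- split(store$kept,
                           vapply(store$kept, `[[`, character(1), "learner"))
  recs <- list()
  per_model <- list()
  for (l in names(kept_by_learner)) {
    models <- kept_by_learner[[l]]
    models <- models[seq_len(min(n_models, length(models)))]
    pm <- matrix(NA_real_, nrow = length(models), ncol = length(features),
                 dimnames = list(NULL, features))
    for (mi in seq_along(models)) {
      k <- models[[mi]]
      eval_data <- stack$datasets[[k$imputation]][store$eligible, ,
                                                  drop = FALSE][k$oob, ,
                                                                drop = FALSE]
      y <- as.numeric(eval_data[[ocol]])
      # one frozen design per model: all transforms are row-wise, so
      # permuting a raw feature equals permuting its design-block rows
      X <- build_design(k$model$design, eval_data)
      base_score <- score(y, predict_design(k$model, X))
      for (f in features) {
        cols <- intersect(feature_columns(k$model$design, f), colnames(X))
        deltas <- with_stream(
          seed, sprintf("perm_%s_%d_%s", l, mi, f), {
            vapply(seq_len(n_shuffles), function(s) {
              Xs <- X
              Xs[, cols] <- X[sample.int(nrow(X)), cols]
              sc <- score(y, predict_design(k$model, Xs))
              if (metric == "MAE") {
                100 * (sc - base_score) / base_score
              } else {
                100 * (base_score - sc) / base_score
              }
            }, numeric(1))
          })
        pm[mi, f] <- mean(deltas)
      }
    }
    per_model[[l]] <- pm
    recs[[l]] <- tibble(model = paste0("base_", l), feature = features,
                        metric = metric, pct_change = colMeans(pm),
                        n_models = length(models), n_shuffles = n_shuffles)
  }
  out <- dplyr::bind_rows(recs)
  attr(out, "per_model") <- per_model
  class(out) <- c("importance_record", class(out))
  out
}

#' Permutation importance of the base-learner predictions in a meta-learner
#'
#' The same shuffling protocol applied to the meta-learner input columns
#' (the averaged ridge and MLP predictions), quantifying how much each
#' base-learner contributes to the stacked model. The ratio of the two
#' importances is attached as attribute `"ratio"` per model.
#'
#' @param meta_models Named list of fitted meta-learners.
#' @param features Meta-features tibble the models were trained on (or an
#'   evaluation subset).
#' @param y Outcome aligned with `features`.
#' @param metric `"MAE"` or `"AUC"`.
#' @param n_shuffles Shuffles per (model, column).
#' @param seed Integer seed.
#' @return An `importance_record` tibble over the prediction columns.
#' @export
meta_importance <- function(meta_models, features, y,
                            metric = c("MAE", "AUC"),
                            n_shuffles = 100L, seed = 1L) {
  metric <- match.arg(metric)
  pred_cols <- grep("^pred_", names(features), value = TRUE)
  if (length(pred_cols) < 2L) {
    abort("Meta features must carry at least 2 prediction columns.",
          class = "metastackr_invalid_argument")
  }
  score <- function(y, pred) {
    if (metric == "MAE") mae(y, pred) else auc(y, pred)
  }
  recs <- list()
  ratios <- list()
  for (nm in names(meta_models)) {
    model <- meta_models[[nm]]
    base_score <- score(y, predict(model, features))
    vals <- vapply(pred_cols, function(f) {
      deltas <- with_stream(seed, sprintf("meta_perm_%s_%s", nm, f), {
        vapply(seq_len(n_shuffles), function(s) {
          shuffled <- features
          shuffled[[f]] <- shuffled[[f]][sample.int(nrow(shuffled))]
          sc <- score(y, predict(model, shuffled))
          if (metric == "MAE") {
            100 * (sc - base_score) / base_score
          } else {
            100 * (base_score - sc) / base_score
          }
        }, numeric(1))
      })
      mean(deltas)
    }, numeric(1))
    recs[[nm]] <- tibble(model = nm, feature = pred_cols, metric = metric,
                         pct_change = unname(vals), n_models = 1L,
                         n_shuffles = n_shuffles)
    ratios[[nm]] <- vals[1L] / vals[2L]
  }
  out <- dplyr::bind_rows(recs)
  attr(out, "ratio") <- ratios
  class(out) <- c("importance_record", class(out))
  out
}
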