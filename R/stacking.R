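#' Bootstrap resampling plans across imputed datasets
#'
#' For every (imputed dataset, bootstrap replicate) pair, draws a
#' with-replacement sample of size `n` (the bootstrap training multiset) and
#' records its out-of-sample complement: the indices never drawn. Defaults of
#' m = 10 imputations and B = 20 replicates give the 200 planned fits of the
#' evaluation protocol.
#'
#' @param n Number of eligible patients (indices are 1..n).
#' @param m Number of imputed datasets.
#' @param B Bootstrap replicates per imputed dataset.
#' @param seed Integer seed; each plan draws from its own named stream.
#' @return Tibble with columns `imputation`, `replicate`, `in_sample`
#'   (list of length-n index vectors) and `oob` (list of complement indices).
#' @export
#' @examples
#' plans <- make_bootstrap_plans(100, m = 2, B = 3, seed = 1)
#' nrow(plans)  # 6
make_bootstrap_plans <- function(n, m, B, seed = 1L) {
  n <- check_count(n, "n", min = 1L)
  m <- check_count(m, "m", min = 1L)
  B <- check_count(B, "B", min = 1L)
  grid <- tidyr::expand_grid(imputation = seq_len(m), replicate = seq_len(B))
  grid |>
    mutate(
      in_sample = purrr::map2(.data$imputation, .data$replicate, function(j, b) {
        with_stream(seed, sprintf("plan_%d_%d", j, b),
                    sample.int(n, n, replace = TRUE))
      }),
      oob = purrr::map(.data$in_sample, function(s) {
        which(!seq_len(n) %in% s)
      })
    )
}

task_metrics <- function(task, y, pred) {
  if (task == "continuous") {
    tibble(metric = "MAE", value = mae(y, pred))
  } else {
    cal <- calibration_in_the_large(y, pmin(pmax(pred, 0), 1))
    dplyr::bind_rows(
      tibble(metric = "AUC",
             value = tryCatch(auc(y, pred), error = function(e) NA_real_)),
      tibble(metric = "calib_in_large", value = cal$difference),
      tibble(metric = "mean_pred", value = cal$mean_pred)
    )
  }
}

#' Generate out-of-sample base-learner predictions over all bootstrap plans
#'
#' For each plan, fits every base-learner on the in-sample rows of the plan's
#' imputed dataset and predicts on the plan's out-of-sample rows only.
#' Predictions are accumulated as per-patient running sums and counts; no
#' prediction is ever stored for a patient contained in the model's own
#' bootstrap training multiset (attempting to would be a hard structural
#' error). Per-plan out-of-sample metrics are logged for the base-learner
#' evaluation, and a seeded subset of fitted models is retained for the
#' permutation-importance protocol.
#'
#' @param stack An [impute_cohort()] result.
#' @param plans Plans from [make_bootstrap_plans()] whose indices refer to the
#'   outcome-observed rows of the stack (in order).
#' @param task `"continuous"` or `"binary"`.
#' @param schema Predictor schema.
#' @param learners Character subset of `c("ridge", "mlp")`.
#' @param preprocess Preprocessing mode for the ridge learner.
#' @param mlp_control An [mlp_control()] for the MLP learner.
#' @param ridge_lambda Optional fixed ridge penalty (skips internal CV).
#' @param keep_models Number of fitted models per learner retained (with
#'   their out-of-sample data references) for importance analysis.
#' @param store_predictions Keep every per-plan out-of-sample prediction
#'   vector (for brute-force replay audits of the averaging).
#' @param seed Integer seed.
#' @return An `oob_store`: list with `sum` and `count` matrices
#'   (patients x learners), `plan_log` (per-plan metric tibble), `kept`
#'   (retained models), `eligible` row indices into the cohort, `patient_id`,
#'   `plans`, `task`.
#' @export
generate_oob_predictions <- function(stack, plans, task,
                                     schema = default_schema(),
                                     learners = c("ridge", "mlp"),
                                     preprocess = "none",
                                     mlp_control = metastackr::mlp_control(),
                                     ridge_lambda = NULL,
                                     keep_models = 10L,
                                     store_predictions = FALSE, seed = 1L) {
  stopifnot(inherits(stack, "imputation_stack"))
  task <- check_task(task)
  learners <- match.arg(learners, c("ridge", "mlp"), several.ok = TRUE)
  ocol <- outcome_col(task)
  eligible <- outcome_availability_mask(stack$datasets[[1L]], task)
  n_elig <- length(eligible)
  if (n_elig == 0L) {
    abort("No patients with an observed outcome.",
          class = "metastackr_invalid_argument")
  }
  if (max(unlist(plans$in_sample)) > n_elig) {
    abort("Plan indices exceed the outcome-observed row set.",
          class = "metastackr_invalid_argument")
  }
  if (max(plans$imputation) > stack$m) {
    abort("Plans reference more imputations than the stack holds.",
          class = "metastackr_invalid_argument")
  }

  pred_sum <- matrix(0, n_elig, length(learners),
                     dimnames = list(NULL, learners))
  pred_count <- matrix(0L, n_elig, length(learners),
                       dimnames = list(NULL, learners))
  logs <- vector("list", nrow(plans) * length(learners))
  keep_idx <- lapply(learners, function(l) {
    with_stream(seed, paste0("keep_models_", l),
                sample.int(nrow(plans), min(keep_models, nrow(plans))))
  })
  names(keep_idx) <- learners
  kept <- list()
  raw_preds <- if (store_predictions) list() else NULL

  li <- 0L
  for (i in seq_len(nrow(plans))) {
    j <- plans$imputation[i]
    data_j <- stack$datasets[[j]][eligible, , drop = FALSE]
    ins <- plans$in_sample[[i]]
    oob <- plans$oob[[i]]
    train <- data_j[ins, , drop = FALSE]
    test <- data_j[oob, , drop = FALSE]
    for (l in learners) {
      fit_seed <- seed_stream(seed, sprintf("fit_%s_%d", l, i))
      model <- if (l == "ridge") {
        fit_ridge(train, ocol, schema, task, preprocess = preprocess,
                  lambda = ridge_lambda, seed = fit_seed)
      } else {
        fit_mlp(train, ocol, schema, task, control = mlp_control,
                seed = fit_seed)
      }
      if (length(oob)) {
        # structural leakage guard: only complement indices are scored
        if (length(intersect(oob, unique(ins)))) {
          abort("Internal error: out-of-sample set overlaps the bootstrap sample.",
                class = "metastackr_leakage_error")
        }
        pred <- predict(model, test)
        pred_sum[oob, l] <- pred_sum[oob, l] + pred
        pred_count[oob, l] <- pred_count[oob, l] + 1L
        if (store_predictions) {
          raw_preds[[length(raw_preds) + 1L]] <-
            tibble(plan_row = i, learner = l, index = oob, pred = pred)
        }
        li <- li + 1L
        logs[[li]] <- task_metrics(task, as.numeric(test[[ocol]]), pred) |>
          mutate(learner = l, imputation = j, replicate = plans$replicate[i],
                 n_oob = length(oob))
      }
      if (i %in% keep_idx[[l]]) {
        kept[[length(kept) + 1L]] <-
          list(learner = l, imputation = j, replicate = plans$replicate[i],
               plan_row = i, model = model, oob = oob)
      }
    }
  }

  structure(
    list(sum = pred_sum, count = pred_count,
         plan_log = dplyr::bind_rows(logs[seq_len(li)]),
         kept = kept, raw_predictions = if (store_predictions)
           dplyr::bind_rows(raw_preds) else NULL,
         eligible = eligible,
         patient_id = stack$datasets[[1L]]$patient_id[eligible],
         plans = plans, task = task, learners = learners, seed = seed),
    class = "oob_store"
  )
}

#' Audit the out-of-sample store against its plans
#'
#' Recomputes, from the stored plans alone, how many times each patient was
#' out-of-sample, and verifies the store's contribution counts match exactly
#' (and therefore that no in-sample contribution was ever accumulated).
#'
#' @param store An `oob_store`.
#' @return Invisibly `TRUE`; aborts on any mismatch.
#' @export
audit_oob <- function(store) {
  stopifnot(inherits(store, "oob_store"))
  expected <- integer(nrow(store$count))
  for (i in seq_len(nrow(store$plans))) {
    oob <- store$plans$oob[[i]]
    expected[oob] <- expected[oob] + 1L
    if (length(intersect(oob, unique(store$plans$in_sample[[i]])))) {
      abort("Leakage: a plan's out-of-sample set intersects its bootstrap sample.",
            class = "metastackr_leakage_error")
    }
  }
  for (l in colnames(store$count)) {
    if (!identical(as.integer(store$count[, l]), expected)) {
      abort("Contribution counts do not match the stored plans.",
            class = "metastackr_leakage_error")
    }
  }
  invisible(TRUE)
}

#' Average accumulated out-of-sample predictions into meta-learner features
#'
#' Pools across bootstrap replicates and imputed datasets: each patient's
#' feature is the arithmetic mean of all their out-of-sample predictions from
#' one base-learner, yielding exactly one row per outcome-observed patient.
#' Patients never out-of-sample (possible only at tiny n) are flagged and
#' excluded from meta-training with a warning.
#'
#' @param store An `oob_store`.
#' @return Tibble (`meta_features`): `patient_id`, `row` (index into the
#'   eligible set), one averaged prediction column per base-learner
#'   (`pred_ridge`, `pred_mlp`), and `never_oob`.
#' @export
average_oob <- function(store) {
  stopifnot(inherits(store, "oob_store"))
  never <- rowSums(store$count) == 0 |
    apply(store$count, 1L, function(r) any(r == 0L))
  if (all(never)) {
    abort("Every patient was in-sample in every plan: no meta features.",
          class = "metastackr_empty_meta_features")
  }
  if (any(never)) {
    warn(sprintf("%d patient(s) never out-of-sample; excluded from meta-training.",
                 sum(never)))
  }
  avg <- store$sum / pmax(store$count, 1L)
  out <- tibble(patient_id = store$patient_id,
                row = seq_along(store$patient_id))
  for (l in colnames(avg)) out[[paste0("pred_", l)]] <- avg[, l]
  out$never_oob <- never
  out[!never, , drop = FALSE]
}

#' Append patient-level covariates to the meta-learner features
#'
#' Implements the covariate-augmented variant in which the meta-learners see
#' the base-learner predictions plus (already imputed) patient covariates.
#'
#' @param features Meta-features from [average_oob()].
#' @param data Completed cohort tibble (same row universe the store's
#'   `eligible` indices refer to).
#' @param covariates Character vector of predictor names to append.
#' @param store The `oob_store` that produced `features` (supplies the
#'   eligible-row mapping). Omit when `data` rows already align with
#'   `features$row`.
#' @return `features` with the covariate columns appended.
#' @export
augment_with_covariates <- function(features, data, covariates,
                                    store = NULL) {
  if (!length(covariates)) return(features)
  unknown <- setdiff(covariates, names(data))
  if (length(unknown)) {
    abort(paste0("Unknown covariate(s): ", paste(unknown, collapse = ", ")),
          class = "metastackr_invalid_argument")
  }
  rows <- if (is.null(store)) features$row else store$eligible[features$row]
  block <- data[rows, covariates, drop = FALSE]
  if (anyNA(block)) {
    abort("Covariates must be imputed before augmentation.",
          class = "metastackr_invalid_argument")
  }
  existing <- intersect(covariates, names(features))
  dup <- covariates[vapply(covariates, function(v) {
    any(vapply(features[setdiff(names(features),
                                c("patient_id", "row", "never_oob"))],
               function(col) is.numeric(col) && is.numeric(block[[v]]) &&
                 isTRUE(all.equal(as.numeric(col), as.numeric(block[[v]]))),
               logical(1)))
  }, logical(1))]
  if (length(existing) || length(dup)) {
    warn("Appended covariate duplicates an existing feature column (collinear).")
  }
  dplyr::bind_cols(features, block)
}

# Unpenalized logistic IRLS whose Newton steps use the SVD pseudo-inverse, so
# directions outside the design's column space stay at zero.
irls_pinv_logistic <- function(Z, y, maxit = 50L, tol = 1e-10) {
  theta <- rep(0, ncol(Z))
  for (it in seq_len(maxit)) {
    eta <- drop(Z %*% theta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z_work <- eta + (y - mu) / w
    Zw <- Z * sqrt(w)
    sv <- svd(Zw)
    keep <- sv$d > max(sv$d) * 1e-10
    theta_new <- drop(sv$v[, keep, drop = FALSE] %*%
                        ((1 / sv$d[keep]) *
                           crossprod(sv$u[, keep, drop = FALSE],
                                     sqrt(w) * z_work)))
    if (max(abs(theta_new - theta)) < tol) return(theta_new)
    theta <- theta_new
  }
  theta
}

# Numeric meta design matrix from a meta-features tibble: prediction columns
# plus any augmented covariates (categoricals as drop-first indicators).
meta_design <- function(features, schema = default_schema()) {
  drop_cols <- c("patient_id", "row", "never_oob")
  cols <- setdiff(names(features), drop_cols)
  blocks <- lapply(cols, function(nm) {
    v <- features[[nm]]
    if (is.numeric(v)) {
      matrix(as.numeric(v), ncol = 1L, dimnames = list(NULL, nm))
    } else {
      lev <- if (nm %in% schema$name) {
        schema$levels[[match(nm, schema$name)]]
      } else {
        sort(unique(as.character(v)))
      }
      keep <- lev[-1L]
      b <- vapply(keep, function(l) as.numeric(v == l), numeric(length(v)))
      if (is.null(dim(b))) b <- matrix(b, nrow = length(v))
      colnames(b) <- paste0(nm, "_", keep)
      b
    }
  })
  do.call(cbind, blocks)
}

#' Fit the unregularized linear/logistic meta-learner
#'
#' Plain least squares (continuous task) or maximum-likelihood logistic
#' regression (binary task) on the averaged base-learner predictions (plus
#' any augmented covariates) with an intercept. No penalty is ever added: a
#' rank-deficient design (e.g. perfectly collinear prediction columns) falls
#' back to the minimum-norm pseudo-inverse solution with a warning.
#'
#' @param features Meta-features tibble from [average_oob()].
#' @param y Outcome values aligned with `features` rows.
#' @param task `"continuous"` or `"binary"`.
#' @param schema Schema used to encode augmented categorical covariates.
#' @return Fitted learner of class `meta_linear`/`metastack_learner`.
#' @export
fit_meta_linear <- function(features, y, task, schema = default_schema()) {
  task <- check_task(task)
  X <- meta_design(features, schema)
  if (nrow(X) < 3L) {
    abort("Need at least 3 rows to fit the meta-learner.",
          class = "metastackr_invalid_argument")
  }
  if (nrow(X) != length(y) || anyNA(y)) {
    abort("`y` must align with `features` and contain no missing values.",
          class = "metastackr_invalid_argument")
  }
  Z <- cbind(`(Intercept)` = 1, X)
  if (task == "continuous") {
    qz <- qr(Z)
    if (qz$rank < ncol(Z)) {
      warn("Collinear meta features; using the minimum-norm least-squares solution.")
      sv <- svd(Z)
      keep <- sv$d > max(sv$d) * 1e-10
      theta <- drop(sv$v[, keep, drop = FALSE] %*%
                      ((1 / sv$d[keep]) *
                         crossprod(sv$u[, keep, drop = FALSE], y)))
    } else {
      theta <- qr.coef(qz, y)
    }
  } else {
    if (!all(y %in% c(0, 1))) {
      abort("Binary task requires a 0/1 outcome.",
            class = "metastackr_invalid_argument")
    }
    if (qr(Z)$rank < ncol(Z)) {
      # rank-deficient likelihood: Newton steps through the pseudo-inverse
      # keep the null-space component at zero (minimum-norm ML solution);
      # no penalty is added
      warn("Collinear meta features; using the minimum-norm ML solution.")
      theta <- irls_pinv_logistic(Z, y)
    } else {
      fit <- suppressWarnings(
        stats::glm.fit(Z, y, family = stats::binomial())
      )
      if (!fit$converged || any(abs(fit$coefficients) > 1e3, na.rm = TRUE)) {
        warn("Logistic meta-learner may not have converged (possible separation).")
      }
      theta <- fit$coefficients
    }
  }
  names(theta) <- colnames(Z)
  structure(list(kind = "meta_linear", task = task, theta = theta,
                 feature_names = colnames(X), schema = schema),
            class = c("meta_linear", "metastack_learner"))
}

#' @export
predict.meta_linear <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else meta_design(newdata, object$schema)
  X <- X[, object$feature_names, drop = FALSE]
  eta <- drop(cbind(1, X) %*% object$theta)
  if (object$task == "binary") stats::plogis(eta) else eta
}

#' Fit the perceptron meta-learner
#'
#' The same multi-layer perceptron as the base-learner (default three hidden
#' layers of 256 units) trained on the averaged base-learner predictions.
#'
#' @inheritParams fit_meta_linear
#' @param control An [mlp_control()].
#' @param seed Training seed.
#' @return Fitted learner of class `meta_mlp`/`mlp_learner`.
#' @export
fit_meta_mlp <- function(features, y, task, control = mlp_control(),
                         seed = 1L, schema = default_schema()) {
  task <- check_task(task)
  X <- meta_design(features, schema)
  if (nrow(X) != length(y) || anyNA(y)) {
    abort("`y` must align with `features` and contain no missing values.",
          class = "metastackr_invalid_argument")
  }
  fit <- fit_mlp_matrix(X, as.numeric(y), task, control, seed)
  fit$kind <- "meta_mlp"
  fit$feature_names <- colnames(X)
  fit$schema <- schema
  class(fit) <- c("meta_mlp", class(fit))
  fit
}

#' @export
predict.meta_mlp <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else meta_design(newdata, object$schema)
  X <- X[, object$feature_names, drop = FALSE]
  predict.mlp_learner(object, X)
}
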