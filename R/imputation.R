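#' Indices of patients with an observed outcome
#'
#' All model development and evaluation for an outcome is restricted to
#' patients whose value of that outcome was actually observed; imputed
#' outcomes are never used for fitting or scoring.
#'
#' @param cohort Cohort tibble with `y_cont` and `y_bin` columns.
#' @param outcome `"continuous"` or `"binary"`.
#' @return Integer vector of row indices with an observed outcome.
#' @export
outcome_availability_mask <- function(cohort, outcome) {
  outcome <- check_task(outcome)
  col <- outcome_col(outcome)
  if (!col %in% names(cohort)) {
    abort(sprintf("Outcome column `%s` not found.", col),
          class = "metastackr_invalid_argument")
  }
  which(!is.na(cohort[[col]]))
}

# Model frame for one chained-equation conditional model: every predictor
# except `exclude`, spline-flagged continuous predictors through the 4-knot
# restricted cubic spline basis, categorical predictors as drop-first
# indicators, plus (optionally) the two outcome columns as linear terms.
impute_model_frame <- function(data, schema, exclude, knots_list,
                               include_outcomes = TRUE) {
  blocks <- list()
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    if (nm == exclude) next
    v <- data[[nm]]
    kind <- schema$kind[i]
    if (kind == "continuous") {
      if (isTRUE(schema$spline[i]) && !is.null(knots_list[[nm]])) {
        b <- rcs_basis(as.numeric(v), knots_list[[nm]])
        colnames(b) <- paste0(nm, "_rcs", seq_len(ncol(b)))
        blocks[[nm]] <- b
      } else {
        blocks[[nm]] <- matrix(as.numeric(v), ncol = 1L,
                               dimnames = list(NULL, nm))
      }
    } else if (kind == "binary") {
      blocks[[nm]] <- matrix(as.numeric(v), ncol = 1L,
                             dimnames = list(NULL, nm))
    } else {
      lev <- schema$levels[[i]]
      keep <- lev[-1L]
      b <- vapply(keep, function(l) as.numeric(v == l), numeric(nrow(data)))
      if (is.null(dim(b))) b <- matrix(b, nrow = nrow(data))
      colnames(b) <- paste0(nm, "_", keep)
      blocks[[nm]] <- b
    }
  }
  if (include_outcomes) {
    for (oc in c("y_cont", "y_bin")) {
      if (oc %in% names(data) && oc != exclude) {
        blocks[[oc]] <- matrix(as.numeric(data[[oc]]), ncol = 1L,
                               dimnames = list(NULL, oc))
      }
    }
  }
  do.call(cbind, blocks)
}

# Predictive-mean matching: for each target prediction, sample one donor's
# observed value among the `donors` observed cases with the closest predicted
# mean. Nearest donors found through a sorted-prediction window.
pmm_draw <- function(pred_obs, obs_values, pred_mis, donors = 5L) {
  donors <- min(donors, length(pred_obs))
  ord <- order(pred_obs)
  ps <- pred_obs[ord]
  vs <- obs_values[ord]
  n <- length(ps)
  pos <- findInterval(pred_mis, ps)
  vapply(seq_along(pred_mis), function(i) {
    lo <- max(1L, pos[i] - donors)
    hi <- min(n, pos[i] + donors)
    cand <- lo:hi
    d <- abs(ps[cand] - pred_mis[i])
    pick <- cand[order(d)[seq_len(donors)]]
    vs[pick[sample.int(length(pick), 1L)]]
  }, numeric(1))
}

# Draw an imputation for one chained variable given current completed data.
# When `frozen` is supplied the fitted coefficients and donor pools come from
# the frozen training imputer instead of being re-estimated.
impute_one <- function(data, schema, v, kind, levels_v, knots_list, obs_mask,
                       donors, include_outcomes = TRUE, frozen = NULL) {
  M <- impute_model_frame(data, schema, v, knots_list, include_outcomes)
  mis <- !obs_mask
  if (!any(mis)) return(list(values = data[[v]], model = NULL))
  if (kind == "continuous") {
    if (is.null(frozen)) {
      fit <- stats::lm.fit(cbind(1, M[obs_mask, , drop = FALSE]),
                           as.numeric(data[[v]][obs_mask]))
      cf <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
      pred_obs <- drop(cbind(1, M[obs_mask, , drop = FALSE]) %*% cf)
      pool_values <- as.numeric(data[[v]][obs_mask])
    } else {
      cf <- frozen$coef
      pred_obs <- frozen$pred_obs
      pool_values <- frozen$values
    }
    pred_mis <- drop(cbind(1, M[mis, , drop = FALSE]) %*% cf)
    draws <- pmm_draw(pred_obs, pool_values, pred_mis, donors)
    vals <- data[[v]]
    vals[mis] <- draws
    list(values = vals,
         model = list(type = "continuous", coef = cf, pred_obs = pred_obs,
                      values = pool_values))
  } else if (kind == "binary") {
    if (is.null(frozen)) {
      yv <- as.numeric(data[[v]][obs_mask])
      fit <- suppressWarnings(
        stats::glm.fit(cbind(1, M[obs_mask, , drop = FALSE]), yv,
                       family = stats::binomial())
      )
      cf <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
    } else {
      cf <- frozen$coef
    }
    p <- stats::plogis(drop(cbind(1, M[mis, , drop = FALSE]) %*% cf))
    vals <- data[[v]]
    vals[mis] <- stats::rbinom(sum(mis), 1L, p)
    list(values = vals, model = list(type = "binary", coef = cf))
  } else {
    if (is.null(frozen)) {
      df <- data.frame(.y = factor(data[[v]][obs_mask], levels = levels_v),
                       M[obs_mask, , drop = FALSE], check.names = FALSE)
      fit <- nnet::multinom(.y ~ ., data = df, trace = FALSE,
                            maxit = 200, MaxNWts = 5000)
      model <- list(type = "categorical", fit = fit, levels = levels_v)
    } else {
      fit <- frozen$fit
      model <- frozen
    }
    nd <- data.frame(M[mis, , drop = FALSE], check.names = FALSE)
    pr <- stats::predict(fit, newdata = nd, type = "probs")
    if (is.null(dim(pr))) pr <- cbind(1 - pr, pr)  # 2-level case
    if (ncol(pr) != length(levels_v)) {
      colnames(pr) <- fit$lev
      full <- matrix(0, nrow(pr), length(levels_v),
                     dimnames = list(NULL, levels_v))
      full[, colnames(pr)] <- pr
      pr <- full
    }
    draw <- apply(pr, 1L, function(p) sample(levels_v, 1L, prob = p))
    vals <- data[[v]]
    vals[mis] <- draw
    list(values = vals, model = model)
  }
}

#' Multiple imputation of missing predictors by chained additive regressions
#'
#' Each incomplete predictor is modelled on every other predictor and on both
#' outcome columns, with spline-flagged continuous predictors entering the
#' conditional models through the 4-knot restricted cubic spline basis.
#' Continuous variables are drawn by predictive-mean matching (donor pool of
#' 5), binary and categorical variables from their predicted class
#' probabilities. The continuous outcome participates in the chain so that it
#' can inform predictor imputation, but the returned datasets restore its
#' original missingness pattern: imputed outcomes are never exposed for model
#' development or evaluation.
#'
#' @param cohort Cohort tibble (predictors + `y_cont`, `y_bin`).
#' @param m Number of completed datasets (default 10).
#' @param seed Integer seed; copy `j` draws from stream `seed + j`.
#' @param schema Predictor schema.
#' @param cycles Chained-equation burn-in cycles per copy (default 5).
#' @param donors Predictive-mean-matching donor pool size (default 5).
#' @param return_models Also freeze per-variable imputation models (fit on the
#'   first completed copy, predictors only) for later single-draw imputation
#'   of new data via [apply_imputer()]. Used by the internal-external
#'   cross-validation, where held-out regions must be imputed from training
#'   models alone.
#' @return An `imputation_stack`: list with `datasets` (list of m completed
#'   tibbles sharing row order with `cohort`), `m`, `seed`, and optionally
#'   `imputer`.
#' @export
impute_cohort <- function(cohort, m = 10L, seed = 1L,
                          schema = default_schema(), cycles = 5L,
                          donors = 5L, return_models = FALSE) {
  m <- check_count(m, "m", min = 1L)
  cycles <- check_count(cycles, "cycles", min = 1L)
  validate_schema(schema)
  preds <- schema$name
  missing_cols <- setdiff(preds, names(cohort))
  if (length(missing_cols)) {
    abort(paste0("Predictors absent from cohort: ",
                 paste(missing_cols, collapse = ", ")),
          class = "metastackr_schema_error")
  }
  all_missing <- preds[vapply(cohort[preds],
                              function(x) all(is.na(x)), logical(1))]
  if (length(all_missing)) {
    abort(paste0("Column(s) entirely missing, cannot impute: ",
                 paste(all_missing, collapse = ", ")),
          class = "metastackr_unimputable_column")
  }

  incomplete <- preds[vapply(cohort[preds], anyNA, logical(1))]
  chain_vars <- incomplete
  if (length(incomplete) && anyNA(cohort$y_cont) && !all(is.na(cohort$y_cont))) {
    chain_vars <- c(chain_vars, "y_cont")
  }

  if (!length(incomplete)) {
    out <- structure(list(datasets = replicate(m, cohort, simplify = FALSE),
                          m = m, seed = as.integer(seed),
                          cycles = cycles, donors = donors),
                     class = "imputation_stack")
    if (return_models) out$imputer <- NULL
    return(out)
  }

  # ascending missingness order stabilizes the chain
  miss_n <- vapply(chain_vars, function(v) sum(is.na(cohort[[v]])), integer(1))
  chain_vars <- chain_vars[order(miss_n)]
  obs_masks <- lapply(chain_vars, function(v) !is.na(cohort[[v]]))
  names(obs_masks) <- chain_vars
  var_kind <- vapply(chain_vars, function(v) {
    if (v == "y_cont") "continuous" else schema$kind[match(v, schema$name)]
  }, character(1))
  var_levels <- lapply(chain_vars, function(v) {
    if (v %in% schema$name) schema$levels[[match(v, schema$name)]] else NULL
  })
  names(var_levels) <- chain_vars

  datasets <- vector("list", m)
  first_models <- NULL
  for (j in seq_len(m)) {
    datasets[[j]] <- withr::with_seed(
      (abs(as.integer(seed)) + j) %% 2147483629L, {
        cur <- cohort
        # initial fill: sample observed values of each incomplete variable
        for (v in chain_vars) {
          mis <- !obs_masks[[v]]
          cur[[v]][mis] <- sample(cur[[v]][obs_masks[[v]]], sum(mis),
                                  replace = TRUE)
        }
        # knots frozen per copy on the initially completed data
        knots_list <- list()
        for (i in which(schema$spline)) {
          nm <- schema$name[i]
          knots_list[[nm]] <- place_knots(as.numeric(cur[[nm]]), 4L)
        }
        models <- list()
        for (cy in seq_len(cycles)) {
          for (v in chain_vars) {
            res <- impute_one(cur, schema, v, var_kind[[v]], var_levels[[v]],
                              knots_list, obs_masks[[v]], donors)
            cur[[v]] <- res$values
            if (cy == cycles) models[[v]] <- res$model
          }
        }
        if (j == 1L) first_models <<- list(models = models,
                                           knots = knots_list)
        # imputed outcomes are never exposed downstream
        cur$y_cont[is.na(cohort$y_cont)] <- NA
        cur
      })
  }

  out <- structure(list(datasets = datasets, m = m, seed = as.integer(seed),
                        cycles = cycles, donors = donors,
                        chain_vars = chain_vars),
                   class = "imputation_stack")
  if (return_models) {
    out$imputer <- freeze_imputer(datasets[[1L]], cohort, schema, chain_vars,
                                  obs_masks, var_kind, var_levels,
                                  first_models$knots, donors)
  }
  out
}

# Frozen imputer for new data: per-variable models refit on the first
# completed training copy using PREDICTORS ONLY (outcomes are unavailable at
# prediction time), plus training marginals for initialization and PMM donor
# pools.
freeze_imputer <- function(completed, cohort, schema, chain_vars, obs_masks,
                           var_kind, var_levels, knots_list, donors) {
  chain_preds <- intersect(chain_vars, schema$name)
  models <- list()
  for (v in chain_preds) {
    M <- impute_model_frame(completed, schema, v, knots_list,
                            include_outcomes = FALSE)
    obs <- obs_masks[[v]]
    if (var_kind[[v]] == "continuous") {
      fit <- stats::lm.fit(cbind(1, M[obs, , drop = FALSE]),
                           as.numeric(completed[[v]][obs]))
      cf <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
      models[[v]] <- list(type = "continuous", coef = cf,
                          pred_obs = drop(cbind(1, M[obs, , drop = FALSE]) %*% cf),
                          values = as.numeric(completed[[v]][obs]))
    } else if (var_kind[[v]] == "binary") {
      fit <- suppressWarnings(
        stats::glm.fit(cbind(1, M[obs, , drop = FALSE]),
                       as.numeric(completed[[v]][obs]),
                       family = stats::binomial()))
      models[[v]] <- list(type = "binary",
                          coef = ifelse(is.na(fit$coefficients), 0,
                                        fit$coefficients))
    } else {
      df <- data.frame(.y = factor(completed[[v]][obs],
                                   levels = var_levels[[v]]),
                       M[obs, , drop = FALSE], check.names = FALSE)
      fit <- nnet::multinom(.y ~ ., data = df, trace = FALSE,
                            maxit = 200, MaxNWts = 5000)
      models[[v]] <- list(type = "categorical", fit = fit,
                          levels = var_levels[[v]])
    }
  }
  # marginals for every predictor: new data may carry missingness in columns
  # that happened to be complete in training
  marginals <- lapply(schema$name, function(v) {
    x <- cohort[[v]]
    x[!is.na(x)]
  })
  names(marginals) <- schema$name
  structure(list(models = models, knots = knots_list, schema = schema,
                 chain_vars = chain_preds, var_kind = var_kind,
                 var_levels = var_levels, marginals = marginals,
                 donors = donors),
            class = "metastack_imputer")
}

#' Impute new data from a frozen training imputer (single draw)
#'
#' Fills missing predictor cells of `newdata` using the conditional models
#' estimated on training data only (see `return_models` in
#' [impute_cohort()]). Outcome columns are neither used nor filled. One
#' stochastic completion is drawn.
#'
#' @param imputer A `metastack_imputer`.
#' @param newdata Tibble with the schema's predictor columns.
#' @param seed Seed of the draw.
#' @param cycles Number of refinement cycles (default 3).
#' @return `newdata` with missing predictor cells completed.
#' @export
apply_imputer <- function(imputer, newdata, seed = 1L, cycles = 3L) {
  stopifnot(inherits(imputer, "metastack_imputer"))
  schema <- imputer$schema
  withr::with_seed(seed_stream(seed, "apply_imputer"), {
    cur <- newdata
    masks <- list()
    for (v in names(imputer$marginals)) {
      mask_v <- !is.na(cur[[v]])
      if (v %in% imputer$chain_vars) masks[[v]] <- mask_v
      mis <- !mask_v
      if (any(mis)) {
        # chain variables get refined below; others keep the marginal draw
        cur[[v]][mis] <- sample(imputer$marginals[[v]], sum(mis),
                                replace = TRUE)
      }
    }
    for (cy in seq_len(cycles)) {
      for (v in imputer$chain_vars) {
        if (all(masks[[v]])) next
        res <- impute_one(cur, schema, v, imputer$var_kind[[v]],
                          imputer$var_levels[[v]], imputer$knots, masks[[v]],
                          imputer$donors, include_outcomes = FALSE,
                          frozen = imputer$models[[v]])
        cur[[v]] <- res$values
      }
    }
    cur
  })
}
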