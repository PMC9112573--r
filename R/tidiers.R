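#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted learner's coefficients
#'
#' For the linear-family learners (`ridge_learner`, `meta_linear`) returns one
#' row per design term; for perceptrons, one row per layer with its shape.
#'
#' @param x A fitted `metastack_learner`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy metastack_learner
#' @export
tidy.metastack_learner <- function(x, ...) {
  if (x$kind %in% c("ridge", "meta_linear")) {
    if (x$kind == "ridge") {
      tibble(term = c("(Intercept)", names(x$coefficients)),
             estimate = c(x$intercept, unname(x$coefficients)))
    } else {
      tibble(term = names(x$theta), estimate = unname(x$theta))
    }
  } else {
    par <- x$net$par
    tibble(term = paste0("layer_", seq_along(par$W)),
           inputs = vapply(par$W, nrow, integer(1)),
           units = vapply(par$W, ncol, integer(1)),
           n_weights = vapply(par$W, length, integer(1)))
  }
}

#' One-row fit summary of a fitted learner
#'
#' @inheritParams tidy.metastack_learner
#' @return A one-row tibble with learner kind, task, training size and the
#'   learner-specific complexity summary (penalty or architecture).
#' @method glance metastack_learner
#' @export
glance.metastack_learner <- function(x, ...) {
  tibble(
    kind = x$kind, task = x$task, n_train = x$n_train %||% NA_integer_,
    lambda = x$lambda %||% NA_real_,
    hidden = if (!is.null(x$hidden)) paste(x$hidden, collapse = "x")
             else NA_character_
  )
}

#' Tidy the metric reports of a pipeline run
#'
#' @param x A `metastack_run`.
#' @param ... Unused.
#' @return Tibble of per-model metric estimates with percentile intervals,
#'   across tasks.
#' @method tidy metastack_run
#' @export
tidy.metastack_run <- function(x, ...) {
  purrr::map_dfr(x$tasks, "report")
}

#' One-row summary of a pipeline run
#'
#' @inheritParams tidy.metastack_run
#' @return A one-row tibble with protocol constants and headline metrics.
#' @method glance metastack_run
#' @export
glance.metastack_run <- function(x, ...) {
  rep <- tidy(x)
  pick <- function(model, metric) {
    v <- rep$estimate[rep$model == model & rep$metric == metric]
    if (length(v)) v[1L] else NA_real_
  }
  tibble(
    n = x$manifest$n, m = x$manifest$m, B = x$manifest$B,
    total_base_fits = x$manifest$total_base_fits, R = x$manifest$R,
    mae_best_base = suppressWarnings(
      min(pick("base_ridge", "MAE"), pick("base_mlp", "MAE"), na.rm = TRUE)),
    mae_best_meta = suppressWarnings(
      min(pick("meta_linear", "MAE"), pick("meta_mlp", "MAE"), na.rm = TRUE)),
    auc_best_base = suppressWarnings(
      max(pick("base_ridge", "AUC"), pick("base_mlp", "AUC"), na.rm = TRUE)),
    auc_best_meta = suppressWarnings(
      max(pick("meta_linear", "AUC"), pick("meta_mlp", "AUC"), na.rm = TRUE))
  )
}
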