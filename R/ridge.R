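#' Fit the penalized-regression base-learner (ridge with spline terms)
#'
#' The statistical base-learner: an L2-penalized regression whose design holds
#' a 4-knot restricted cubic spline basis for each spline-flagged continuous
#' predictor, full one-hot indicators for categorical predictors (the penalty
#' absorbs the collinearity) and binary flags as-is. The intercept is never
#' penalized. For the continuous task the fit is penalized least squares,
#' solved exactly through the SVD so the \eqn{\lambda = 0} limit reproduces
#' ordinary least squares; for the binary task it is a penalized logistic
#' likelihood maximized by iteratively reweighted least squares. The penalty
#' is chosen by internal 5-fold cross-validation over a log-spaced grid unless
#' `lambda` is given.
#'
#' @param data Tibble holding predictor columns and the outcome.
#' @param outcome Name of the outcome column.
#' @param schema Predictor schema (see [default_schema()]).
#' @param task `"continuous"` or `"binary"`.
#' @param preprocess `"none"` (default), `"standardize"` or `"normalize"`;
#'   parameters estimated on training rows only.
#' @param lambda Optional fixed penalty; `NULL` selects by cross-validation.
#' @param lambda_grid Candidate penalties for cross-validation.
#' @param nfolds Internal cross-validation folds.
#' @param knots_k Number of spline knots.
#' @param seed Seed for the fold assignment.
#' @return A fitted learner (class `ridge_learner`/`metastack_learner`)
#'   carrying the frozen design transform, coefficients and selected penalty.
#' @export
fit_ridge <- function(data, outcome, schema = default_schema(),
                      task = c("continuous", "binary"),
                      preprocess = "none",
                      lambda = NULL,
                      lambda_grid = 10^seq(-4, 4, length.out = 25),
                      nfolds = 5L, knots_k = 4L, seed = 1L) {
  task <- match.arg(task)
  if (!outcome %in% names(data)) {
    abort(sprintf("Outcome column `%s` not found.", outcome),
          class = "metastackr_invalid_argument")
  }
  data <- data[!is.na(data[[outcome]]), , drop = FALSE]
  if (nrow(data) == 0L) {
    abort("No rows with an observed outcome.",
          class = "metastackr_invalid_argument")
  }
  y <- as.numeric(data[[outcome]])
  if (length(unique(y)) < 2L) {
    abort("Outcome is constant; fit is degenerate.",
          class = "metastackr_degenerate_fit")
  }
  if (task == "binary" && !all(y %in% c(0, 1))) {
    abort("Binary task requires a 0/1 outcome.",
          class = "metastackr_invalid_argument")
  }

  dspec <- design_spec(data, schema, knots_k = knots_k, contrasts = "full")
  X_raw <- build_design(dspec, data)
  pp <- fit_preprocess(X_raw, preprocess)
  X <- apply_preprocess(pp, X_raw)

  if (is.null(lambda)) {
    folds <- with_stream(seed, "ridge_cv",
                         sample(rep_len(seq_len(nfolds), nrow(X))))
    cv <- ridge_cv(X, y, task, lambda_grid, folds)
    lambda <- cv$lambda
  } else {
    cv <- NULL
  }
  fit <- if (task == "continuous") {
    ridge_solve_gaussian(X, y, lambda)
  } else {
    ridge_solve_logistic(X, y, lambda)
  }

  structure(
    list(kind = "ridge", task = task, design = dspec, preprocess = pp,
         coefficients = fit$beta, intercept = fit$intercept,
         lambda = lambda, cv = cv, seed = seed, n_train = nrow(X)),
    class = c("ridge_learner", "metastack_learner")
  )
}

# Exact ridge path for squared error: center X and y, then use the SVD of the
# centered design so any lambda (including 0, where the solution is the
# minimum-norm least-squares fit) is evaluated cheaply.
ridge_gaussian_path <- function(X, y) {
  xbar <- colMeans(X)
  ybar <- mean(y)
  Xc <- sweep(X, 2L, xbar, "-")
  sv <- svd(Xc)
  keep <- sv$d > max(sv$d[1], 1e-12) * 1e-10
  list(xbar = xbar, ybar = ybar,
       u = sv$u[, keep, drop = FALSE], d = sv$d[keep],
       v = sv$v[, keep, drop = FALSE],
       uty = crossprod(sv$u[, keep, drop = FALSE], y - ybar))
}

ridge_path_beta <- function(path, lambda) {
  shrink <- path$d / (path$d^2 + lambda)
  beta <- drop(path$v %*% (shrink * path$uty))
  list(beta = beta, intercept = path$ybar - sum(path$xbar * beta))
}

ridge_solve_gaussian <- function(X, y, lambda) {
  out <- ridge_path_beta(ridge_gaussian_path(X, y), lambda)
  names(out$beta) <- colnames(X)
  out
}

# Penalized logistic via IRLS; intercept unpenalized.
ridge_solve_logistic <- function(X, y, lambda, maxit = 50L, tol = 1e-9,
                                 start = NULL) {
  p <- ncol(X)
  Z <- cbind(`(Intercept)` = 1, X)
  pen <- c(0, rep(lambda, p))
  theta <- start %||% c(stats::qlogis(min(max(mean(y), 1e-6), 1 - 1e-6)),
                        rep(0, p))
  for (it in seq_len(maxit)) {
    eta <- drop(Z %*% theta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    g <- crossprod(Z, y - mu) - pen * theta
    H <- crossprod(Z * w, Z)
    diag(H) <- diag(H) + pen + 1e-12
    step <- tryCatch(solve(H, g), error = function(e) {
      solve(H + diag(1e-8, nrow(H)), g)
    })
    theta_new <- theta + drop(step)
    if (max(abs(theta_new - theta)) < tol) {
      theta <- theta_new
      break
    }
    theta <- theta_new
  }
  beta <- theta[-1L]
  names(beta) <- colnames(X)
  list(beta = beta, intercept = theta[1L], theta = theta)
}

ridge_cv <- function(X, y, task, lambda_grid, folds) {
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  loss <- matrix(NA_real_, nrow = length(lambda_grid),
                 ncol = max(folds))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    te <- !tr
    if (task == "continuous") {
      path <- ridge_gaussian_path(X[tr, , drop = FALSE], y[tr])
      for (i in seq_along(lambda_grid)) {
        b <- ridge_path_beta(path, lambda_grid[i])
        pred <- drop(X[te, , drop = FALSE] %*% b$beta) + b$intercept
        loss[i, f] <- mean((y[te] - pred)^2)
      }
    } else {
      start <- NULL
      for (i in seq_along(lambda_grid)) {
        fit <- ridge_solve_logistic(X[tr, , drop = FALSE], y[tr],
                                    lambda_grid[i], start = start)
        start <- fit$theta
        eta <- drop(X[te, , drop = FALSE] %*% fit$beta) + fit$intercept
        mu <- pmin(pmax(stats::plogis(eta), 1e-12), 1 - 1e-12)
        loss[i, f] <- -2 * mean(y[te] * log(mu) + (1 - y[te]) * log(1 - mu))
      }
    }
  }
  mean_loss <- rowMeans(loss)
  best <- which.min(mean_loss)
  list(lambda = lambda_grid[best],
       table = tibble(lambda = lambda_grid, loss = mean_loss))
}

#' Predict from a fitted learner
#'
#' Applies the learner's frozen transforms (spline knots, category encodings,
#' preprocessing parameters estimated at training time) and returns real
#' predictions for the continuous task or probabilities in \[0, 1\] for the
#' binary task.
#'
#' @param object A fitted `metastack_learner`.
#' @param newdata Tibble of predictor columns (complete, schema-compatible).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.metastack_learner <- function(object, newdata, ...) {
  X <- apply_preprocess(object$preprocess,
                        build_design(object$design, newdata))
  eta <- drop(X %*% object$coefficients) + object$intercept
  if (object$task == "binary") stats::plogis(eta) else eta
}
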