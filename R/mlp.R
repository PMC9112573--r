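#' Control parameters of the multi-layer perceptron learners
#'
#' Defaults reproduce the reference architecture: three hidden layers of 256
#' rectified-linear units, trained by the adaptive-moment (Adam) optimizer on
#' mini-batches of 256 rows for up to 100 epochs, with early stopping on a
#' 10% internal validation split (patience 10) and inputs standardized
#' internally. Width and depth are exposed so scaled-down experiments can be
#' configured explicitly.
#'
#' @param hidden Integer vector of hidden-layer widths.
#' @param epochs Maximum training epochs.
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam step size.
#' @param patience Early-stopping patience in epochs (`Inf` disables).
#' @param val_fraction Fraction of training rows held out internally for early
#'   stopping; splits with fewer than 2 rows fall back to training-loss
#'   stopping.
#' @return An object of class `mlp_control`.
#' @export
mlp_control <- function(hidden = c(256L, 256L, 256L), epochs = 100L,
                        batch_size = 256L, learning_rate = 1e-3,
                        patience = 10L, val_fraction = 0.1) {
  stopifnot(all(hidden >= 1L), epochs >= 1L, batch_size >= 1L,
            learning_rate > 0, val_fraction >= 0, val_fraction < 1)
  structure(list(hidden = as.integer(hidden), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, patience = patience,
                 val_fraction = val_fraction),
            class = "mlp_control")
}

#' Fit the multi-layer perceptron base-learner
#'
#' A fully connected feed-forward network on the one-hot / spline-free design
#' (continuous and binary predictors as-is, categorical predictors as full
#' indicator blocks), with squared-error loss for the continuous task and
#' cross-entropy with a sigmoid output for the binary task. Training is
#' deterministic given `seed` (weight initialization, batch shuffling and the
#' validation split all draw from seeded streams).
#'
#' @inheritParams fit_ridge
#' @param control An [mlp_control()].
#' @return A fitted learner (class `mlp_learner`/`metastack_learner`).
#' @export
fit_mlp <- function(data, outcome, schema = default_schema(),
                    task = c("continuous", "binary"),
                    control = mlp_control(), seed = 1L) {
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
  # MLP design: no spline expansion (the network learns its own bends)
  flat_schema <- schema
  flat_schema$spline <- rep(FALSE, nrow(schema))
  dspec <- design_spec(data, flat_schema, contrasts = "full")
  X_raw <- build_design(dspec, data)
  pp <- fit_preprocess(X_raw, "standardize")
  X <- apply_preprocess(pp, X_raw)

  net <- with_stream(seed, "mlp_fit",
                     mlp_train(X, y, task, control))

  structure(
    list(kind = "mlp", task = task, design = dspec, preprocess = pp,
         net = net, control = control, seed = seed, n_train = nrow(X),
         hidden = control$hidden),
    class = c("mlp_learner", "metastack_learner")
  )
}

fit_mlp_matrix <- function(X, y, task, control, seed) {
  pp <- fit_preprocess(X, "standardize")
  net <- with_stream(seed, "mlp_fit",
                     mlp_train(apply_preprocess(pp, X), y, task, control))
  structure(list(kind = "mlp", task = task, design = NULL, preprocess = pp,
                 net = net, control = control, seed = seed,
                 n_train = nrow(X), hidden = control$hidden),
            class = c("mlp_learner", "metastack_learner"))
}

mlp_init <- function(sizes) {
  L <- length(sizes) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                                  sd = sqrt(2 / sizes[l])),
                     nrow = sizes[l])
    b[[l]] <- rep(0, sizes[l + 1L])
  }
  list(W = W, b = b)
}

mlp_forward <- function(par, X) {
  L <- length(par$W)
  A <- vector("list", L + 1L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    Z <- sweep(A[[l]] %*% par$W[[l]], 2L, par$b[[l]], "+")
    A[[l + 1L]] <- if (l < L) pmax(Z, 0) else Z
  }
  A
}

mlp_loss <- function(par, X, y, task) {
  out <- drop(mlp_forward(par, X)[[length(par$W) + 1L]])
  if (task == "continuous") {
    mean((y - out)^2)
  } else {
    p <- pmin(pmax(stats::plogis(out), 1e-12), 1 - 1e-12)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
}

mlp_train <- function(X, y, task, control) {
  n <- nrow(X)
  sizes <- c(ncol(X), control$hidden, 1L)
  par <- mlp_init(sizes)
  L <- length(par$W)

  n_val <- floor(control$val_fraction * n)
  if (n_val >= 2L && n - n_val >= 2L) {
    val_idx <- sample.int(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
  } else {
    val_idx <- integer()
    tr_idx <- seq_len(n)
  }
  Xtr <- X[tr_idx, , drop = FALSE]
  ytr <- y[tr_idx]
  Xval <- X[val_idx, , drop = FALSE]
  yval <- y[val_idx]

  mW <- lapply(par$W, function(w) w * 0); vW <- mW
  mb <- lapply(par$b, function(b) b * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  lr <- control$learning_rate
  t_step <- 0L
  best <- list(loss = Inf, par = par, epoch = 0L)
  wait <- 0L
  ntr <- nrow(Xtr)

  for (epoch in seq_len(control$epochs)) {
    ord <- sample.int(ntr)
    starts <- seq(1L, ntr, by = control$batch_size)
    for (s in starts) {
      idx <- ord[s:min(s + control$batch_size - 1L, ntr)]
      Xb <- Xtr[idx, , drop = FALSE]
      yb <- ytr[idx]
      A <- mlp_forward(par, Xb)
      out <- drop(A[[L + 1L]])
      nb <- length(idx)
      # dLoss/dZ_out (both losses give a (fitted - target)-shaped gradient)
      delta <- if (task == "continuous") {
        matrix(2 * (out - yb) / nb, ncol = 1L)
      } else {
        matrix((stats::plogis(out) - yb) / nb, ncol = 1L)
      }
      t_step <- t_step + 1L
      for (l in rev(seq_len(L))) {
        gW <- crossprod(A[[l]], delta)
        gb <- colSums(delta)
        if (l > 1L) {
          delta <- (delta %*% t(par$W[[l]])) * (A[[l]] > 0)
        }
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        mhW <- mW[[l]] / (1 - beta1^t_step)
        vhW <- vW[[l]] / (1 - beta2^t_step)
        mhb <- mb[[l]] / (1 - beta1^t_step)
        vhb <- vb[[l]] / (1 - beta2^t_step)
        par$W[[l]] <- par$W[[l]] - lr * mhW / (sqrt(vhW) + eps)
        par$b[[l]] <- par$b[[l]] - lr * mhb / (sqrt(vhb) + eps)
      }
    }
    monitor <- if (length(val_idx)) {
      mlp_loss(par, Xval, yval, task)
    } else {
      mlp_loss(par, Xtr, ytr, task)
    }
    if (monitor < best$loss - 1e-9) {
      best <- list(loss = monitor, par = par, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= control$patience) break
    }
  }
  list(par = best$par, epochs_run = epoch, best_epoch = best$epoch,
       monitor_loss = best$loss, sizes = sizes)
}

#' @export
predict.mlp_learner <- function(object, newdata, ...) {
  X <- if (is.null(object$design)) {
    as.matrix(newdata)
  } else {
    build_design(object$design, newdata)
  }
  X <- apply_preprocess(object$preprocess, X)
  out <- drop(mlp_forward(object$net$par, X)[[length(object$net$par$W) + 1L]])
  if (object$task == "binary") stats::plogis(out) else out
}
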