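#' Place restricted cubic spline knots at conventional quantiles
#'
#' Knots are located at fixed quantiles of the observed values following the
#' Harrell convention: for the default four knots, the 5th, 35th, 65th and
#' 95th percentiles. Knots estimated on a training sample are frozen and
#' reused verbatim on any later data; they are never re-estimated at
#' prediction time.
#'
#' @param x Numeric vector of observed values (`NA` dropped).
#' @param k Number of knots (3--7 supported; default 4).
#' @return An object of class `spline_spec`: list with sorted `knots` and the
#'   quantile `probs` used.
#' @export
#' @examples
#' place_knots(0:100)$knots  # ~ (5, 35, 65, 95)
place_knots <- function(x, k = 4L) {
  k <- check_count(k, "k", min = 3L)
  probs_table <- list(
    `3` = c(0.10, 0.50, 0.90),
    `4` = c(0.05, 0.35, 0.65, 0.95),
    `5` = c(0.05, 0.275, 0.50, 0.725, 0.95),
    `6` = c(0.05, 0.23, 0.41, 0.59, 0.77, 0.95),
    `7` = c(0.025, 0.1833, 0.3417, 0.50, 0.6583, 0.8167, 0.975)
  )
  probs <- probs_table[[as.character(k)]]
  if (is.null(probs)) {
    abort("Only 3 to 7 knots are supported.",
          class = "metastackr_invalid_argument")
  }
  x <- x[is.finite(x)]
  if (length(unique(x)) < k) {
    abort(sprintf("Need at least %d distinct finite values to place %d knots.",
                  k, k),
          class = "metastackr_degenerate_predictor")
  }
  knots <- unname(stats::quantile(x, probs, type = 7))
  if (any(diff(knots) <= 0)) {
    # heavy ties: fall back to evenly spaced distinct quantiles of unique values
    knots <- unname(stats::quantile(unique(x), probs, type = 7))
  }
  if (any(diff(knots) <= 0)) {
    abort("Knots are not strictly increasing (predictor too discrete).",
          class = "metastackr_degenerate_predictor")
  }
  structure(list(knots = knots, probs = probs), class = "spline_spec")
}

#' Restricted (natural) cubic spline basis
#'
#' Builds the k-1 column basis of a restricted cubic spline with the given
#' knots: column 1 is the identity (linear term); the remaining k-2 columns
#' are truncated-cubic combinations constrained so the fitted function is
#' linear beyond the boundary knots. Nonlinear columns are scaled by
#' \eqn{(t_k - t_1)^2} so all columns live on comparable scales, which matters
#' under a ridge penalty. Values outside the knot range are valid: the tails
#' are linear by construction.
#'
#' @param x Numeric vector.
#' @param spec A `spline_spec` from [place_knots()], or a numeric vector of
#'   knots.
#' @return Numeric matrix with `length(knots) - 1` columns.
#' @export
#' @examples
#' sp <- place_knots(rnorm(100))
#' ncol(rcs_basis(rnorm(10), sp))  # 3 columns for 4 knots
rcs_basis <- function(x, spec) {
  knots <- if (inherits(spec, "spline_spec")) spec$knots else as.numeric(spec)
  k <- length(knots)
  if (k < 3L || any(diff(knots) <= 0)) {
    abort("`spec` must carry at least 3 strictly increasing knots.",
          class = "metastackr_invalid_argument")
  }
  tk <- knots[k]
  tk1 <- knots[k - 1L]
  scale2 <- (tk - knots[1L])^2
  out <- matrix(0, nrow = length(x), ncol = k - 1L)
  out[, 1L] <- x
  cub <- function(u) pmax(u, 0)^3
  for (j in seq_len(k - 2L)) {
    tj <- knots[j]
    out[, j + 1L] <- (cub(x - tj) -
                        cub(x - tk1) * (tk - tj) / (tk - tk1) +
                        cub(x - tk) * (tk1 - tj) / (tk - tk1)) / scale2
  }
  colnames(out) <- c("x", paste0("x", strrep("'", seq_len(k - 2L))))
  out
}
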