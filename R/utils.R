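#' @importFrom rlang abort warn .data %||%
#' @importFrom tibble tibble as_tibble is_tibble
#' @import dplyr
NULL

# Deterministic sub-seed for a named random stream. Every stage of the
# pipeline (generation, missingness, imputation copy j, bootstrap plan i, ...)
# draws from its own stream so stages are independently reproducible and
# inserting a stage never perturbs the draws of another.
seed_stream <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes)) %% 1000003L
  as.integer((abs(as.integer(seed)) %% 1000003L) * 2053L + h * 7L + 1L) %% 2147483629L
}

with_stream <- function(seed, stage, code) {
  withr::with_seed(seed_stream(seed, stage), code)
}

# Shared argument checks ------------------------------------------------------

check_proportion <- function(x, name, open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (open && (x <= 0 || x >= 1)) || (!open && (x < 0 || x > 1))) {
    abort(sprintf("`%s` must be a proportion in %s.", name,
                  if (open) "(0, 1)" else "[0, 1]"),
          class = "metastackr_invalid_argument")
  }
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x)) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min),
          class = "metastackr_invalid_argument")
  }
  invisible(as.integer(x))
}

check_task <- function(task) {
  if (!is.character(task) || length(task) != 1L ||
      !task %in% c("continuous", "binary")) {
    abort('`task` must be "continuous" or "binary".',
          class = "metastackr_invalid_argument")
  }
  task
}

outcome_col <- function(task) {
  if (check_task(task) == "continuous") "y_cont" else "y_bin"
}
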