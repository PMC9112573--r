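# Frozen design-matrix transform shared by the learners.
#
# The transform is estimated on training rows only (spline knots, category
# level sets, preprocessing centers/scales) and then applied verbatim to any
# new data, so nothing about test rows can leak into the fitted model.

design_spec <- function(data, schema, knots_k = 4L,
                        contrasts = c("full", "drop_first")) {
  contrasts <- match.arg(contrasts)
  validate_schema(schema)
  missing_cols <- setdiff(schema$name, names(data))
  if (length(missing_cols)) {
    abort(paste0("Predictors absent from data: ",
                 paste(missing_cols, collapse = ", ")),
          class = "metastackr_schema_error")
  }
  if (anyNA(data[schema$name])) {
    abort("Design construction requires complete predictors (impute first).",
          class = "metastackr_invalid_argument")
  }
  specs <- vector("list", nrow(schema))
  names(specs) <- schema$name
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    kind <- schema$kind[i]
    if (kind == "continuous" && isTRUE(schema$spline[i])) {
      specs[[nm]] <- list(type = "rcs", spec = place_knots(data[[nm]], knots_k))
    } else if (kind == "continuous") {
      specs[[nm]] <- list(type = "linear")
    } else if (kind == "binary") {
      specs[[nm]] <- list(type = "binary")
    } else {
      lev <- schema$levels[[i]] %||% sort(unique(as.character(data[[nm]])))
      keep <- if (contrasts == "drop_first") lev[-1L] else lev
      specs[[nm]] <- list(type = "onehot", levels = lev, keep = keep)
    }
  }
  structure(list(schema = schema, specs = specs, contrasts = contrasts,
                 knots_k = knots_k),
            class = "design_spec")
}

build_design <- function(spec, data) {
  stopifnot(inherits(spec, "design_spec"))
  schema <- spec$schema
  missing_cols <- setdiff(schema$name, names(data))
  if (length(missing_cols)) {
    abort(paste0("Predictors absent from data: ",
                 paste(missing_cols, collapse = ", ")),
          class = "metastackr_schema_error")
  }
  if (anyNA(data[schema$name])) {
    abort("Prediction requires complete predictors.",
          class = "metastackr_invalid_argument")
  }
  blocks <- lapply(schema$name, function(nm) {
    s <- spec$specs[[nm]]
    v <- data[[nm]]
    if (s$type == "rcs") {
      b <- rcs_basis(as.numeric(v), s$spec)
      colnames(b) <- paste0(nm, "_rcs", seq_len(ncol(b)))
      b
    } else if (s$type == "linear") {
      matrix(as.numeric(v), ncol = 1L, dimnames = list(NULL, nm))
    } else if (s$type == "binary") {
      matrix(as.numeric(v), ncol = 1L, dimnames = list(NULL, nm))
    } else {
      v <- as.character(v)
      unknown <- setdiff(unique(v), s$levels)
      if (length(unknown)) {
        abort(sprintf("Unknown level(s) %s in `%s`.",
                      paste(unknown, collapse = ", "), nm),
              class = "metastackr_schema_error")
      }
      b <- vapply(s$keep, function(l) as.numeric(v == l),
                  numeric(length(v)))
      if (is.null(dim(b))) b <- matrix(b, nrow = length(v))
      colnames(b) <- paste0(nm, "_", s$keep)
      b
    }
  })
  do.call(cbind, blocks)
}

# Preprocessing of an assembled design matrix: none, z-standardization, or
# min-max normalization. Parameters are estimated from training rows only.
fit_preprocess <- function(X, mode = c("none", "standardize", "normalize")) {
  mode <- match.arg(mode)
  if (mode == "none") {
    return(structure(list(mode = mode), class = "preprocess_spec"))
  }
  if (mode == "standardize") {
    center <- colMeans(X)
    scale <- apply(X, 2L, stats::sd)
    scale[!is.finite(scale) | scale == 0] <- 1
    structure(list(mode = mode, center = center, scale = scale),
              class = "preprocess_spec")
  } else {
    lo <- apply(X, 2L, min)
    hi <- apply(X, 2L, max)
    rng <- hi - lo
    rng[rng == 0] <- 1
    structure(list(mode = mode, center = lo, scale = rng),
              class = "preprocess_spec")
  }
}

apply_preprocess <- function(pp, X) {
  stopifnot(inherits(pp, "preprocess_spec"))
  if (pp$mode == "none") return(X)
  sweep(sweep(X, 2L, pp$center, "-"), 2L, pp$scale, "/")
}
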