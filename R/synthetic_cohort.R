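#' Default predictor schema for a synthetic primary-care depression cohort
#'
#' The analysis pipeline expects 31 baseline predictors: three continuous
#' variables modelled through restricted cubic splines (age, BMI, baseline
#' depression severity on the PHQ-9 0--27 scale), two categorical variables
#' (ethnicity, deprivation quintile) and 26 binary history/comorbidity flags.
#' Real extracts carry their own variable names; these placeholders reproduce
#' the taxonomy (demographics, condition severity, previous treatment,
#' comorbidities) without claiming the original coding.
#'
#' @return A tibble with columns `name`, `kind` (`"continuous"`, `"binary"` or
#'   `"categorical"`), `levels` (list column, categorical only) and `spline`
#'   (`TRUE` for the three continuous predictors entering the spline basis).
#' @export
#' @examples
#' sch <- default_schema()
#' nrow(sch)                      # 31 predictors
#' sum(sch$kind == "continuous")  # 3, all spline-flagged
default_schema <- function() {
  flags <- c(
    "sex", "smoker", "alcohol_misuse", "anxiety", "panic_disorder",
    "sleep_disorder", "self_harm_hist", "psychotherapy_hist", "hypnotic_use",
    "anxiolytic_use", "nsaid_use", "statin_use", "diabetes", "hypertension",
    "cvd", "asthma", "copd", "cancer", "ckd", "epilepsy", "migraine",
    "hypothyroidism", "arthritis", "ibd", "obesity_dx", "substance_misuse"
  )
  sch <- tibble(
    name = c("age", "bmi", "base_severity", "ethnicity", "deprivation", flags),
    kind = c(rep("continuous", 3L), rep("categorical", 2L),
             rep("binary", length(flags))),
    levels = c(vector("list", 3L),
               list(c("white", "black", "asian", "mixed", "other"),
                    paste0("q", 1:5)),
               vector("list", length(flags))),
    spline = c(rep(TRUE, 3L), rep(FALSE, 2L + length(flags)))
  )
  validate_schema(sch)
  sch
}

validate_schema <- function(schema) {
  stopifnot(is.data.frame(schema),
            all(c("name", "kind", "levels", "spline") %in% names(schema)))
  if (anyDuplicated(schema$name)) {
    abort("Schema predictor names must be unique.",
          class = "metastackr_invalid_argument")
  }
  if (!all(schema$kind %in% c("continuous", "binary", "categorical"))) {
    abort("Schema `kind` must be continuous, binary or categorical.",
          class = "metastackr_invalid_argument")
  }
  bad <- schema$kind == "categorical" &
    vapply(schema$levels, function(l) length(l) < 2L, logical(1))
  if (any(bad)) {
    abort("Categorical predictors need at least 2 levels.",
          class = "metastackr_invalid_argument")
  }
  if (any(schema$spline & schema$kind != "continuous")) {
    abort("Only continuous predictors can be spline-flagged.",
          class = "metastackr_invalid_argument")
  }
  invisible(schema)
}

#' The ten region labels used by the synthetic cohort
#'
#' Mirrors data collection across ten English regions, the clustering unit of
#' the internal-external cross-validation.
#' @return Character vector of length 10.
#' @export
region_levels <- function() {
  c("north_east", "north_west", "yorkshire_humber", "east_midlands",
    "west_midlands", "east_of_england", "london", "south_east_coast",
    "south_central", "south_west")
}

default_missing_rates <- function() {
  c(base_severity = 0.75, bmi = 0.05, smoker = 0.02, alcohol_misuse = 0.02)
}

#' Configuration of the synthetic cohort generator
#'
#' Bundles every knob of the data-generating process. Defaults emulate the
#' structure of the motivating primary-care cohort: a binary dropout outcome
#' with 37.5% prevalence, an integer severity outcome on the PHQ-9 0--27 scale
#' observed for only 16384/187757 of patients, 75% missingness in baseline
#' severity, and ten regions with small random intercepts.
#'
#' @param n Number of patients.
#' @param seed Integer master seed; each generation stage uses a named
#'   sub-stream derived from it.
#' @param target_prevalence Population event probability of the binary outcome.
#' @param noise_sd Residual SD of the latent continuous outcome, on the PHQ-9
#'   scale (before rounding/clipping).
#' @param nonlinearity_weight Multiplier on the smooth nonlinear (spline-bend)
#'   terms; 0 gives a purely linear continuous outcome.
#' @param interaction_weight Multiplier on the pairwise interaction terms.
#' @param missing_rates Named vector of per-predictor missingness proportions
#'   used by [apply_missingness()].
#' @param region_effect_sd SD of the random region intercepts.
#' @param cont_subset_fraction Fraction of patients with an observed continuous
#'   outcome (the severity subcohort); the binary outcome is always observed.
#' @return An object of class `generator_config` (a named list).
#' @export
#' @examples
#' cfg <- generator_config(n = 500, seed = 1)
#' cohort <- generate_cohort(cfg)$cohort
generator_config <- function(n,
                             seed = 1L,
                             target_prevalence = 0.375,
                             noise_sd = 5.5,
                             nonlinearity_weight = 1,
                             interaction_weight = 1,
                             missing_rates = default_missing_rates(),
                             region_effect_sd = 0.3,
                             cont_subset_fraction = 16384 / 187757) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0 || n != floor(n)) {
    abort("`n` must be a non-negative integer.",
          class = "metastackr_invalid_argument")
  }
  check_proportion(target_prevalence, "target_prevalence", open = TRUE)
  check_proportion(cont_subset_fraction, "cont_subset_fraction")
  if (noise_sd < 0 || region_effect_sd < 0) {
    abort("Scale parameters must be non-negative.",
          class = "metastackr_invalid_argument")
  }
  if (length(missing_rates) &&
      (any(missing_rates < 0) || any(missing_rates > 1))) {
    abort("`missing_rates` must lie in [0, 1].",
          class = "metastackr_invalid_argument")
  }
  structure(
    list(n = as.integer(n), seed = as.integer(seed),
         target_prevalence = target_prevalence, noise_sd = noise_sd,
         nonlinearity_weight = nonlinearity_weight,
         interaction_weight = interaction_weight,
         missing_rates = missing_rates,
         region_effect_sd = region_effect_sd,
         cont_subset_fraction = cont_subset_fraction),
    class = "generator_config"
  )
}

# True effect sizes of the generating model. Baseline severity dominates the
# continuous outcome; ethnicity and deprivation dominate the binary outcome,
# echoing the importance ordering seen in routine primary-care dropout data.
generator_coefficients <- function() {
  list(
    cont = list(
      intercept = 8,
      base_severity = 0.45, age = 0.02, bmi = 0.03,
      anxiety = 0.8, sleep_disorder = 0.6, self_harm_hist = 0.5,
      deprivation = 0.15,                       # per quintile step
      bend_scale = 3,                            # cubic bend in base_severity
      interaction = 0.008                        # (severity-16) x (age-50)
    ),
    bin = list(
      ethnicity = c(white = 0, black = 0.35, asian = 0.30, mixed = 0.20,
                    other = 0.25),
      deprivation = 0.12,                        # per quintile step
      age = -0.004,
      smoker = 0.10, alcohol_misuse = 0.10, substance_misuse = 0.12,
      bend_scale = 0.3,                          # cubic bend in age
      interaction = 0.15                         # smoker x alcohol_misuse
    )
  )
}

severity_bend <- function(sev) pmax((sev - 18) / 9, 0)^3
age_bend <- function(age) pmax((age - 60) / 30, 0)^3

# Linear predictors of the generating model on a predictor tibble (no
# missingness). Returns list(mu_lin, mu_nl, mu_int, eta_lin, eta_nl, eta_int).
generator_signal <- function(X, config) {
  cf <- generator_coefficients()
  depr_step <- as.numeric(factor(X$deprivation, levels = paste0("q", 1:5))) - 3
  cc <- cf$cont
  mu_lin <- cc$intercept +
    cc$base_severity * (X$base_severity - 16) +
    cc$age * (X$age - 50) +
    cc$bmi * (X$bmi - 27) +
    cc$anxiety * X$anxiety +
    cc$sleep_disorder * X$sleep_disorder +
    cc$self_harm_hist * X$self_harm_hist +
    cc$deprivation * depr_step
  mu_nl <- cc$bend_scale * severity_bend(X$base_severity)
  mu_int <- cc$interaction * (X$base_severity - 16) * (X$age - 50)

  cb <- cf$bin
  eta_lin <- unname(cb$ethnicity[X$ethnicity]) +
    cb$deprivation * depr_step +
    cb$age * (X$age - 50) +
    cb$smoker * X$smoker +
    cb$alcohol_misuse * X$alcohol_misuse +
    cb$substance_misuse * X$substance_misuse
  eta_nl <- cb$bend_scale * age_bend(X$age)
  eta_int <- cb$interaction * X$smoker * X$alcohol_misuse
  list(mu_lin = mu_lin, mu_nl = mu_nl, mu_int = mu_int,
       eta_lin = eta_lin, eta_nl = eta_nl, eta_int = eta_int)
}

#' Generate a synthetic cohort with oracle ground truth
#'
#' Draws `config$n` patients from a known data-generating process: 31 mixed
#' predictors, an integer continuous outcome produced by rounding and clipping
#' a latent mean (linear + smooth nonlinear bend in baseline severity +
#' severity-by-age interaction + random region intercept + Gaussian noise) to
#' the 0--27 PHQ-9 range, and a binary outcome from a logistic latent model
#' whose intercept is calibrated so the mean event probability equals
#' `target_prevalence`. No missingness is applied here; see
#' [apply_missingness()].
#'
#' @param config A [generator_config()].
#' @return A list with `cohort` (tibble: `patient_id`, `region`, 31 predictor
#'   columns, `y_cont`, `y_bin`) and `oracle` (tibble: `patient_id`,
#'   `mu_cont_raw` latent mean before integerization, `mu_cont` its clipped
#'   value, `p_bin` true event probability; the generating coefficients are
#'   attached as attribute `"coefficients"`).
#' @export
#' @examples
#' out <- generate_cohort(generator_config(n = 200, seed = 42))
#' mean(out$cohort$y_bin)     # close to 0.375
#' range(out$cohort$y_cont)   # within 0..27
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n
  schema <- default_schema()
  if (n == 0L) {
    empty <- tibble(patient_id = character(), region = character())
    for (i in seq_len(nrow(schema))) {
      empty[[schema$name[i]]] <-
        if (schema$kind[i] == "continuous") numeric() else character()
    }
    empty$y_cont <- integer()
    empty$y_bin <- integer()
    oracle <- tibble(patient_id = character(), mu_cont_raw = numeric(),
                     mu_cont = numeric(), p_bin = numeric())
    attr(oracle, "coefficients") <- generator_coefficients()
    return(list(cohort = empty, oracle = oracle))
  }

  X <- with_stream(config$seed, "predictors", {
    flags <- default_schema() |> filter(.data$kind == "binary") |> pull("name")
    flag_p <- stats::setNames(
      round(stats::runif(length(flags), 0.05, 0.40), 3), flags)
    # fixed marginals given the seed stream; sex kept near-balanced
    flag_p["sex"] <- 0.62
    out <- tibble(
      patient_id = sprintf("pt%07d", seq_len(n)),
      region = sample(region_levels(), n, replace = TRUE),
      age = stats::runif(n, 18, 90),
      bmi = pmin(45, pmax(15, stats::rnorm(n, 27, 5))),
      base_severity = pmin(27, pmax(0, round(stats::rnorm(n, 16, 5)))),
      ethnicity = sample(c("white", "black", "asian", "mixed", "other"), n,
                         replace = TRUE,
                         prob = c(0.80, 0.05, 0.08, 0.03, 0.04)),
      deprivation = sample(paste0("q", 1:5), n, replace = TRUE)
    )
    for (f in flags) out[[f]] <- stats::rbinom(n, 1L, flag_p[[f]])
    out
  })

  sig <- generator_signal(X, config)
  region_int <- with_stream(config$seed, "region_effects", {
    stats::setNames(stats::rnorm(10, 0, config$region_effect_sd),
                    region_levels())
  })
  u <- unname(region_int[X$region])

  mu_raw <- sig$mu_lin + config$nonlinearity_weight * sig$mu_nl +
    config$interaction_weight * sig$mu_int + u
  eps <- with_stream(config$seed, "cont_noise",
                     stats::rnorm(n, 0, config$noise_sd))
  y_cont <- as.integer(pmin(27, pmax(0, round(mu_raw + eps))))

  eta0 <- sig$eta_lin + config$nonlinearity_weight * sig$eta_nl +
    config$interaction_weight * sig$eta_int + u
  # calibrate the intercept so the mean event probability hits the target
  alpha <- stats::uniroot(
    function(a) mean(stats::plogis(a + eta0)) - config$target_prevalence,
    interval = c(-20, 20), tol = 1e-10
  )$root
  p_bin <- stats::plogis(alpha + eta0)
  y_bin <- with_stream(config$seed, "bin_outcome",
                       stats::rbinom(n, 1L, p_bin))

  cohort <- X
  cohort$y_cont <- y_cont
  cohort$y_bin <- as.integer(y_bin)

  oracle <- tibble(patient_id = X$patient_id, mu_cont_raw = mu_raw,
                   mu_cont = pmin(27, pmax(0, mu_raw)), p_bin = p_bin)
  cf <- generator_coefficients()
  cf$bin_intercept <- alpha
  cf$region_intercepts <- region_int
  attr(oracle, "coefficients") <- cf
  list(cohort = cohort, oracle = oracle)
}

#' Apply a missing-at-random missingness mechanism to a generated cohort
#'
#' Masks predictor values with probabilities that depend only on fully
#' observed columns (age, sex, region intercept side information is never
#' used), so the mechanism is missing-at-random by construction: conditional
#' on the observed drivers, masking is independent of the masked value. The
#' continuous outcome is reduced to the severity subcohort via
#' `cont_subset_fraction` (completely at random); the binary outcome is never
#' masked.
#'
#' @param cohort A cohort tibble from [generate_cohort()] with no prior
#'   predictor missingness.
#' @param config The [generator_config()] supplying `missing_rates` and
#'   `cont_subset_fraction`.
#' @return The cohort with `NA` in masked cells.
#' @export
apply_missingness <- function(cohort, config) {
  stopifnot(inherits(config, "generator_config"))
  rates <- config$missing_rates
  if (length(rates) && (any(rates < 0) || any(rates > 1))) {
    abort("missing rates must lie in [0, 1].",
          class = "metastackr_invalid_argument")
  }
  schema <- default_schema()
  if (anyNA(cohort[schema$name])) {
    abort("`cohort` must not already contain predictor missingness.",
          class = "metastackr_invalid_argument")
  }
  n <- nrow(cohort)
  out <- cohort
  if (n > 0L) {
    # MAR drivers: age and sex are always fully observed
    z_age <- as.numeric(scale(out$age))
    if (all(is.na(z_age))) z_age <- rep(0, n)
    driver <- 0.8 * z_age + 0.4 * out$sex
    for (v in names(rates)) {
      r <- rates[[v]]
      if (r <= 0) next
      if (!v %in% schema$name) {
        abort(sprintf("Unknown predictor `%s` in missing_rates.", v),
              class = "metastackr_invalid_argument")
      }
      if (r >= 1) {
        out[[v]][] <- NA
        next
      }
      a <- stats::uniroot(
        function(a) mean(stats::plogis(a + driver)) - r,
        interval = c(-30, 30), tol = 1e-10
      )$root
      mask <- with_stream(config$seed, paste0("missing_", v),
                          stats::runif(n) < stats::plogis(a + driver))
      out[[v]][mask] <- NA
    }
    if (config$cont_subset_fraction < 1) {
      keep <- with_stream(config$seed, "cont_subset",
                          stats::runif(n) < config$cont_subset_fraction)
      out$y_cont[!keep] <- NA
    }
  }
  out
}

#' Generate a cohort and apply its missingness mechanism in one call
#'
#' @inheritParams generate_cohort
#' @return As [generate_cohort()], with masked cells in `cohort`.
#' @export
simulate_cohort <- function(config) {
  out <- generate_cohort(config)
  out$cohort <- apply_missingness(out$cohort, config)
  out
}
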