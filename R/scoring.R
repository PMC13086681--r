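# The mean-centered Cox linear score: score_pat = sum_i beta_i (X_i - xbar_i).
# CAPRI uses 14 clinical variables (including thoracic aortic calcium
# volume); eCAPRI adds L3 muscle area, BSA-indexed RV volume and BSA-indexed
# PA max radius. The published coefficients, fitted on a 765-patient TAVI
# training cohort, are packaged as frozen defaults.

#' Construct a score model
#'
#' @param name Model name.
#' @param variables Character vector, ordered variable names (no repeats).
#' @param beta Named numeric coefficients, keyed exactly by `variables`.
#' @param xbar Named numeric training means, keyed exactly by `variables`.
#' @param provenance `"packaged"` or `"fitted"`, plus free-form detail.
#' @param baseline Optional `data.frame` with `time` and `hazard` (Breslow
#'   cumulative baseline hazard at the training means), required by
#'   [risk_probability()].
#' @return An object of class `score_model`.
#' @export
score_model <- function(name, variables, beta, xbar,
                        provenance = "fitted", baseline = NULL) {
  variables <- as.character(variables)
  if (anyDuplicated(variables)) stopf("variables must not repeat")
  if (!identical(sort(names(beta)), sort(variables)) ||
      !identical(sort(names(xbar)), sort(variables)))
    stopf("beta and xbar must be keyed exactly by `variables`")
  structure(list(name = name, variables = variables,
                 beta = beta[variables], xbar = xbar[variables],
                 provenance = provenance, baseline = baseline),
            class = "score_model")
}

#' @export
print.score_model <- function(x, ...) {
  cat(sprintf("<score_model> %s (%s): %d variables\n", x$name,
              paste(x$provenance, collapse = "; "), length(x$variables)))
  print(data.frame(beta = x$beta, xbar = x$xbar))
  invisible(x)
}

# Final multivariate Cox coefficients and training means, transcribed
# digit-for-digit from the published fit on the full 765-patient training
# set. Ordinal grades are 0-based (grade I = 0), the coding under which
# these means match the cohort's category frequencies.
capri_table <- function() {
  data.frame(
    variable = c("age_years", "paps_tens_mmHg", "aortic_gradient_mmHg",
                 "ejection_fraction_pct", "male", "clearance_grade",
                 "paps_available", "peripheral_arterial_disease",
                 "respiratory_failure", "tia_stroke", "coronary_disease",
                 "nyha", "mitral_regurgitation", "tac_volume_ml",
                 "l3_muscle_area_cm2", "bsai_rv_volume",
                 "bsai_pa_max_radius"),
    beta_capri = c(0.0115, 0.1620, -0.0032, 0.0027, 0.1806, 0.4433,
                   -0.3357, 0.0262, 0.1801, 0.3529, -0.4413, 0.1998,
                   0.0382, -0.0394, NA, NA, NA),
    beta_ecapri = c(-0.0017, 0.1496, -0.0033, 0.0088, 0.9495, 0.3635,
                    -0.3648, 0.1262, 0.1569, 0.4121, -0.4802, 0.2177,
                    -0.0584, -0.0432, -0.0221, 0.0068, 0.3040),
    xbar = c(82.19, 3.10, 48.62, 56.70, 0.51, 1.67, 0.74, 0.12, 0.20,
             0.11, 0.32, 1.41, 0.83, 3.79, 120.32, 74.02, 0.95),
    stringsAsFactors = FALSE)
}

#' Packaged CAPRI score model
#'
#' The 14-variable clinical + TAC score with its published coefficients
#' and training means.
#'
#' @return A [score_model()].
#' @export
capri_model <- function() {
  tb <- capri_table()
  keep <- !is.na(tb$beta_capri)
  score_model("CAPRI", tb$variable[keep],
              setNames(tb$beta_capri[keep], tb$variable[keep]),
              setNames(tb$xbar[keep], tb$variable[keep]),
              provenance = "packaged")
}

#' Packaged eCAPRI score model
#'
#' The CAPRI variables plus L3-level muscle area, BSA-indexed RV volume
#' and BSA-indexed pulmonary-artery max radius, with published
#' coefficients and training means.
#'
#' @return A [score_model()].
#' @export
ecapri_model <- function() {
  tb <- capri_table()
  score_model("eCAPRI", tb$variable,
              setNames(tb$beta_ecapri, tb$variable),
              setNames(tb$xbar, tb$variable),
              provenance = "packaged")
}

#' Both packaged score models
#'
#' @return List with elements `capri` and `ecapri`.
#' @export
packaged_models <- function() {
  list(capri = capri_model(), ecapri = ecapri_model())
}

roman_to_grade <- function(x) {
  map <- c(I = 0, II = 1, III = 2, IV = 3, V = 4)
  out <- unname(map[toupper(trimws(x))])
  out
}

#' Encode raw clinical records
#'
#' Validates and numerically encodes the CAPRI clinical variables: ordinal
#' grades given as Roman numerals are mapped 0-based (I to 0, II to 1, ...);
#' numeric grade inputs are taken as already 0-based encodings; binaries
#' must be 0/1 (logicals accepted). The PAPs rule is enforced: when
#' `paps_available` is 0, `paps_tens_mmHg` is coerced to 0 (with a warning
#' if a nonzero pressure was supplied).
#'
#' @param records `data.frame` (or coercible) of raw clinical inputs.
#' @return Numeric `data.frame` with the same rows.
#' @export
encode_clinical <- function(records) {
  df <- as.data.frame(records)
  ord_max <- c(nyha = 3, mitral_regurgitation = 4, clearance_grade = 4)
  for (nm in names(ord_max)) {
    if (!nm %in% names(df)) next
    v <- df[[nm]]
    if (is.character(v) || is.factor(v)) {
      g <- roman_to_grade(as.character(v))
      if (anyNA(g)) {
        bad <- unique(as.character(v)[is.na(g)])
        stopf("unknown grade for %s: %s", nm, paste(bad, collapse = ", "))
      }
      v <- g
    }
    if (any(v < 0 | v > ord_max[nm] | v != round(v)))
      stopf("%s grade out of range [0, %d]: %s", nm, ord_max[nm],
            paste(unique(v[v < 0 | v > ord_max[nm] | v != round(v)]),
                  collapse = ", "))
    df[[nm]] <- as.numeric(v)
  }
  bins <- c("male", "paps_available", "peripheral_arterial_disease",
            "respiratory_failure", "tia_stroke", "coronary_disease")
  for (nm in intersect(bins, names(df))) {
    v <- df[[nm]]
    if (is.logical(v)) v <- as.numeric(v)
    if (!all(v %in% c(0, 1)))
      stopf("%s must be 0/1; got: %s", nm,
            paste(unique(v[!v %in% c(0, 1)]), collapse = ", "))
    df[[nm]] <- as.numeric(v)
  }
  if (all(c("paps_available", "paps_tens_mmHg") %in% names(df))) {
    off <- df$paps_available == 0 & df$paps_tens_mmHg != 0
    if (any(off)) {
      warnf("PAPs supplied for %d record(s) with paps_available = 0; coerced to 0",
            sum(off))
      df$paps_tens_mmHg[off] <- 0
    }
  }
  df
}

#' Compute a mean-centered Cox linear score
#'
#' `score_pat = sum_i beta_i * (X_i - xbar_i)` over the model's variables.
#' A patient exactly at the training means scores 0; score differences
#' between patients do not depend on the means.
#'
#' @param model A [score_model()].
#' @param newdata `data.frame` (or named list/vector) covering every model
#'   variable.
#' @return Numeric vector, one score per row.
#' @examples
#' m <- ecapri_model()
#' compute_score(m, as.list(m$xbar))  # 0 by construction
#' @export
compute_score <- function(model, newdata) {
  stopifnot(inherits(model, "score_model"))
  if (!is.data.frame(newdata)) newdata <- as.data.frame(as.list(newdata))
  missing <- setdiff(model$variables, names(newdata))
  if (length(missing))
    stopf("newdata lacks model variable(s): %s", paste(missing, collapse = ", "))
  x <- as.matrix(newdata[, model$variables, drop = FALSE])
  x <- sweep(x, 2, model$xbar)   # center first: score at the means is exactly 0
  as.numeric(x %*% model$beta)
}

#' Fit a multivariate Cox model as a score
#'
#' Maximizes the Cox partial likelihood (Efron tie correction by default)
#' over the given variables and packages the result as a mean-centered
#' linear score: coefficients from the fit, centering means from the
#' training columns. The Breslow baseline cumulative hazard at the
#' training means is retained so that [risk_probability()] can map scores
#' to event probabilities.
#'
#' @param cohort `data.frame` with the variables plus follow-up time and
#'   event columns.
#' @param variables Character vector of covariates to include.
#' @param time,event Column names (defaults `"followup_days"`, `"event"`).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param name Model name.
#' @return A [score_model()] with extra fields: `loglik` (null, fitted),
#'   `se` (per-variable standard errors), `n`, `nevent`.
#' @export
fit_cox <- function(cohort, variables, time = "followup_days",
                    event = "event", ties = c("efron", "breslow"),
                    name = "fitted") {
  ties <- match.arg(ties)
  missing <- setdiff(c(variables, time, event), names(cohort))
  if (length(missing))
    stopf("cohort lacks column(s): %s", paste(missing, collapse = ", "))
  if (sum(cohort[[event]]) < 2) stopf("need at least 2 events to fit")
  const <- variables[vapply(variables, function(v)
    var(cohort[[v]]) == 0, TRUE)]
  if (length(const))
    stopf("constant covariate(s): %s", paste(const, collapse = ", "))
  x <- as.matrix(cohort[, variables, drop = FALSE])
  y <- survival::Surv(cohort[[time]], cohort[[event]])
  fit <- survival::coxph(y ~ x, ties = ties,
                         control = survival::coxph.control(iter.max = 50))
  if (fit$iter >= 50)
    stopf("Cox fit did not converge in %d iterations", 50)
  beta <- setNames(as.numeric(coef(fit)), variables)
  se <- setNames(sqrt(diag(fit$var)), variables)
  if (any(abs(beta) > 20))
    warnf("very large coefficient(s) (|beta| > 20): possible complete separation")
  xbar <- colMeans(cohort[, variables, drop = FALSE])
  # cumulative hazard referenced to a patient at the training means, the
  # same reference point as the centered score
  bh <- survival::basehaz(fit, centered = FALSE)
  m <- score_model(name, variables, beta, xbar = xbar,
                   provenance = sprintf("fitted (ties = %s)", ties),
                   baseline = data.frame(
                     time = bh$time,
                     hazard = bh$hazard * exp(sum(beta * xbar))))
  m$loglik <- fit$loglik
  m$se <- se
  m$n <- nrow(cohort)
  m$nevent <- sum(cohort[[event]])
  m
}

#' Write / read a score model as JSON
#'
#' Versioned schema (`schema_version` 1) carrying the name, ordered
#' variables, coefficients, training means and (when available) the
#' baseline cumulative hazard. Numeric values round-trip unchanged.
#'
#' @param model A [score_model()].
#' @param path File path.
#' @return `write_score_model` returns `path` invisibly; `read_score_model`
#'   returns the [score_model()].
#' @export
write_score_model <- function(model, path) {
  stopifnot(inherits(model, "score_model"))
  obj <- list(schema_version = 1L, name = model$name,
              variables = as.list(model$variables),
              beta = as.list(model$beta), xbar = as.list(model$xbar),
              provenance = model$provenance)
  if (!is.null(model$baseline))
    obj$baseline <- list(time = model$baseline$time,
                         hazard = model$baseline$hazard)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_score_model
#' @export
read_score_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version) || obj$schema_version != 1)
    stopf("unsupported score-model schema version")
  baseline <- if (!is.null(obj$baseline))
    data.frame(time = obj$baseline$time, hazard = obj$baseline$hazard)
  score_model(obj$name, unlist(obj$variables),
              unlist(obj$beta), unlist(obj$xbar),
              provenance = obj$provenance, baseline = baseline)
}
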