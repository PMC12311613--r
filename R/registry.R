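#' @title Declarative model registry
#' @description
#' Each risk model ships as a JSON file describing its mathematical form
#' (`logistic_direct`, `cox_baseline`, `rr_times_incidence` or
#' `annual_recursion`), intercept, terms (predictor, transformation
#' pipeline, coefficient) and baseline tables (baseline survival,
#' age-sex incidence, or annual hazard tables).  Twelve calculators are
#' bundled; each file records its source citation and whether the
#' transcription is exact or a documented surrogate.
#' @name model_registry
NULL

.known_models <- function() {
  data.frame(
    name = c("LCRAT", "LLPv2", "LLPv3", "Pittsburgh", "HUNT", "OWL",
             "LCRS", "PLCOm2012", "PLCOall2014", "NHIS", "LLPi", "Bach"),
    population = c("ever_only", "all", "all", "ever_only", "ever_only",
                   "all", "all", "ever_only", "all", "ever_only", "all",
                   "ever_only"),
    horizon = c(5, 5, 5, 6, 6, 6, 6, 6, 6, 6.6, 8.7, 10),
    stringsAsFactors = FALSE)
}

.transform_ops <- c("add", "subtract", "multiply", "divide", "power",
                    "log", "truncate", "map", "bin", "indicator")

#' Load a model specification
#'
#' @param path path to a JSON model-spec file.
#' @return A validated `lr_model_spec` list.
#' @export
load_model_spec <- function(path) {
  if (!file.exists(path)) stop("spec file not found: ", path, call. = FALSE)
  spec <- jsonlite::read_json(path, simplifyVector = FALSE)
  spec$path <- path
  validate_model_spec(spec)
}

#' Validate a model specification
#'
#' Checks the schema: known form and population, positive horizon, every
#' referenced predictor a canonical cohort field, known transformation
#' ops, and — for the twelve bundled model names — the expected
#' population and horizon.
#'
#' @param spec a model-spec list.
#' @return The spec with class `lr_model_spec`; stops with the offending
#'   field path on violation.
#' @export
validate_model_spec <- function(spec) {
  req <- c("schema_version", "name", "population", "horizon_years",
           "form", "terms")
  miss <- setdiff(req, names(spec))
  if (length(miss)) {
    stop("spec error at <root>: missing field(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!spec$form %in% c("logistic_direct", "cox_baseline",
                        "rr_times_incidence", "annual_recursion")) {
    stop("spec error at form: unknown form '", spec$form, "'",
         call. = FALSE)
  }
  if (!spec$population %in% c("ever_only", "all")) {
    stop("spec error at population: must be ever_only or all",
         call. = FALSE)
  }
  if (!is.numeric(spec$horizon_years) || spec$horizon_years <= 0) {
    stop("spec error at horizon_years: must be positive", call. = FALSE)
  }
  known <- .known_models()
  k <- match(spec$name, known$name)
  if (!is.na(k)) {
    if (spec$population != known$population[k] ||
        abs(spec$horizon_years - known$horizon[k]) > 1e-9) {
      stop("spec error: model ", spec$name, " must have population ",
           known$population[k], " and horizon ", known$horizon[k],
           call. = FALSE)
    }
  }
  fields <- setdiff(cohort_columns(), c("id", "event", "time"))
  for (i in seq_along(spec$terms)) {
    term <- spec$terms[[i]]
    at <- paste0("terms[", i, "]")
    if (is.null(term$predictor) || !term$predictor %in% fields) {
      stop("spec error at ", at, ": unknown predictor '",
           term$predictor, "'", call. = FALSE)
    }
    if (is.null(term$coef) || !is.numeric(term$coef)) {
      stop("spec error at ", at, ": missing numeric coef", call. = FALSE)
    }
    for (j in seq_along(term$transform)) {
      op <- term$transform[[j]]$op
      if (is.null(op) || !op %in% .transform_ops) {
        stop("spec error at ", at, ".transform[", j, "]: unknown op '",
             op, "'", call. = FALSE)
      }
    }
  }
  if (spec$form == "cox_baseline") {
    s0 <- spec$baselines$s0
    if (is.null(s0) || s0 <= 0 || s0 > 1) {
      stop("spec error at baselines.s0: need baseline survival in (0, 1]",
           call. = FALSE)
    }
  }
  if (spec$form == "rr_times_incidence" &&
      is.null(spec$baselines$incidence)) {
    stop("spec error at baselines.incidence: age-sex baseline risk ",
         "table required", call. = FALSE)
  }
  if (spec$form == "annual_recursion" &&
      (is.null(spec$baselines$lc_hazard) ||
       is.null(spec$baselines$mortality_hazard))) {
    stop("spec error at baselines: annual lung-cancer and competing ",
         "mortality hazard tables required", call. = FALSE)
  }
  class(spec) <- "lr_model_spec"
  spec
}

#' List the bundled model specifications
#'
#' @return Named list of the twelve bundled `lr_model_spec` objects.
#' @export
registry_list <- function() {
  dir <- system.file("models", package = "lungrisk")
  paths <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  specs <- lapply(paths, load_model_spec)
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs[.known_models()$name]
}

#' Ground-truth model for simulation studies
#'
#' A simple all-population logistic model on age, sex, COPD and smoking
#' status, built in code (not part of the registry).  Its risk scale
#' (mean absolute risk around 10%) is deliberately higher than any real
#' lung-cancer calculator so that simulated cohorts carry enough events
#' for tight Monte-Carlo checks of the calibration machinery.
#'
#' @return An `lr_model_spec`.
#' @export
ground_truth_spec <- function() {
  validate_model_spec(list(
    schema_version = "1.0",
    name = "GroundTruth",
    label = "synthetic ground-truth generator (not a published model)",
    source = "built in code; see package vignette",
    surrogate = TRUE,
    population = "all",
    horizon_years = 6,
    form = "logistic_direct",
    intercept = -2.4,
    terms = list(
      list(predictor = "age", coef = 0.03,
           transform = list(list(op = "subtract", value = 60))),
      list(predictor = "sex", coef = 1,
           transform = list(list(op = "map",
                                 levels = list(male = 0.3, female = 0)))),
      list(predictor = "copd", coef = 0.5, transform = list()),
      list(predictor = "smoking_status", coef = 1,
           transform = list(list(op = "map",
                                 levels = list(never = 0, former = 0.2,
                                               current = 0.4))))),
    baselines = NULL))
}
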