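#' @title Pipeline orchestration
#' @description
#' End-to-end run: obtain a cohort (file or synthetic), impute if
#' incomplete, validate every requested model per stratum, run the
#' count-matched screening comparisons, and serialize a reproducible
#' report bundle (JSON/CSV first; figures are conveniences downstream).
#' @name cli_reporting
NULL

#' Build a run configuration
#'
#' @param cohort_file CSV path, or `NULL` to generate the default
#'   synthetic cohort.
#' @param cohort_config generator config used when `cohort_file` is
#'   `NULL` (default: [default_cohort_config()]).
#' @param models model names to run, or `"all"`.
#' @param strata subset of `c("ever", "never")`.
#' @param m number of imputations when the cohort is incomplete.
#' @param seed integer master seed.
#' @param out_dir output directory, or `NULL` to skip serialization.
#' @param with_missingness inject the configured missingness into a
#'   synthetic cohort before imputation (exercises the MICE path).
#' @param censor_handling passed to [outcome_at_horizon()].
#' @return A validated `lr_run_config` list.
#' @export
run_config <- function(cohort_file = NULL, cohort_config = NULL,
                       models = "all", strata = c("ever", "never"),
                       m = 5, seed = 1L, out_dir = NULL,
                       with_missingness = TRUE,
                       censor_handling = "as_control") {
  known <- .known_models()$name
  if (identical(models, "all")) models <- known
  bad <- setdiff(models, known)
  if (length(bad)) {
    stop("config error: unknown model name(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  stopifnot(all(strata %in% c("ever", "never")), m >= 1)
  structure(list(cohort_file = cohort_file,
                 cohort_config = cohort_config,
                 models = models, strata = strata, m = as.integer(m),
                 seed = as.integer(seed), out_dir = out_dir,
                 with_missingness = isTRUE(with_missingness),
                 censor_handling = censor_handling,
                 schema_version = "1.0"),
            class = "lr_run_config")
}

#' Run the full validation pipeline
#'
#' Stages: cohort acquisition, missingness injection (synthetic only),
#' multiple imputation, per-stratum model validation, screening
#' comparison (on the first imputed dataset), radial feature summaries
#' of each model's high-risk quartile.  Ever-smoker strata run every
#' requested model; never-smoker strata run only the all-population
#' models and only the T/CPMA criterion (the smoking-based criteria
#' select nobody there).
#'
#' @param config an `lr_run_config`.
#' @return A report bundle list with elements `reports`, `comparisons`,
#'   `calibration`, `radial`, `log`; serialized under
#'   `config$out_dir` when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "lr_run_config"))
  log <- list(seed = config$seed,
              package_version = as.character(utils::packageVersion("lungrisk")),
              schema_version = config$schema_version,
              stages = list())
  stage <- function(.stage, ...) {  # dotted formal: avoid partial match
    log$stages[[.stage]] <<- list(...)
  }

  if (!is.null(config$cohort_file)) {
    cohort <- read_cohort(config$cohort_file)
    stage("read", source = config$cohort_file, n = nrow(cohort))
  } else {
    gcfg <- config$cohort_config
    if (is.null(gcfg)) gcfg <- default_cohort_config()
    cohort <- generate_cohort(gcfg, seed = config$seed)
    stage("simulate", n = nrow(cohort), seed = config$seed)
    if (config$with_missingness) {
      cohort <- inject_missingness(cohort, gcfg,
                                   seed = config$seed + 1000L)
      stage("missingness", n_missing = n_missing_subjects(cohort))
    }
  }

  if (n_missing_subjects(cohort) > 0 && config$m >= 2) {
    cohorts <- mice_impute(cohort, m = config$m,
                           seed = config$seed + 2000L)
    stage("impute", m = config$m)
  } else {
    cohorts <- list(cohort)
    stage("impute", m = 1L)
  }

  specs <- registry_list()[config$models]
  reports <- list()
  calib <- list()
  radial <- list()
  comparisons <- list()
  for (stratum in config$strata) {
    sub <- lapply(cohorts, subset_by_smoking, group = stratum)
    run_specs <- Filter(function(s) {
      stratum == "ever" || s$population == "all"
    }, specs)
    for (spec in run_specs) {
      rep <- validation_report(sub, spec, stratum = stratum,
                               censor_handling = config$censor_handling)
      key <- paste(stratum, spec$name, sep = ".")
      reports[[key]] <- rep
      cb <- rep$calibration_bins
      cb$model <- spec$name
      cb$stratum <- stratum
      calib[[key]] <- cb
      pred1 <- predict_cohort(spec, sub[[1]])
      oc1 <- outcome_at_horizon(sub[[1]], spec$horizon_years,
                                config$censor_handling)
      b1 <- calibration_bins(pred1$risk[oc1$keep], oc1$outcome[oc1$keep],
                             ids = sub[[1]]$id[oc1$keep])
      rs <- radial_feature_summary(sub[[1]],
                                   attr(b1, "high_risk_ids"))
      rs$model <- spec$name
      rs$stratum <- stratum
      radial[[key]] <- rs
    }
    crits <- if (stratum == "ever") c("tcpma", "uspstf", "nelson")
             else "tcpma"
    for (cr in crits) {
      cmp <- compare_all(sub[[1]], cr, run_specs)
      cmp$stratum <- stratum
      comparisons[[paste(stratum, cr, sep = ".")]] <- cmp
    }
    stage(paste0("stratum_", stratum), n = nrow(sub[[1]]),
          models = length(run_specs))
  }

  bundle <- list(reports = reports,
                 comparisons = do.call(rbind, c(comparisons,
                                                make.row.names = FALSE)),
                 calibration = do.call(rbind, c(calib,
                                                make.row.names = FALSE)),
                 radial = do.call(rbind, c(radial,
                                           make.row.names = FALSE)),
                 log = log)
  if (!is.null(config$out_dir)) write_report_bundle(bundle, config)
  bundle
}

#' Serialize a report bundle
#'
#' Writes `reports.json`, `comparisons.csv`, `calibration.csv`,
#' `radial.csv` and `run_log.json` under the output directory.  Output
#' is byte-identical for identical config and seed.
#'
#' @param bundle output of [run_pipeline()].
#' @param config the `lr_run_config` used.
#' @return The output directory, invisibly.
#' @export
write_report_bundle <- function(bundle, config) {
  dir <- config$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  reports <- lapply(bundle$reports, function(r) {
    r$calibration_bins <- as.data.frame(r$calibration_bins)
    attr(r$calibration_bins, "assignment") <- NULL
    attr(r$calibration_bins, "high_risk_ids") <- NULL
    unclass(r)
  })
  jsonlite::write_json(list(schema_version = config$schema_version,
                            seed = config$seed, reports = reports),
                       file.path(dir, "reports.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  utils::write.csv(bundle$comparisons,
                   file.path(dir, "comparisons.csv"), row.names = FALSE)
  utils::write.csv(bundle$calibration,
                   file.path(dir, "calibration.csv"), row.names = FALSE)
  utils::write.csv(bundle$radial, file.path(dir, "radial.csv"),
                   row.names = FALSE)
  jsonlite::write_json(bundle$log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(dir)
}
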