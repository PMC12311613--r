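#' @title Cohort container and CSV interchange
#' @description
#' A cohort is a plain `data.frame` with one row per subject carrying the
#' epidemiological predictors used by the bundled risk models plus the
#' follow-up outcome (incident lung cancer indicator and time in years).
#' The class `lr_cohort` marks a validated cohort and stores provenance
#' (source file, or generator config digest and seed) in attributes.
#' @name cohort
NULL

# Canonical column set, in file order.  Types: c = character, i = integer,
# n = numeric, l = logical.
.cohort_schema <- function() {
  c(id = "c", sex = "c", age = "i", height = "n", bmi = "n",
    education_level = "c", smoking_status = "c",
    age_started = "n", smoking_years = "n", quit_years = "n",
    cigarettes_per_day = "n", pack_years = "n", inhale_to_lungs = "l",
    secondhand_smoke_hours_per_day = "n", alcohol_days_per_week = "n",
    physical_activity_minutes_per_week = "n",
    physical_activity_sessions_per_week = "n",
    family_history_lc = "c", asbestos_exposure = "l", prior_cancer = "l",
    copd = "l", chronic_bronchitis = "l", emphysema = "l",
    interstitial_lung_disease = "l", diabetes = "l", cough = "l",
    event = "l", time = "n")
}

#' Canonical cohort columns
#'
#' @return Character vector of the canonical column names, in the order
#'   they are written to CSV.
#' @export
cohort_columns <- function() names(.cohort_schema())

# Fields that are structurally not applicable for never smokers.
smoker_only_fields <- function() {
  c("age_started", "smoking_years", "quit_years", "cigarettes_per_day",
    "pack_years", "inhale_to_lungs")
}

.level_sets <- function() {
  list(sex = c("male", "female"),
       education_level = c("middle_school_or_below", "high_school",
                           "college_or_above"),
       smoking_status = c("never", "current", "former"),
       family_history_lc = c("none", "first_degree"))
}

#' Validate a cohort data frame
#'
#' Checks the hard row invariants: unique ids, age at least 45, known
#' factor levels, smoker-only fields absent for never smokers, quit years
#' zero for current smokers and non-negative for former smokers, and
#' positive follow-up time.  The pack-year identity
#' (pack-years = cigarettes/day / 20 x smoking years) is *soft*: deviations
#' beyond 25% raise a warning, not a rejection.
#'
#' @param df data frame with the canonical columns.
#' @return Character vector of row-level problems (empty when valid).
#' @export
validate_cohort <- function(df) {
  problems <- character(0)
  note <- function(ids, msg) {
    if (length(ids)) c(problems, paste0("row id=", ids, ": ", msg))
    else problems
  }
  if (anyDuplicated(df$id)) {
    dup <- unique(df$id[duplicated(df$id)])
    problems <- note(dup, "duplicate id")
  }
  bad_age <- !is.na(df$age) & df$age < 45
  problems <- note(df$id[bad_age], "age below 45")
  for (fld in names(.level_sets())) {
    lv <- .level_sets()[[fld]]
    bad <- !is.na(df[[fld]]) & !(df[[fld]] %in% lv)
    problems <- note(df$id[bad], paste0("unknown ", fld, " level"))
  }
  never <- !is.na(df$smoking_status) & df$smoking_status == "never"
  for (fld in smoker_only_fields()) {
    bad <- never & !is.na(df[[fld]])
    problems <- note(df$id[bad],
                     paste0(fld, " present for a never smoker"))
  }
  cur <- !is.na(df$smoking_status) & df$smoking_status == "current"
  bad <- cur & !is.na(df$quit_years) & df$quit_years != 0
  problems <- note(df$id[bad], "current smoker with nonzero quit_years")
  fmr <- !is.na(df$smoking_status) & df$smoking_status == "former"
  bad <- fmr & !is.na(df$quit_years) & df$quit_years < 0
  problems <- note(df$id[bad], "negative quit_years")
  bad <- !is.na(df$time) & df$time <= 0
  problems <- note(df$id[bad], "non-positive follow-up time")
  # soft pack-year consistency
  ok3 <- !is.na(df$pack_years) & !is.na(df$cigarettes_per_day) &
    !is.na(df$smoking_years) & df$pack_years > 0
  dev <- abs(df$pack_years - df$cigarettes_per_day / 20 * df$smoking_years)
  soft <- ok3 & dev > 0.25 * df$pack_years
  if (any(soft, na.rm = TRUE)) {
    warning(sum(soft), " row(s) deviate from the pack-year identity by ",
            "more than 25% (soft check); first id: ",
            df$id[which(soft)[1]], call. = FALSE)
  }
  problems
}

#' Construct a validated cohort
#'
#' @param df data frame carrying (at least) the canonical columns.
#' @param provenance list recorded as the `provenance` attribute.
#' @return An `lr_cohort` data frame with columns in canonical order.
#' @export
as_cohort <- function(df, provenance = list()) {
  schema <- .cohort_schema()
  missing_cols <- setdiff(names(schema), names(df))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[, names(schema), drop = FALSE]
  for (col in names(schema)) {
    df[[col]] <- switch(schema[[col]],
                        c = as.character(df[[col]]),
                        i = {
                          x <- as.numeric(df[[col]])
                          frac <- !is.na(x) & x != floor(x)
                          if (any(frac)) {
                            warning("fractional ", col, " floored for ",
                                    sum(frac), " row(s)", call. = FALSE)
                          }
                          as.integer(floor(x))
                        },
                        n = as.numeric(df[[col]]),
                        l = .as_logical(df[[col]]))
  }
  problems <- validate_cohort(df)
  if (length(problems)) {
    stop("cohort validation failed:\n  ",
         paste(utils::head(problems, 20), collapse = "\n  "),
         if (length(problems) > 20) "\n  ..." else "",
         call. = FALSE)
  }
  rownames(df) <- NULL
  structure(df, class = c("lr_cohort", "data.frame"),
            provenance = provenance)
}

.as_logical <- function(x) {
  if (is.logical(x)) return(x)
  xs <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(xs))
  out[xs %in% c("true", "t", "1", "yes")] <- TRUE
  out[xs %in% c("false", "f", "0", "no")] <- FALSE
  bad <- !is.na(xs) & xs != "" & is.na(out)
  if (any(bad)) stop("non-parsable logical value: ", xs[which(bad)[1]],
                     call. = FALSE)
  out
}

#' Read a cohort from CSV
#'
#' RFC-4180 CSV, UTF-8, one row per subject.  Empty cells, `NA` and the
#' em-dash (as used in published tables for not-applicable cells) are read
#' as missing.  External header names can be adapted via a column map
#' (named vector `external -> canonical` or a two-column CSV file with
#' headers `external,canonical`), so cohorts with different headers can be
#' used without code changes.
#'
#' @param path CSV file path.
#' @param na_strings tokens interpreted as missing.
#' @param column_map optional named character vector or path to a mapping
#'   file; names (or the `external` column) are the file's headers.
#' @return A validated [as_cohort()] object.
#' @export
read_cohort <- function(path, na_strings = c("", "—", "NA"),
                        column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character",
                        na.strings = na_strings, check.names = FALSE,
                        fileEncoding = "UTF-8")
  if (!is.null(column_map)) {
    if (is.character(column_map) && length(column_map) == 1 &&
        file.exists(column_map)) {
      m <- utils::read.csv(column_map, colClasses = "character")
      column_map <- stats::setNames(m$canonical, m$external)
    }
    hit <- names(df) %in% names(column_map)
    names(df)[hit] <- unname(column_map[names(df)[hit]])
  }
  as_cohort(df, provenance = list(source = path))
}

#' Write a cohort to CSV
#'
#' Missing values are written as empty cells (configurable sentinel), so
#' `read_cohort(write_cohort(x))` round-trips exactly.
#'
#' @param cohort validated cohort.
#' @param path output file path.
#' @param na sentinel written for missing cells.
#' @export
write_cohort <- function(cohort, path, na = "") {
  stopifnot(inherits(cohort, "lr_cohort"))
  df <- as.data.frame(cohort)
  for (col in names(df)) {
    if (is.logical(df[[col]])) {
      df[[col]] <- ifelse(is.na(df[[col]]), NA,
                          ifelse(df[[col]], "TRUE", "FALSE"))
    }
  }
  utils::write.csv(df, path, row.names = FALSE, na = na,
                   fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

#' Subset a cohort by smoking group
#'
#' `ever` selects current plus former smokers; `never` selects never
#' smokers.  The two groups partition the cohort.
#'
#' @param cohort validated cohort.
#' @param group `"ever"` or `"never"`.
#' @return The subset as an `lr_cohort`.
#' @export
subset_by_smoking <- function(cohort, group = c("ever", "never")) {
  group <- match.arg(group)
  keep <- if (group == "ever") {
    cohort$smoking_status %in% c("current", "former")
  } else {
    cohort$smoking_status == "never"
  }
  keep[is.na(keep)] <- FALSE
  out <- as.data.frame(cohort)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("lr_cohort", "data.frame"),
            provenance = c(attr(cohort, "provenance"),
                           list(subset = group)))
}

#' Count subjects with missing data
#'
#' A subject counts as having missing data when at least one *applicable*
#' field is `NA`; smoker-only fields are not applicable for never smokers
#' and do not count.
#'
#' @param cohort validated cohort.
#' @param fields fields to inspect (default: all predictor fields).
#' @return Integer count of subjects.
#' @export
n_missing_subjects <- function(cohort, fields = NULL) {
  if (is.null(fields)) {
    fields <- setdiff(cohort_columns(), c("id", "event", "time"))
  }
  never <- cohort$smoking_status == "never"
  any_na <- rep(FALSE, nrow(cohort))
  for (fld in fields) {
    na_here <- is.na(cohort[[fld]])
    if (fld %in% smoker_only_fields()) na_here <- na_here & !never
    any_na <- any_na | na_here
  }
  sum(any_na)
}

#' @export
print.lr_cohort <- function(x, ...) {
  cat("<lr_cohort> ", nrow(x), " subjects; ",
      sum(x$event, na.rm = TRUE), " events\n", sep = "")
  prov <- attr(x, "provenance")
  if (length(prov)) {
    cat("provenance:",
        paste(names(prov), vapply(prov, function(p)
          paste(format(p), collapse = " "), ""),
          sep = "=", collapse = "; "), "\n")
  }
  invisible(x)
}
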