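#' @title Screening eligibility criteria
#' @description
#' Boolean eligibility rules for three low-dose CT screening programmes,
#' with boundary inclusivity following each criterion's printed symbols
#' exactly.  All three are pure functions of the subject record.
#'
#' * USPSTF-2021: age 50-80, current or former smokers who quit at most
#'   15 years ago, at least 20 pack-years.
#' * NELSON: age 50-74, current or former smokers who quit at most 10
#'   years ago, and either more than 15 cigarettes/day for more than 25
#'   years or more than 10 cigarettes/day for more than 30 years
#'   (strict inequalities).
#' * T/CPMA 013-2020: age 50-74 (clause a, mandatory) and at least one
#'   of: (b) at least 30 pack-years in current smokers or former smokers
#'   who quit less than 15 years ago; (c) long-term passive smoking;
#'   (d) COPD history; (e) occupational carcinogen exposure (asbestos);
#'   (f) first-degree relative with lung cancer.
#'
#' The source cohort records daily secondhand-smoke hours rather than
#' passive-smoking years, so clause (c) is operationalized through a
#' configurable proxy threshold on hours per day (default: at least 1
#' hour/day); clause (e) is narrowed to the asbestos-exposure field, the
#' only occupational-exposure variable available.
#' @name screening_criteria
NULL

.need <- function(df, fields, criteria) {
  for (fld in fields) {
    if (anyNA(df[[fld]])) {
      bad <- df$id[which(is.na(df[[fld]]))[1]]
      stop("eligibility error (", criteria, "): missing ", fld,
           " (first id: ", bad, ")", call. = FALSE)
    }
  }
}

.smoker_fields_ok <- function(df, fields, criteria) {
  # smoker-only fields must be present for smokers; never smokers are
  # decided by status alone
  smoker <- df$smoking_status %in% c("current", "former")
  for (fld in fields) {
    bad <- smoker & is.na(df[[fld]])
    if (any(bad)) {
      stop("eligibility error (", criteria, "): missing ", fld,
           " for a smoker (first id: ", df$id[which(bad)[1]], ")",
           call. = FALSE)
    }
  }
}

.elig_frame <- function(df, criteria, eligible, clauses) {
  data.frame(id = df$id, criteria = criteria, eligible = eligible,
             triggered_clauses = clauses, stringsAsFactors = FALSE)
}

#' USPSTF-2021 eligibility
#'
#' @param cohort validated cohort (or any data frame with the required
#'   fields).
#' @return Data frame with `id`, `criteria`, `eligible`,
#'   `triggered_clauses`.
#' @export
eligible_uspstf <- function(cohort) {
  df <- as.data.frame(cohort)
  .need(df, c("age", "smoking_status"), "USPSTF-2021")
  .smoker_fields_ok(df, c("pack_years", "quit_years"), "USPSTF-2021")
  smoker <- df$smoking_status %in% c("current", "former")
  age_ok <- df$age >= 50 & df$age <= 80
  quit_ok <- smoker & (df$smoking_status == "current" | df$quit_years <= 15)
  py_ok <- smoker & df$pack_years >= 20
  eligible <- age_ok & quit_ok & py_ok
  clauses <- ifelse(eligible, "age;quit;pack_years", "")
  .elig_frame(df, "USPSTF-2021", eligible, clauses)
}

#' NELSON eligibility
#'
#' @inheritParams eligible_uspstf
#' @return Data frame as in [eligible_uspstf()].
#' @export
eligible_nelson <- function(cohort) {
  df <- as.data.frame(cohort)
  .need(df, c("age", "smoking_status"), "NELSON")
  .smoker_fields_ok(df, c("cigarettes_per_day", "smoking_years",
                          "quit_years"), "NELSON")
  smoker <- df$smoking_status %in% c("current", "former")
  age_ok <- df$age >= 50 & df$age <= 74
  quit_ok <- smoker & (df$smoking_status == "current" | df$quit_years <= 10)
  int1 <- smoker & df$cigarettes_per_day > 15 & df$smoking_years > 25
  int2 <- smoker & df$cigarettes_per_day > 10 & df$smoking_years > 30
  eligible <- age_ok & quit_ok & (int1 | int2)
  clauses <- paste0(ifelse(eligible & int1, "intensity1;", ""),
                    ifelse(eligible & int2, "intensity2;", ""))
  .elig_frame(df, "NELSON", eligible, sub(";$", "", clauses))
}

#' T/CPMA 013-2020 eligibility
#'
#' Clause (a) (age 50-74) is a mandatory gate; eligibility additionally
#' requires at least one of clauses (b)-(f).  `triggered_clauses`
#' records every satisfied clause label.
#'
#' @inheritParams eligible_uspstf
#' @param passive_smoke_threshold hours/day of secondhand-smoke exposure
#'   treated as long-term passive smoking (clause c proxy).
#' @return Data frame as in [eligible_uspstf()].
#' @export
eligible_tcpma <- function(cohort, passive_smoke_threshold = 1) {
  df <- as.data.frame(cohort)
  .need(df, c("age", "smoking_status", "copd", "asbestos_exposure",
              "family_history_lc", "secondhand_smoke_hours_per_day"),
        "T/CPMA 013-2020")
  .smoker_fields_ok(df, c("pack_years", "quit_years"), "T/CPMA 013-2020")
  smoker <- df$smoking_status %in% c("current", "former")
  a <- df$age >= 50 & df$age <= 74
  b <- smoker & df$pack_years >= 30 &
    (df$smoking_status == "current" | df$quit_years < 15)
  cc <- df$secondhand_smoke_hours_per_day >= passive_smoke_threshold
  d <- df$copd
  e <- df$asbestos_exposure
  f <- df$family_history_lc == "first_degree"
  b[is.na(b)] <- FALSE
  eligible <- a & (b | cc | d | e | f)
  mk <- function(flag, lab) ifelse(flag, paste0(lab, ";"), "")
  clauses <- paste0(mk(a, "a"), mk(b, "b"), mk(cc, "c"), mk(d, "d"),
                    mk(e, "e"), mk(f, "f"))
  .elig_frame(df, "T/CPMA 013-2020", eligible, sub(";$", "", clauses))
}

#' Apply a named screening criterion
#'
#' @param cohort validated cohort.
#' @param name one of `"tcpma"`, `"uspstf"`, `"nelson"`.
#' @param ... passed to the criterion function.
#' @return Data frame as in [eligible_uspstf()].
#' @export
apply_criteria <- function(cohort, name = c("tcpma", "uspstf", "nelson"),
                           ...) {
  name <- match.arg(name)
  switch(name,
         tcpma = eligible_tcpma(cohort, ...),
         uspstf = eligible_uspstf(cohort, ...),
         nelson = eligible_nelson(cohort, ...))
}
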