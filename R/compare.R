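#' @title Count-matched screening comparison
#' @description
#' Compares each risk model against a screening criterion by setting the
#' model's risk threshold so that it selects exactly as many subjects as
#' the criterion, then tabulating sensitivity, specificity and cases
#' detected at each horizon.
#' @name screening_comparison
NULL

#' Outcome indicator at a horizon
#'
#' A subject is a case at horizon `t` when the event occurred at or
#' before `t`.  Subjects censored before `t` without an event are
#' treated as controls by default; `censor_handling = "exclude"` flags
#' them for exclusion instead.
#'
#' @param cohort validated cohort.
#' @param t horizon in years.
#' @param censor_handling `"as_control"` (default) or `"exclude"`.
#' @return List with logical `outcome` and logical `keep` (all `TRUE`
#'   under `"as_control"`).
#' @export
outcome_at_horizon <- function(cohort, t,
                               censor_handling = c("as_control",
                                                   "exclude")) {
  censor_handling <- match.arg(censor_handling)
  outcome <- cohort$event & cohort$time <= t
  keep <- if (censor_handling == "exclude") {
    outcome | cohort$time > t
  } else rep(TRUE, nrow(cohort))
  list(outcome = outcome, keep = keep)
}

#' Match a selection count with a risk threshold
#'
#' The threshold is the `n_target`-th largest risk; subjects with risk
#' at or above the threshold are selected.  When ties at the threshold
#' overshoot `n_target`, the excess tied subjects are dropped by
#' ascending id, so exactly `n_target` subjects are selected.
#'
#' @param risks numeric risk vector.
#' @param n_target number of subjects to select (1..length(risks)).
#' @param ids subject ids (default: positional).
#' @return List with `threshold` and `selected` (ids).
#' @export
match_threshold <- function(risks, n_target, ids = NULL) {
  n <- length(risks)
  if (n_target < 1 || n_target > n) {
    stop("error: n_target out of range", call. = FALSE)
  }
  if (is.null(ids)) ids <- as.character(seq_len(n))
  thr <- sort(risks, decreasing = TRUE)[n_target]
  above <- risks > thr
  tied <- risks == thr
  need <- n_target - sum(above)
  tied_ids <- sort(ids[tied])  # drop excess ties by ascending id
  keep_tied <- tied_ids[seq_len(need)]
  selected <- c(ids[above], keep_tied)
  list(threshold = thr, selected = selected)
}

#' Confusion-matrix metrics for a screening selection
#'
#' TP are selected cases, FN unselected cases, FP selected non-cases,
#' TN unselected non-cases; sensitivity = TP / (TP + FN),
#' specificity = TN / (TN + FP).
#'
#' @param selected ids of the selected subjects.
#' @param ids all subject ids.
#' @param outcomes logical case indicators aligned with `ids`.
#' @return List with `tp`, `fn`, `fp`, `tn`, `sensitivity`,
#'   `specificity`.
#' @export
confusion_metrics <- function(selected, ids, outcomes) {
  stopifnot(all(selected %in% ids))
  if (!any(outcomes)) {
    stop("undefined error: no cases, sensitivity undefined",
         call. = FALSE)
  }
  sel <- ids %in% selected
  tp <- sum(sel & outcomes)
  fn <- sum(!sel & outcomes)
  fp <- sum(sel & !outcomes)
  tn <- sum(!sel & !outcomes)
  list(tp = tp, fn = fn, fp = fp, tn = tn,
       sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
}

#' Compare models against a screening criterion at matched counts
#'
#' For each model: the criterion's selection count becomes the model's
#' target, the threshold is matched exactly, and sensitivity,
#' specificity (at the model's native horizon) and cases selected at
#' every standard horizon are tabulated.  The first output row describes
#' the criterion itself.
#'
#' @param cohort validated, complete cohort (one smoking group).
#' @param criteria `"tcpma"`, `"uspstf"` or `"nelson"`.
#' @param specs list of `lr_model_spec` objects applicable to the
#'   cohort's population.
#' @param horizons horizons at which case counts are reported.
#' @return Data frame with one row per screening method.
#' @export
compare_all <- function(cohort, criteria, specs,
                        horizons = c(5, 6, 6.6, 8.7, 10)) {
  elig <- apply_criteria(cohort, criteria)
  n_target <- sum(elig$eligible)
  if (n_target == 0) {
    stop("comparison error: criterion selects no subjects", call. = FALSE)
  }
  hcols <- paste0("cases_", horizons, "y")
  case_counts <- function(selected) {
    sel <- cohort$id %in% selected
    vapply(horizons, function(t) {
      sum(outcome_at_horizon(cohort, t)$outcome & sel)
    }, 0)
  }
  crit_row <- data.frame(method = elig$criteria[1], model = NA_character_,
                         threshold = NA_real_, n_selected = n_target,
                         sensitivity = NA_real_, specificity = NA_real_,
                         stringsAsFactors = FALSE)
  crit_row[hcols] <- as.list(case_counts(elig$id[elig$eligible]))
  rows <- list(crit_row)
  for (spec in specs) {
    pred <- predict_cohort(spec, cohort)
    mt <- match_threshold(pred$risk, n_target, ids = pred$id)
    oc <- outcome_at_horizon(cohort, spec$horizon_years)$outcome
    cm <- confusion_metrics(mt$selected, cohort$id, oc)
    row <- data.frame(method = elig$criteria[1], model = spec$name,
                      threshold = mt$threshold,
                      n_selected = length(mt$selected),
                      sensitivity = cm$sensitivity,
                      specificity = cm$specificity,
                      stringsAsFactors = FALSE)
    counts <- case_counts(mt$selected)
    # a model reports cases at its native horizon only, as published
    native <- abs(horizons - spec$horizon_years) < 1e-9
    counts[!native] <- NA
    row[hcols] <- as.list(counts)
    rows[[length(rows) + 1]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
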