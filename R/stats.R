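#' @title Discrimination and calibration statistics
#' @name validation_stats
NULL

.check_auc_input <- function(scores, outcomes) {
  stopifnot(length(scores) == length(outcomes))
  outcomes <- as.logical(outcomes)
  if (anyNA(scores) || anyNA(outcomes)) {
    stop("undefined error: NA in scores or outcomes", call. = FALSE)
  }
  if (!any(outcomes) || all(outcomes)) {
    stop("undefined error: AUC needs at least one case and one control",
         call. = FALSE)
  }
  outcomes
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random case outscores
#' a random control, ties counted one half.  Computed from midranks.
#'
#' @param scores numeric risk scores.
#' @param outcomes logical case indicators.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, outcomes) {
  outcomes <- .check_auc_input(scores, outcomes)
  m <- sum(outcomes)
  n <- sum(!outcomes)
  r <- rank(scores, ties.method = "average")
  (sum(r[outcomes]) - m * (m + 1) / 2) / (m * n)
}

#' DeLong confidence interval for the AUC
#'
#' Variance from the case and control placement values (the DeLong
#' structural components), normal interval clipped to `[0, 1]`.
#'
#' @inheritParams auc
#' @param level confidence level.
#' @return List with `auc`, `var`, `lo`, `hi`.
#' @export
auc_ci <- function(scores, outcomes, level = 0.95) {
  outcomes <- .check_auc_input(scores, outcomes)
  m <- sum(outcomes)
  n <- sum(!outcomes)
  r_all <- rank(scores, ties.method = "average")
  r_case <- rank(scores[outcomes], ties.method = "average")
  r_ctrl <- rank(scores[!outcomes], ties.method = "average")
  # placements: fraction of the other group each observation beats
  v10 <- (r_all[outcomes] - r_case) / n
  v01 <- 1 - (r_all[!outcomes] - r_ctrl) / m
  a <- (sum(r_all[outcomes]) - m * (m + 1) / 2) / (m * n)
  v <- stats::var(v10) / m + stats::var(v01) / n
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(auc = a, var = v,
       lo = max(0, a - z * sqrt(v)),
       hi = min(1, a + z * sqrt(v)))
}

#' Expected/observed calibration ratio
#'
#' E is the sum of predicted risks, O the observed case count within the
#' horizon; the ratio E/O is below 1 when the model underestimates risk.
#' The interval uses the Poisson approximation on O:
#' ratio x exp(-+ z / sqrt(O)).
#'
#' @param predicted predicted absolute risks.
#' @param outcomes logical case indicators within the horizon.
#' @param level confidence level.
#' @return List with `expected`, `observed`, `ratio`, `lo`, `hi`.
#' @export
eo_ratio <- function(predicted, outcomes, level = 0.95) {
  stopifnot(length(predicted) == length(outcomes))
  o <- sum(as.logical(outcomes))
  if (o == 0) {
    stop("undefined error: no observed cases, E/O undefined",
         call. = FALSE)
  }
  e <- sum(predicted)
  ratio <- e / o
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(expected = e, observed = o, ratio = ratio,
       lo = ratio * exp(-z / sqrt(o)), hi = ratio * exp(z / sqrt(o)))
}

#' Risk-quartile calibration bins
#'
#' Ranks subjects by predicted risk ascending (stable sort: tied risks
#' keep input order) and splits them into four groups of approximately
#' equal size; when n is not divisible by 4, the remainder goes to the
#' lowest-risk bins.  The fourth bin is the high-risk group.
#'
#' @param predicted predicted absolute risks.
#' @param outcomes logical case indicators.
#' @param ids optional subject ids carried into the output.
#' @return Data frame with one row per bin: `bin`, `n`, `mean_predicted`,
#'   `observed_proportion`, `cases`; attribute `assignment` maps each
#'   input position to its bin.
#' @export
calibration_bins <- function(predicted, outcomes, ids = NULL) {
  n <- length(predicted)
  if (n < 4) stop("calibration error: need at least 4 subjects",
                  call. = FALSE)
  outcomes <- as.logical(outcomes)
  ord <- order(predicted)  # stable for ties
  sizes <- rep(n %/% 4, 4)
  r <- n %% 4
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1
  bin_sorted <- rep(1:4, times = sizes)
  bin <- integer(n)
  bin[ord] <- bin_sorted
  out <- data.frame(
    bin = 1:4,
    n = sizes,
    mean_predicted = vapply(1:4, function(b) mean(predicted[bin == b]), 0),
    observed_proportion = vapply(1:4, function(b) mean(outcomes[bin == b]), 0),
    cases = vapply(1:4, function(b) sum(outcomes[bin == b]), 0))
  attr(out, "assignment") <- bin
  if (!is.null(ids)) attr(out, "high_risk_ids") <- ids[bin == 4]
  out
}

# Table-style groupings of continuous features for the radial summary.
.radial_bins <- function() {
  list(
    age = list(breaks = c(50, 55, 60, 65, 70, 75, 80, 85, 90),
               labels = c("45-49", "50-54", "55-59", "60-64", "65-69",
                          "70-74", "75-79", "80-84", "85-89", "90+")),
    bmi = list(breaks = c(18.5, 24),
               labels = c("<18.5", "18.5-23.9", ">=24")),
    smoking_years = list(breaks = c(10, 20, 30, 40, 50, 60),
                         labels = c("<10", "10-19", "20-29", "30-39",
                                    "40-49", "50-59", ">=60")),
    pack_years = list(breaks = c(20, 40, 60),
                      labels = c("<20", "20-39", "40-59", ">=60")),
    cigarettes_per_day = list(breaks = c(10, 15, 20, 25, 30, 35),
                              labels = c("<10", "10-14", "15-19",
                                         "20-24", "25-29", "30-34",
                                         ">=35")))
}

#' Feature percentages of a high-risk group
#'
#' For each requested feature, the percentage of the high-risk group in
#' each category (continuous features binned with the published table
#' groupings).  Feeds the radial percentage histograms.
#'
#' @param cohort validated cohort.
#' @param high_risk_ids ids of the high-risk group (subset of the
#'   cohort's ids).
#' @param features character vector of cohort fields; defaults to the
#'   features shared by at least three bundled models.
#' @return Data frame with `feature`, `category`, `count`, `percent`.
#' @export
radial_feature_summary <- function(cohort, high_risk_ids,
                                   features = c("sex", "age", "bmi",
                                                "education_level",
                                                "prior_cancer",
                                                "emphysema", "copd",
                                                "family_history_lc",
                                                "smoking_status",
                                                "smoking_years",
                                                "pack_years",
                                                "cigarettes_per_day")) {
  if (length(high_risk_ids) == 0) {
    stop("error: empty high-risk set", call. = FALSE)
  }
  if (!all(high_risk_ids %in% cohort$id)) {
    stop("error: high-risk ids not all present in the cohort",
         call. = FALSE)
  }
  df <- as.data.frame(cohort)[match(high_risk_ids, cohort$id), ,
                              drop = FALSE]
  bins <- .radial_bins()
  rows <- list()
  for (f in features) {
    x <- df[[f]]
    if (is.logical(x)) {
      x <- ifelse(x, "yes", "no")
    } else if (is.numeric(x) && !is.null(bins[[f]])) {
      b <- bins[[f]]
      x <- b$labels[findInterval(x, b$breaks) + 1L]
    } else {
      x <- as.character(x)
    }
    tab <- table(x, useNA = "no")
    if (length(tab) == 0) next  # feature not applicable in this stratum
    rows[[f]] <- data.frame(feature = f, category = names(tab),
                            count = as.integer(tab),
                            percent = 100 * as.integer(tab) / sum(tab),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
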