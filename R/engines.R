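#' @title Risk engines
#' @description
#' Evaluates a model specification on subjects to produce an absolute
#' risk over the model's horizon, through one of four mathematical
#' forms: direct logistic risk, Cox baseline-survival risk
#' 1 - S0(t)^exp(lp), case-control relative risk applied to an age-sex
#' baseline incidence on the odds scale, and an annual recursion over
#' lung-cancer and competing-mortality hazards.
#' @name risk_engines
NULL

# Apply one term's transformation pipeline to a vector.
.apply_transform <- function(x, transform, predictor) {
  for (step in transform) {
    x <- switch(step$op,
      add = x + step$value,
      subtract = x - step$value,
      multiply = x * step$value,
      divide = x / step$value,
      power = x^step$value,
      log = log(x + if (is.null(step$offset)) 0 else step$offset),
      truncate = pmin(pmax(x, if (is.null(step$lo)) -Inf else step$lo),
                      if (is.null(step$hi)) Inf else step$hi),
      map = {
        lv <- step$levels
        out <- unlist(lv)[as.character(x)]
        if (anyNA(out[!is.na(x)])) {
          stop("evaluation error: unmapped level of ", predictor,
               call. = FALSE)
        }
        as.numeric(out)
      },
      indicator = as.numeric(as.character(x) == step$level),
      bin = {
        breaks <- unlist(step$breaks)
        vals <- unlist(step$values)
        idx <- findInterval(as.numeric(x), breaks) + 1L
        vals[idx]
      },
      stop("spec error: unknown transform op '", step$op, "'",
           call. = FALSE))
  }
  x
}

# Vectorized linear predictor for a whole data frame of subjects.
.lp_vec <- function(spec, df) {
  n <- nrow(df)
  lp <- rep(if (is.null(spec$intercept)) 0 else spec$intercept, n)
  never <- !is.na(df$smoking_status) & df$smoking_status == "never"
  for (term in spec$terms) {
    x <- df[[term$predictor]]
    if (is.logical(x)) x <- as.numeric(x)
    contrib <- rep(0, n)
    active <- rep(TRUE, n)
    if (isTRUE(term$smoker_only)) active <- !never
    if (any(active)) {
      xa <- .apply_transform(x[active], term$transform, term$predictor)
      if (anyNA(xa)) {
        bad <- df$id[active][which(is.na(xa))[1]]
        stop("evaluation error: missing predictor '", term$predictor,
             "' (first id: ", bad, ")", call. = FALSE)
      }
      contrib[active] <- term$coef * as.numeric(xa)
    }
    lp <- lp + contrib
  }
  lp
}

#' Evaluate a model's linear predictor for one subject
#'
#' intercept + sum of coefficient x transformed predictor, with each
#' term's transformation pipeline applied in order.
#'
#' @param spec an `lr_model_spec`.
#' @param subject one-row data frame (or list) of predictor values.
#' @return Numeric scalar.
#' @export
evaluate_linear_predictor <- function(spec, subject) {
  df <- as.data.frame(subject, stringsAsFactors = FALSE)
  if (is.null(df$id)) df$id <- "<subject>"
  .check_population(spec, df)
  .lp_vec(spec, df)
}

.check_population <- function(spec, df) {
  if (spec$population == "ever_only" &&
      any(df$smoking_status == "never", na.rm = TRUE)) {
    stop("population error: model ", spec$name,
         " applies to ever smokers only", call. = FALSE)
  }
  invisible(TRUE)
}

#' Logistic risk
#'
#' @param lp linear predictor.
#' @return 1 / (1 + exp(-lp)).
#' @export
risk_logistic <- function(lp) stats::plogis(lp)

#' Cox baseline-survival risk
#'
#' @param lp linear predictor (centered as the spec prescribes).
#' @param s0 baseline survival at the horizon, in (0, 1].
#' @return 1 - s0^exp(lp).
#' @export
risk_cox <- function(lp, s0) {
  if (any(s0 <= 0 | s0 > 1)) {
    stop("spec error: baseline survival must be in (0, 1]", call. = FALSE)
  }
  1 - s0^exp(lp)
}

#' Relative risk applied to a baseline incidence
#'
#' Converts the baseline absolute risk to odds, multiplies by the
#' relative (odds) ratio, and converts back; capped at 1.
#'
#' @param rr relative (odds) ratio, non-negative.
#' @param baseline_risk baseline absolute risk in `[0, 1)`.
#' @return Absolute risk.
#' @export
risk_rr_incidence <- function(rr, baseline_risk) {
  if (any(rr < 0)) stop("spec error: negative relative risk", call. = FALSE)
  if (any(baseline_risk < 0 | baseline_risk >= 1)) {
    stop("spec error: baseline risk must be in [0, 1)", call. = FALSE)
  }
  odds <- baseline_risk / (1 - baseline_risk) * rr
  pmin(odds / (1 + odds), 1)
}

#' Annual recursion over competing hazards
#'
#' Cumulative probability of a lung-cancer event by the horizon when a
#' subject faces, each year, a lung-cancer hazard and a competing
#' mortality hazard:
#' sum over k of (product over j < k of (1 - h_lc(j)) (1 - h_m(j)))
#' times h_lc(k).  A fractional final year contributes its pro-rata
#' hazard fraction.
#'
#' @param annual_lc_hazard per-year lung-cancer hazards (length at least
#'   `ceiling(horizon)`).
#' @param annual_mort_hazard per-year competing mortality hazards.
#' @param horizon positive horizon in years.
#' @return Probability in `[0, 1]`.
#' @export
risk_annual_recursion <- function(annual_lc_hazard, annual_mort_hazard,
                                  horizon) {
  if (any(annual_lc_hazard < 0 | annual_lc_hazard > 1) ||
      any(annual_mort_hazard < 0 | annual_mort_hazard > 1)) {
    stop("spec error: hazards must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(horizon > 0)
  full <- floor(horizon + 1e-9)
  frac <- horizon - full
  need <- full + (frac > 1e-9)
  if (length(annual_lc_hazard) < need ||
      length(annual_mort_hazard) < need) {
    stop("spec error: hazard tables shorter than the horizon",
         call. = FALSE)
  }
  alive <- 1
  risk <- 0
  for (k in seq_len(full)) {
    risk <- risk + alive * annual_lc_hazard[k]
    alive <- alive * (1 - annual_lc_hazard[k]) * (1 - annual_mort_hazard[k])
  }
  if (frac > 1e-9) {
    risk <- risk + alive * frac * annual_lc_hazard[full + 1]
  }
  risk
}

# Age-sex rate lookup.  `table` is a list of rows with sex ("male",
# "female" or "any"), age_lo, age_hi and a value column; ages outside
# the table are clamped to the nearest band.
.lookup_rate <- function(table, value_col, sex, age) {
  tab <- do.call(rbind, lapply(table, function(r) {
    data.frame(sex = r$sex, age_lo = r$age_lo, age_hi = r$age_hi,
               value = r[[value_col]], stringsAsFactors = FALSE)
  }))
  out <- rep(NA_real_, length(age))
  for (s in unique(tab$sex)) {
    rows <- tab[tab$sex == s, , drop = FALSE]
    rows <- rows[order(rows$age_lo), , drop = FALSE]
    sel <- if (s == "any") rep(TRUE, length(sex)) else sex == s
    if (!any(sel)) next
    a <- pmin(pmax(age[sel], min(rows$age_lo)), max(rows$age_hi))
    idx <- findInterval(a, rows$age_lo)
    out[sel] <- rows$value[idx]
  }
  if (anyNA(out)) {
    stop("spec error: baseline table does not cover all subjects",
         call. = FALSE)
  }
  out
}

# Recursion form over a cohort: per-year lung-cancer hazard is the
# age-sex baseline hazard at the attained age scaled by exp(lp).
.recursion_cohort <- function(spec, df, lp) {
  h <- spec$horizon_years
  full <- floor(h + 1e-9)
  frac <- h - full
  years <- full + (frac > 1e-9)
  n <- nrow(df)
  alive <- rep(1, n)
  risk <- rep(0, n)
  rel <- exp(lp)
  for (k in seq_len(years)) {
    attained <- df$age + k - 1
    h0 <- .lookup_rate(spec$baselines$lc_hazard, "hazard", df$sex, attained)
    hm <- .lookup_rate(spec$baselines$mortality_hazard, "hazard",
                       df$sex, attained)
    hlc <- pmin(h0 * rel, 1)
    w <- if (k <= full) 1 else frac
    risk <- risk + alive * w * hlc
    if (k <= full) alive <- alive * (1 - hlc) * (1 - hm)
  }
  risk
}

#' Predict absolute risk for a whole cohort
#'
#' Routes to the model's form and returns one row per subject.
#'
#' @param spec an `lr_model_spec`.
#' @param cohort validated cohort (must match the model's population).
#' @return Data frame with columns `id`, `model`, `horizon`, `risk`,
#'   `linear_predictor`.
#' @export
predict_cohort <- function(spec, cohort) {
  df <- as.data.frame(cohort)
  .check_population(spec, df)
  lp <- .lp_vec(spec, df)
  risk <- switch(spec$form,
    logistic_direct = risk_logistic(lp),
    cox_baseline = risk_cox(lp, spec$baselines$s0),
    rr_times_incidence = {
      base <- .lookup_rate(spec$baselines$incidence, "risk", df$sex, df$age)
      risk_rr_incidence(exp(lp), base)
    },
    annual_recursion = .recursion_cohort(spec, df, lp))
  data.frame(id = df$id, model = spec$name,
             horizon = spec$horizon_years, risk = risk,
             linear_predictor = lp, stringsAsFactors = FALSE)
}

#' Predict absolute risk for one subject
#'
#' @param spec an `lr_model_spec`.
#' @param subject one-row data frame (or list) of predictor values.
#' @return One-row data frame as in [predict_cohort()].
#' @export
predict_risk <- function(spec, subject) {
  df <- as.data.frame(subject, stringsAsFactors = FALSE)
  if (is.null(df$id)) df$id <- "<subject>"
  predict_cohort(spec, df)
}
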