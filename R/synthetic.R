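#' @title Synthetic cohort generator
#' @description
#' Generates cohorts whose categorical marginals match a configuration
#' exactly (deterministic allocation of category labels followed by a
#' seeded shuffle of the joint assignment), with continuous variables
#' drawn from truncated normals restricted to each subject's assigned
#' category bin, pack-years derived from the intensity-duration identity
#' and rescaled so the stratum mean matches the configured mean, and case
#' event times placed to reproduce the configured cumulative event
#' schedule exactly.
#' @name synthetic_cohort
NULL

# Inverse-CDF truncated normal draw; `lo`/`hi` may be vectors.
# Degenerate intervals (both bounds in an extreme tail) collapse to the
# interval midpoint.
.rtnorm <- function(n, mean, sd, lo, hi) {
  if (n == 0) return(numeric(0))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  x <- stats::qnorm(plo + stats::runif(n) * pmax(phi - plo, 0), mean, sd)
  deg <- (phi - plo) < 1e-12 | !is.finite(x)
  if (any(deg)) {
    mid <- (rep_len(lo, n) + rep_len(hi, n)) / 2
    x[deg] <- mid[deg]
  }
  x
}

# Bin boundary lookup: half-open [lo, hi) intervals per category label.
.bins <- list(
  age_group = rbind("45-49" = c(45, 50), "50-54" = c(50, 55),
                    "55-59" = c(55, 60), "60-64" = c(60, 65),
                    "65-69" = c(65, 70), "70-74" = c(70, 75),
                    "75-79" = c(75, 80), "80-84" = c(80, 85),
                    "85-89" = c(85, 90), "90+" = c(90, 96)),
  bmi_group = rbind("<18.5" = c(13, 18.5), "18.5-23.9" = c(18.5, 24),
                    ">=24" = c(24, 50)),
  height_group = rbind("<150" = c(138, 150), "150-154" = c(150, 155),
                       "155-159" = c(155, 160), ">=160" = c(160, 186)),
  smoking_years_group = rbind("<10" = c(1, 10), "10-19" = c(10, 20),
                              "20-29" = c(20, 30), "30-39" = c(30, 40),
                              "40-49" = c(40, 50), "50-59" = c(50, 60),
                              ">=60" = c(60, 70)),
  cpd_group = rbind("<10" = c(1, 10), "10-14" = c(10, 15),
                    "15-19" = c(15, 20), "20-24" = c(20, 25),
                    "25-29" = c(25, 30), "30-34" = c(30, 35),
                    ">=35" = c(35, 80)))

# Shuffled vector of category labels matching `counts` exactly.
.alloc <- function(counts) {
  sample(rep(names(counts), times = counts))
}

# Draw a binned continuous variable: truncated normal within each
# subject's assigned bin, optional integer flooring.
.draw_binned <- function(labels, binset, mean, sd, integer = FALSE,
                         cap = NULL) {
  lo <- binset[labels, 1]
  hi <- binset[labels, 2]
  if (!is.null(cap)) hi <- pmin(hi, cap)
  x <- .rtnorm(length(labels), mean, sd, lo, pmax(hi, lo + 1e-6))
  x <- pmin(pmax(x, lo), hi - 1e-9)
  if (integer) floor(x) else round(x, 4)
}

.yes <- function(labels) labels == "yes"

# Repair infeasible smoking-years-group assignments by swapping labels
# between subjects (preserves marginal counts exactly).  `cap` is the
# per-subject upper bound on smoking years.
.repair_sy_groups <- function(labels, cap, binset) {
  lo <- binset[labels, 1]
  bad <- which(lo > cap)
  for (i in bad) {
    lo_i <- binset[labels[i], 1]
    if (lo_i <= cap[i]) next  # fixed by an earlier swap
    cand <- which(binset[labels, 1] <= cap[i] & lo_i <= cap)
    cand <- setdiff(cand, i)
    if (!length(cand)) {
      stop("generator error: no feasible smoking-years assignment",
           call. = FALSE)
    }
    j <- cand[1]
    tmp <- labels[i]; labels[i] <- labels[j]; labels[j] <- tmp
  }
  labels
}

# Generate one stratum as a data frame of predictors (no follow-up yet).
.generate_stratum <- function(cfg, st) {
  n <- cfg$strata[[st]]$n
  smoking <- cfg$strata[[st]]$smoking
  cat <- lapply(cfg$cat, `[[`, st)
  cont <- lapply(cfg$cont, `[[`, st)

  age_lab <- .alloc(cat$age_group)
  age <- .draw_binned(age_lab, .bins$age_group, cont$age[1], cont$age[2],
                      integer = TRUE)
  d <- data.frame(
    sex = .alloc(cat$sex),
    age = as.integer(age),
    height = .draw_binned(.alloc(cat$height_group), .bins$height_group,
                          cont$height[1], cont$height[2]),
    bmi = .draw_binned(.alloc(cat$bmi_group), .bins$bmi_group,
                       cont$bmi[1], cont$bmi[2]),
    education_level = .alloc(cat$education_level),
    family_history_lc = .alloc(cat$family_history_lc),
    asbestos_exposure = .yes(.alloc(cat$asbestos_exposure)),
    prior_cancer = .yes(.alloc(cat$prior_cancer)),
    copd = .yes(.alloc(cat$copd)),
    chronic_bronchitis = .yes(.alloc(cat$chronic_bronchitis)),
    emphysema = .yes(.alloc(cat$emphysema)),
    interstitial_lung_disease = .yes(.alloc(cat$interstitial_lung_disease)),
    diabetes = .yes(.alloc(cat$diabetes)),
    cough = .yes(.alloc(cat$cough)),
    stringsAsFactors = FALSE)

  shs <- cont$secondhand_smoke_hours_per_day
  d$secondhand_smoke_hours_per_day <-
    round(pmax(.rtnorm(n, shs[1], shs[2], 0, 12), 0), 4)

  alc <- .alloc(cat$alcohol_group)
  d$alcohol_days_per_week <- ifelse(alc == "<5",
                                    sample(0:4, n, replace = TRUE),
                                    sample(5:7, n, replace = TRUE))
  pam <- .alloc(cat$pa_minutes_group)
  d$physical_activity_minutes_per_week <-
    ifelse(pam == "<30", floor(stats::runif(n, 0, 30)),
           floor(pmax(pmin(stats::rnorm(n, 150, 120), 840), 30)))
  pas <- .alloc(cat$pa_sessions_group)
  d$physical_activity_sessions_per_week <-
    ifelse(pas == "<3", sample(0:2, n, replace = TRUE),
           floor(pmax(pmin(stats::rnorm(n, 5, 3), 14), 3)))

  if (smoking == "ever") {
    status3 <- .alloc(cat$smoking_status3)
    d$smoking_status <- ifelse(status3 == "current", "current", "former")
    # feasibility cap on smoking years given age, earliest plausible
    # initiation age 8 and the quit-years floor implied by status
    quit_lo <- ifelse(status3 == "former_ge15", 15,
                      ifelse(status3 == "former_lt15", 0.5, 0))
    cap <- d$age - 8 - quit_lo
    sy_lab <- .repair_sy_groups(.alloc(cat$smoking_years_group), cap,
                                .bins$smoking_years_group)
    sy <- .draw_binned(sy_lab, .bins$smoking_years_group,
                       cont$smoking_years[1], cont$smoking_years[2],
                       integer = TRUE, cap = cap + 1)
    sy <- pmax(pmin(sy, cap), .bins$smoking_years_group[sy_lab, 1])
    d$smoking_years <- round(sy, 4)

    quit <- numeric(n)
    lt <- status3 == "former_lt15"
    ge <- status3 == "former_ge15"
    quit[lt] <- .rtnorm(sum(lt), cont$quit_years[1], cont$quit_years[2],
                        0.5, 15 - 1e-6)
    hi_ge <- pmax(d$age[ge] - 8 - d$smoking_years[ge], 15 + 1e-6)
    quit[ge] <- pmin(.rtnorm(sum(ge), cont$quit_years[1],
                             cont$quit_years[2], 15, 40), hi_ge)
    d$quit_years <- round(quit, 4)

    cpd <- .draw_binned(.alloc(cat$cpd_group), .bins$cpd_group,
                        cont$cigarettes_per_day[1],
                        cont$cigarettes_per_day[2], integer = TRUE)
    d$cigarettes_per_day <- cpd
    raw_py <- cpd / 20 * d$smoking_years
    f <- cont$pack_years[1] / mean(raw_py)
    f <- min(max(f, 0.8), 1.25)  # stay within the soft 25% identity band
    d$pack_years <- round(f * raw_py, 4)
    d$age_started <- round(pmax(d$age - d$smoking_years - d$quit_years, 8), 4)
    d$inhale_to_lungs <- .yes(.alloc(cat$inhale_to_lungs))
  } else {
    d$smoking_status <- "never"
    for (fld in smoker_only_fields()) d[[fld]] <- NA
    d$inhale_to_lungs <- as.logical(d$inhale_to_lungs)
    for (fld in setdiff(smoker_only_fields(), "inhale_to_lungs")) {
      d[[fld]] <- as.numeric(d[[fld]])
    }
  }
  d
}

# Event times reproducing a cumulative schedule exactly: counts per
# interval are the schedule differences, remaining cases fall after the
# last horizon.
.event_times <- function(n_cases, horizons, cum, fu_max) {
  per <- diff(c(0, cum))
  later <- n_cases - utils::tail(cum, 1)
  edges <- c(0, horizons, fu_max)
  counts <- c(per, later)
  t <- numeric(0)
  for (k in seq_along(counts)) {
    if (counts[k] == 0) next
    lo <- edges[k]; hi <- edges[k + 1]
    x <- lo + (hi - lo) * stats::runif(counts[k])
    # keep strictly inside the interval after 4-decimal rounding
    t <- c(t, pmin(pmax(round(x, 4), lo + 1e-4), hi - 1e-4))
  }
  sample(t)
}

#' Generate a synthetic cohort
#'
#' In `marginal_matching` mode (default), every categorical count of the
#' configuration is reproduced exactly and case event times reproduce the
#' configured cumulative event schedule exactly; non-cases are censored
#' at times of at least 10 years.  In `risk_structure` mode the covariates
#' are generated the same way but outcomes are re-simulated from
#' `config$true_model` via [simulate_outcomes()], giving a cohort with
#' known ground-truth risks.
#'
#' @param config a `lr_cohort_config` (see [default_cohort_config()]).
#' @param seed overrides `config$seed` when given.
#' @return A validated `lr_cohort`.
#' @export
generate_cohort <- function(config, seed = NULL) {
  validate_cohort_config(config)
  if (is.null(seed)) seed <- config$seed
  set.seed(seed)
  parts <- list()
  for (st in names(config$strata)) {
    d <- .generate_stratum(config, st)
    d$event <- config$strata[[st]]$case
    parts[[st]] <- d
  }
  sch <- config$event_schedule
  parts$ec$time <- .event_times(nrow(parts$ec), sch$horizons, sch$ever,
                                config$followup_max)
  parts$nc$time <- .event_times(nrow(parts$nc), sch$horizons, sch$never,
                                config$followup_max)
  for (st in c("en", "nn")) {
    n <- nrow(parts[[st]])
    parts[[st]]$time <- round(stats::runif(n, 10.0001,
                                           config$followup_max), 4)
  }
  df <- do.call(rbind, parts)
  df <- df[sample(nrow(df)), , drop = FALSE]
  df$id <- sprintf("S%05d", seq_len(nrow(df)))
  cohort <- as_cohort(df, provenance = list(generator = "lungrisk",
                                            mode = config$mode,
                                            seed = seed))
  if (identical(config$mode, "risk_structure")) {
    if (is.null(config$true_model)) {
      stop("config error: risk_structure mode requires a true_model",
           call. = FALSE)
    }
    cohort <- simulate_outcomes(cohort, config$true_model, seed = seed + 1L)
  }
  cohort
}

#' Inject missing values
#'
#' Selects exactly `config$missingness$n` subjects uniformly at random
#' (MCAR) and blanks one applicable field per subject among the
#' configured eligible fields.  For never smokers only the non-smoking
#' eligible fields can be blanked.
#'
#' @param cohort complete cohort.
#' @param config a `lr_cohort_config`.
#' @param seed overrides `config$seed + 1000` when given.
#' @return The cohort with missing values, provenance updated.
#' @export
inject_missingness <- function(cohort, config, seed = NULL) {
  n_miss <- config$missingness$n
  if (n_miss > nrow(cohort)) {
    stop("config error: missingness count exceeds cohort size",
         call. = FALSE)
  }
  if (is.null(seed)) seed <- config$seed + 1000L
  set.seed(seed)
  fields <- config$missingness$fields
  idx <- sample(nrow(cohort), n_miss)
  never <- cohort$smoking_status == "never"
  for (i in idx) {
    elig <- if (never[i]) setdiff(fields, smoker_only_fields()) else fields
    if (!length(elig)) next
    fld <- if (length(elig) == 1) elig else sample(elig, 1)
    cohort[[fld]][i] <- NA
  }
  attr(cohort, "provenance") <- c(attr(cohort, "provenance"),
                                  list(missingness_seed = seed))
  cohort
}

#' Simulate outcomes from a known risk model
#'
#' Draws each subject's event indicator Bernoulli(risk) where risk is the
#' model's absolute risk over its horizon; event times are uniform on
#' (0, horizon], non-events are censored after the horizon.  Used for
#' ground-truth property tests: the expected case count equals the sum of
#' the true risks.
#'
#' @param cohort complete cohort (covariates used; outcomes replaced).
#' @param true_model a `lr_model_spec` evaluable on every subject.
#' @param seed integer seed.
#' @return The cohort with simulated `event`/`time`.
#' @export
simulate_outcomes <- function(cohort, true_model, seed) {
  set.seed(seed)
  risks <- predict_cohort(true_model, cohort)$risk
  if (any(is.na(risks)) || any(risks < 0) || any(risks > 1)) {
    stop("engine error: true model produced risks outside [0, 1]",
         call. = FALSE)
  }
  h <- true_model$horizon_years
  ev <- stats::runif(nrow(cohort)) < risks
  t <- numeric(nrow(cohort))
  t[ev] <- pmax(round(h * stats::runif(sum(ev)), 4), 1e-4)
  t[!ev] <- round(stats::runif(sum(!ev), max(h, 10) + 0.0001, 19.3), 4)
  cohort$event <- ev
  cohort$time <- t
  attr(cohort, "provenance") <- c(attr(cohort, "provenance"),
                                  list(true_model = true_model$name,
                                       outcome_seed = seed))
  cohort
}
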