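# Fixtures built in code.

# One fully specified subject row with overridable fields.
subject_row <- function(id = "A001", sex = "male", age = 60L,
                        height = 165, bmi = 23,
                        education_level = "middle_school_or_below",
                        smoking_status = "never",
                        age_started = NA_real_,
                        smoking_years = NA_real_,
                        quit_years = NA_real_,
                        cigarettes_per_day = NA_real_,
                        pack_years = NA_real_,
                        inhale_to_lungs = NA,
                        secondhand_smoke_hours_per_day = 0,
                        alcohol_days_per_week = 5,
                        physical_activity_minutes_per_week = 100,
                        physical_activity_sessions_per_week = 3,
                        family_history_lc = "none",
                        asbestos_exposure = FALSE, prior_cancer = FALSE,
                        copd = FALSE, chronic_bronchitis = FALSE,
                        emphysema = FALSE,
                        interstitial_lung_disease = FALSE,
                        diabetes = FALSE, cough = FALSE,
                        event = FALSE, time = 12) {
  data.frame(id = id, sex = sex, age = age, height = height, bmi = bmi,
             education_level = education_level,
             smoking_status = smoking_status, age_started = age_started,
             smoking_years = smoking_years, quit_years = quit_years,
             cigarettes_per_day = cigarettes_per_day,
             pack_years = pack_years,
             inhale_to_lungs = as.logical(inhale_to_lungs),
             secondhand_smoke_hours_per_day = secondhand_smoke_hours_per_day,
             alcohol_days_per_week = alcohol_days_per_week,
             physical_activity_minutes_per_week = physical_activity_minutes_per_week,
             physical_activity_sessions_per_week = physical_activity_sessions_per_week,
             family_history_lc = family_history_lc,
             asbestos_exposure = asbestos_exposure,
             prior_cancer = prior_cancer, copd = copd,
             chronic_bronchitis = chronic_bronchitis,
             emphysema = emphysema,
             interstitial_lung_disease = interstitial_lung_disease,
             diabetes = diabetes, cough = cough, event = event,
             time = time, stringsAsFactors = FALSE)
}

smoker_row <- function(id = "B001", smoking_status = "current",
                       age = 60L, smoking_years = 30,
                       quit_years = 0, cigarettes_per_day = NULL,
                       pack_years = NULL, age_started = 20,
                       inhale_to_lungs = TRUE, ...) {
  # keep the pack-year identity consistent unless both are forced
  if (is.null(cigarettes_per_day) && is.null(pack_years)) {
    cigarettes_per_day <- 20
    pack_years <- cigarettes_per_day / 20 * smoking_years
  } else if (is.null(cigarettes_per_day)) {
    cigarettes_per_day <- pack_years * 20 / smoking_years
  } else if (is.null(pack_years)) {
    pack_years <- cigarettes_per_day / 20 * smoking_years
  }
  subject_row(id = id, smoking_status = smoking_status, age = age,
              smoking_years = smoking_years, quit_years = quit_years,
              cigarettes_per_day = cigarettes_per_day,
              pack_years = pack_years, age_started = age_started,
              inhale_to_lungs = inhale_to_lungs, ...)
}

# Strip class and provenance for content-equality comparisons.
plain <- function(x) {
  x <- as.data.frame(x)
  attr(x, "provenance") <- NULL
  class(x) <- "data.frame"
  x
}

# Cached scaled synthetic cohort (shared across test files).
.fixture_env <- new.env(parent = emptyenv())

small_config <- function(frac = 0.03) {
  key <- paste0("cfg", frac)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- scale_cohort_config(default_cohort_config(),
                                               frac)
  }
  .fixture_env[[key]]
}

small_cohort <- function(frac = 0.03, seed = 42L) {
  key <- paste0("coh", frac, ".", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_cohort(small_config(frac), seed = seed)
  }
  .fixture_env[[key]]
}

# Minimal logistic toy spec.
toy_spec <- function(terms = list(), intercept = 0, form = "logistic_direct",
                     population = "all", horizon = 6, baselines = NULL,
                     name = "Toy") {
  validate_model_spec(list(schema_version = "1.0", name = name,
                           population = population,
                           horizon_years = horizon, form = form,
                           intercept = intercept, terms = terms,
                           baselines = baselines))
}
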