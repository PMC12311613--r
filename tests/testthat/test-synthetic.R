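# Reconstruct a categorical cell count from a generated cohort.
count_cell <- function(ch, smoking, case, filter_fn) {
  grp <- if (smoking == "ever") ch$smoking_status %in% c("current", "former")
         else ch$smoking_status == "never"
  sum(grp & (ch$event == case) & filter_fn(ch))
}

test_that("every categorical cell of the scaled config is reproduced exactly", {
  cfg <- small_config()
  ch <- small_cohort()
  strata <- list(ec = c("ever", TRUE), en = c("ever", FALSE),
                 nc = c("never", TRUE), nn = c("never", FALSE))
  checks <- list(
    sex = function(lv) function(d) d$sex == lv,
    education_level = function(lv) function(d) d$education_level == lv,
    family_history_lc = function(lv) function(d) d$family_history_lc == lv,
    copd = function(lv) function(d) d$copd == (lv == "yes"),
    emphysema = function(lv) function(d) d$emphysema == (lv == "yes"))
  for (st in names(strata)) {
    for (var in names(checks)) {
      counts <- cfg$cat[[var]][[st]]
      for (lv in names(counts)) {
        got <- count_cell(ch, strata[[st]][1],
                          as.logical(strata[[st]][2]), checks[[var]](lv))
        expect_equal(got, unname(counts[lv]),
                     info = paste(st, var, lv))
      }
    }
    # binned continuous variables match their group counts too
    bmi_counts <- cfg$cat$bmi_group[[st]]
    cuts <- function(d) findInterval(d$bmi, c(18.5, 24)) + 1L
    for (k in 1:3) {
      got <- count_cell(ch, strata[[st]][1], as.logical(strata[[st]][2]),
                        function(d) cuts(d) == k)
      expect_equal(got, unname(bmi_counts[k]), info = paste(st, "bmi", k))
    }
  }
})

test_that("the event schedule is reproduced exactly per smoking group", {
  cfg <- small_config()
  ch <- small_cohort()
  for (grp in c("ever", "never")) {
    sub <- subset_by_smoking(ch, grp)
    sched <- cfg$event_schedule[[grp]]
    for (i in seq_along(sched)) {
      t <- cfg$event_schedule$horizons[i]
      expect_equal(sum(sub$event & sub$time <= t), sched[i],
                   info = paste(grp, t))
    }
  }
})

test_that("non-cases are censored at 10 years or later", {
  ch <- small_cohort()
  expect_true(all(ch$time[!ch$event] >= 10))
  expect_true(all(ch$time > 0))
})

test_that("generation is deterministic under a fixed seed", {
  a <- generate_cohort(small_config(), seed = 7)
  b <- generate_cohort(small_config(), seed = 7)
  expect_identical(plain(a), plain(b))
  c <- generate_cohort(small_config(), seed = 8)
  expect_false(identical(plain(a), plain(c)))
})

test_that("smoking timelines are internally consistent", {
  ev <- subset_by_smoking(small_cohort(), "ever")
  expect_true(all(ev$smoking_years >= 1))
  expect_true(all(ev$age_started >= 8))
  expect_true(all(ev$quit_years[ev$smoking_status == "current"] == 0))
  expect_true(all(ev$quit_years[ev$smoking_status == "former"] > 0))
  # soft pack-year identity holds by construction
  dev <- abs(ev$pack_years - ev$cigarettes_per_day / 20 * ev$smoking_years)
  expect_true(all(dev <= 0.25 * ev$pack_years + 1e-6))
})

test_that("inconsistent configs are rejected", {
  cfg <- small_config()
  cfg$cat$sex$ec["male"] <- cfg$cat$sex$ec["male"] + 1
  expect_error(generate_cohort(cfg), "config error.*sex.*ec")
  cfg2 <- small_config()
  cfg2$event_schedule$ever <- rev(cfg2$event_schedule$ever)
  expect_error(generate_cohort(cfg2), "non-decreasing")
})

test_that("inject_missingness blanks exactly the configured count", {
  cfg <- small_config()
  ch <- small_cohort()
  chm <- inject_missingness(ch, cfg, seed = 5)
  expect_equal(n_missing_subjects(chm), cfg$missingness$n)
  # count = 0 leaves the cohort unchanged
  cfg0 <- cfg
  cfg0$missingness$n <- 0L
  expect_identical(plain(inject_missingness(ch, cfg0, seed = 5)),
                   plain(ch))
  # a single eligible field concentrates all the blanks in that column
  cfg1 <- cfg
  cfg1$missingness$fields <- "bmi"
  cfg1$missingness$n <- 25L
  ch1 <- inject_missingness(ch, cfg1, seed = 5)
  expect_equal(sum(is.na(ch1$bmi)), 25)
  # count beyond the cohort is a config error
  cfgbad <- cfg
  cfgbad$missingness$n <- nrow(ch) + 1L
  expect_error(inject_missingness(ch, cfgbad), "config error")
})

test_that("simulate_outcomes respects degenerate risk levels", {
  ch <- small_cohort()
  zero <- toy_spec(intercept = -745)  # plogis underflows to exactly 0
  sim0 <- simulate_outcomes(ch, zero, seed = 1)
  expect_equal(sum(sim0$event), 0)
  one <- toy_spec(intercept = 745)
  sim1 <- simulate_outcomes(ch, one, seed = 1)
  expect_equal(sum(sim1$event), nrow(ch))
  expect_true(all(sim1$time <= one$horizon_years))
})

test_that("constant-risk simulation matches the binomial bound", {
  # risk 0.01 on ~10k subjects: count within 3 sqrt(np(1-p)) of np
  cfg <- scale_cohort_config(default_cohort_config(), 0.33)
  ch <- generate_cohort(cfg, seed = 11)
  p <- 0.01
  const <- toy_spec(intercept = stats::qlogis(p))
  sim <- simulate_outcomes(ch, const, seed = 12)
  n <- nrow(ch)
  expect_lt(abs(sum(sim$event) - n * p), 3 * sqrt(n * p * (1 - p)))
})

test_that("risk_structure mode simulates outcomes from the true model", {
  cfg <- small_config()
  cfg$mode <- "risk_structure"
  expect_error(generate_cohort(cfg, seed = 3), "true_model")
  cfg$true_model <- ground_truth_spec()
  ch <- generate_cohort(cfg, seed = 3)
  expect_gt(sum(ch$event), 0)
  expect_true(all(ch$time[ch$event] <= cfg$true_model$horizon_years))
})
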