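test_that("match_threshold selects the top n_target, ties dropped by id", {
  r <- match_threshold(c(0.1, 0.2, 0.3, 0.4), 2)
  expect_equal(r$threshold, 0.3)
  expect_setequal(r$selected, c("3", "4"))
  # tie at the threshold: the excess tied subject with the larger id is
  # dropped, so ids "2" (risk 0.3) and "4" (risk 0.4) remain
  rt <- match_threshold(c(0.2, 0.3, 0.3, 0.4), 2,
                        ids = c("1", "2", "3", "4"))
  expect_equal(rt$threshold, 0.3)
  expect_setequal(rt$selected, c("2", "4"))
  all_r <- match_threshold(c(0.5, 0.1, 0.9), 3)
  expect_equal(all_r$threshold, 0.1)
  expect_length(all_r$selected, 3)
  expect_error(match_threshold(c(0.1, 0.2), 3), "out of range")
  expect_error(match_threshold(c(0.1, 0.2), 0), "out of range")
})

test_that("match_threshold always returns exactly n_target subjects", {
  set.seed(77)
  for (i in 1:30) {
    n <- sample(5:60, 1)
    # heavy ties on purpose
    risks <- sample(round(stats::runif(4), 2), n, replace = TRUE)
    k <- sample(n, 1)
    ids <- sample(sprintf("id%03d", 1:n))
    expect_length(match_threshold(risks, k, ids)$selected, k)
  }
})

test_that("confusion_metrics matches a hand-computed table", {
  ids <- sprintf("s%02d", 1:10)
  out <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
           FALSE)
  sel <- c("s01", "s02", "s04", "s05")
  cm <- confusion_metrics(sel, ids, out)
  expect_equal(cm$tp, 2)
  expect_equal(cm$fn, 1)
  expect_equal(cm$fp, 2)
  expect_equal(cm$tn, 5)
  expect_equal(cm$sensitivity, 2 / 3)
  expect_equal(cm$specificity, 5 / 7)
  # select exactly the cases
  perfect <- confusion_metrics(ids[out], ids, out)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  none <- confusion_metrics(character(0), ids, out)
  expect_equal(none$sensitivity, 0)
  expect_equal(none$specificity, 1)
  expect_error(confusion_metrics(sel, ids, rep(FALSE, 10)), "no cases")
})

test_that("sensitivity is non-decreasing in n_target", {
  ev <- subset_by_smoking(small_cohort(), "ever")
  spec <- registry_list()$PLCOm2012
  pred <- predict_cohort(spec, ev)
  oc <- outcome_at_horizon(ev, spec$horizon_years)$outcome
  sens <- vapply(seq(10, nrow(ev), length.out = 12), function(k) {
    sel <- match_threshold(pred$risk, round(k), ids = pred$id)$selected
    confusion_metrics(sel, ev$id, oc)$sensitivity
  }, 0)
  expect_true(all(diff(sens) >= 0))
})

test_that("compare_all matches counts for every model and errors on empty criteria", {
  ev <- subset_by_smoking(small_cohort(), "ever")
  specs <- registry_list()
  cmp <- compare_all(ev, "uspstf", specs)
  n_target <- cmp$n_selected[1]
  expect_gt(n_target, 0)
  expect_true(all(cmp$n_selected == n_target))
  expect_equal(nrow(cmp), 13)
  # a model reports cases at its native horizon only
  bach <- cmp[cmp$model %in% "Bach", ]
  expect_false(is.na(bach$cases_10y))
  expect_true(is.na(bach$cases_5y))
  # empty criteria selection
  kids <- as_cohort(rbind(smoker_row("K1", age = 46L),
                          smoker_row("K2", age = 47L)))
  expect_error(compare_all(kids, "uspstf", specs["PLCOm2012"]),
               "selects no subjects")
})

test_that("a criteria-indicator model reproduces the criteria selection", {
  ev <- subset_by_smoking(small_cohort(), "ever")
  el <- apply_criteria(ev, "nelson")
  risks <- as.numeric(el$eligible)
  mt <- match_threshold(risks, sum(el$eligible), ids = el$id)
  expect_setequal(mt$selected, el$id[el$eligible])
  oc <- outcome_at_horizon(ev, 6)$outcome
  cm_model <- confusion_metrics(mt$selected, ev$id, oc)
  cm_crit <- confusion_metrics(el$id[el$eligible], ev$id, oc)
  expect_identical(cm_model, cm_crit)
})

test_that("ranking by the true risk beats random selection", {
  cfg <- small_config(frac = 0.1)
  cfg$mode <- "risk_structure"
  cfg$true_model <- ground_truth_spec()
  wins <- 0
  for (s in 1:5) {
    ch <- generate_cohort(cfg, seed = 200 + s)
    pred <- predict_cohort(cfg$true_model, ch)
    k <- round(nrow(ch) / 4)
    sel <- match_threshold(pred$risk, k, ids = pred$id)$selected
    oc <- outcome_at_horizon(ch, cfg$true_model$horizon_years)$outcome
    model_cases <- sum(oc[ch$id %in% sel])
    set.seed(300 + s)
    rand_cases <- mean(replicate(20, sum(oc[sample(nrow(ch), k)])))
    wins <- wins + (model_cases > rand_cases)
  }
  expect_gte(wins, 4)  # allow one Monte-Carlo upset
})
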