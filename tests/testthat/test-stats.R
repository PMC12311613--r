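test_that("auc handles separation, ties and degenerate input", {
  y <- c(rep(FALSE, 4), rep(TRUE, 3))
  expect_equal(auc(c(1, 2, 3, 4, 5, 6, 7), y), 1)
  expect_equal(auc(rep(2.5, 7), y), 0.5)
  # 6 subjects with ties, against exhaustive concordance
  s <- c(0.1, 0.4, 0.4, 0.2, 0.4, 0.9)
  o <- c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE)
  expect_equal(auc(s, o), brute_auc(s, o), tolerance = 1e-15)
  expect_error(auc(1:4, rep(TRUE, 4)), "at least one case and one control")
})

test_that("auc is invariant under strictly monotone score transforms", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    s <- stats::rnorm(n)
    o <- stats::runif(n) < 0.3
    if (!any(o) || all(o)) next
    a <- auc(s, o)
    expect_equal(auc(exp(s), o), a, tolerance = 1e-12)
    expect_equal(auc(stats::plogis(3 * s + 1), o), a, tolerance = 1e-12)
  }
})

test_that("auc_ci behaves at the boundaries and shrinks with n", {
  y <- rep(c(TRUE, FALSE), each = 25)
  s <- c(stats::rnorm(25, 2), stats::rnorm(25))
  perfect <- auc_ci(c(2:26, rep(0, 25)) + 0, y)
  expect_equal(perfect$hi, 1)
  ci1 <- auc_ci(s, y)
  ci2 <- auc_ci(rep(s, 2), rep(y, 2))
  expect_lt(ci2$hi - ci2$lo, ci1$hi - ci1$lo)
})

test_that("the DeLong interval matches a bootstrap oracle", {
  set.seed(99)
  s <- stats::rnorm(100) + rep(c(1.2, 0), times = c(40, 60))
  y <- rep(c(TRUE, FALSE), times = c(40, 60))
  boots <- replicate(10000, {
    i <- sample(which(y), replace = TRUE)
    j <- sample(which(!y), replace = TRUE)
    auc(c(s[i], s[j]), c(y[i], y[j]))
  })
  bci <- stats::quantile(boots, c(0.025, 0.975), names = FALSE)
  d <- auc_ci(s, y)
  expect_equal(d$lo, bci[1], tolerance = 0.02)
  expect_equal(d$hi, bci[2], tolerance = 0.02)
})

test_that("eo_ratio computes E, O and the Poisson interval", {
  pred <- c(0.4, 0.6, 1.0, 3.0)  # sums to 5
  out <- rep(c(TRUE, FALSE), times = c(10, 10))
  r <- eo_ratio(c(pred, rep(0, 16)), out)
  expect_equal(r$ratio, 0.5)
  expect_equal(r$lo, 0.5 * exp(-stats::qnorm(0.975) / sqrt(10)),
               tolerance = 1e-12)
  # E equal to O gives exactly 1
  p1 <- rep(0.5, 20)
  expect_equal(eo_ratio(p1, out)$ratio, 1)
  expect_error(eo_ratio(pred, rep(FALSE, 4)), "no observed cases")
})

test_that("calibration bins split by the documented remainder rule", {
  b8 <- calibration_bins(seq(0.1, 0.8, by = 0.1), rep(FALSE, 8))
  expect_equal(b8$n, rep(2, 4))
  expect_equal(b8$observed_proportion, rep(0, 4))
  b10 <- calibration_bins(stats::runif(10), rep(c(TRUE, FALSE), 5))
  expect_equal(b10$n, c(3, 3, 2, 2))  # remainder to the lowest bins
  expect_error(calibration_bins(c(0.1, 0.2, 0.3), c(TRUE, FALSE, TRUE)),
               "at least 4")
})

test_that("calibration bins order ascending and sum to the stratum", {
  set.seed(5)
  n <- 101
  p <- stats::runif(n)
  y <- stats::runif(n) < p
  b <- calibration_bins(p, y, ids = sprintf("x%03d", 1:n))
  expect_equal(sum(b$n), n)
  expect_true(all(diff(b$mean_predicted) > 0))
  expect_equal(sum(b$cases), sum(y))
  hi <- attr(b, "high_risk_ids")
  expect_length(hi, b$n[4])
  # the high-risk quartile holds the largest predictions
  expect_gte(min(p[match(hi, sprintf("x%03d", 1:n))]),
             max(sort(p)[seq_len(n - b$n[4])]))
})

test_that("tied predictions keep input order (stable bins)", {
  p <- rep(0.5, 8)
  b <- calibration_bins(p, rep(FALSE, 8), ids = letters[1:8])
  expect_equal(attr(b, "high_risk_ids"), c("g", "h"))
})

test_that("radial summaries tabulate percentages per feature", {
  ch <- small_cohort()
  fem <- ch$id[ch$sex == "female"][1:10]
  rs <- radial_feature_summary(ch, fem, features = c("sex", "copd"))
  expect_equal(rs$percent[rs$feature == "sex" & rs$category == "female"],
               100)
  for (f in unique(rs$feature)) {
    expect_equal(sum(rs$percent[rs$feature == f]), 100, tolerance = 1e-9)
  }
  # hand-tabulated 4-subject group
  ids4 <- ch$id[c(which(ch$education_level == "middle_school_or_below")[1:2],
                  which(ch$education_level == "high_school")[1],
                  which(ch$education_level == "college_or_above")[1])]
  rs4 <- radial_feature_summary(ch, ids4, features = "education_level")
  expect_equal(sort(rs4$percent), c(25, 25, 50))
  expect_error(radial_feature_summary(ch, character(0)), "empty")
  expect_error(radial_feature_summary(ch, "nope"), "not all present")
})
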