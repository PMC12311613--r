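test_that("the linear predictor matches a hand-computed dot product", {
  # four mixed terms on one smoker: identity, centering, log, mapping
  spec <- toy_spec(intercept = -1.5, terms = list(
    list(predictor = "age", coef = 0.05,
         transform = list(list(op = "subtract", value = 60))),
    list(predictor = "bmi", coef = -0.1, transform = list()),
    list(predictor = "pack_years", coef = 0.4,
         transform = list(list(op = "log", offset = 1))),
    list(predictor = "sex", coef = 1,
         transform = list(list(op = "map",
                               levels = list(male = 0.3, female = 0))))))
  s <- smoker_row(age = 66L, bmi = 24, pack_years = 30)
  # by hand: -1.5 + 0.05*6 - 0.1*24 + 0.4*log(31) + 0.3
  expected <- -1.5 + 0.3 - 2.4 + 0.4 * log(31) + 0.3
  expect_equal(evaluate_linear_predictor(spec, s), expected,
               tolerance = 1e-12)
  # degenerate cases
  expect_equal(evaluate_linear_predictor(toy_spec(intercept = 2.5), s), 2.5)
  one <- toy_spec(terms = list(list(predictor = "bmi", coef = 2,
                                    transform = list())))
  s$bmi <- 3
  expect_equal(evaluate_linear_predictor(one, s), 6)
})

test_that("missing predictors and wrong populations are named errors", {
  spec <- toy_spec(terms = list(list(predictor = "bmi", coef = 1,
                                     transform = list())))
  s <- subject_row("M9")
  s$bmi <- NA_real_
  expect_error(evaluate_linear_predictor(spec, s), "missing predictor 'bmi'.*M9")
  ever_spec <- toy_spec(population = "ever_only")
  expect_error(evaluate_linear_predictor(ever_spec, subject_row()),
               "population error")
})

test_that("risk_logistic matches its closed form", {
  expect_equal(risk_logistic(0), 0.5)
  expect_equal(risk_logistic(log(1 / 3)), 0.25, tolerance = 1e-12)
  expect_lt(risk_logistic(-50), 1e-20)
})

test_that("risk_cox matches its closed form", {
  expect_equal(risk_cox(0, 0.99), 0.01)
  expect_equal(risk_cox(3.7, 1), 0)
  # constant-hazard construction: s0 = exp(-lambda t)
  lambda <- 0.002; t <- 6; lp <- 0.8
  expect_equal(risk_cox(lp, exp(-lambda * t)),
               1 - exp(-lambda * t * exp(lp)), tolerance = 1e-12)
  expect_error(risk_cox(0, 0), "baseline survival")
})

test_that("risk_rr_incidence follows odds algebra", {
  expect_equal(risk_rr_incidence(1, 0.037), 0.037)
  expect_equal(risk_rr_incidence(2, 0.01),
               (0.01 / 0.99 * 2) / (1 + 0.01 / 0.99 * 2),
               tolerance = 1e-12)
  expect_equal(risk_rr_incidence(2, 0.01), 0.0198019801980198,
               tolerance = 1e-12)
  expect_equal(risk_rr_incidence(5, 0), 0)
  expect_error(risk_rr_incidence(-1, 0.1), "negative")
})

test_that("risk_annual_recursion matches trivial closed forms", {
  expect_equal(risk_annual_recursion(rep(0, 10), rep(0.02, 10), 10), 0)
  h <- 0.013
  expect_equal(risk_annual_recursion(rep(h, 8), rep(0, 8), 8),
               1 - (1 - h)^8, tolerance = 1e-12)
  expect_error(risk_annual_recursion(rep(1.2, 5), rep(0, 5), 5),
               "hazards")
  expect_error(risk_annual_recursion(rep(0.1, 3), rep(0, 3), 5),
               "shorter")
})

test_that("risk_annual_recursion equals the competing-processes oracle", {
  set.seed(2024)
  for (i in 1:25) {
    hlc <- stats::runif(10, 0, 0.2)
    hm <- stats::runif(10, 0, 0.3)
    expect_equal(risk_annual_recursion(hlc, hm, 10),
                 oracle_recursion(hlc, hm, 10), tolerance = 1e-12)
  }
})

test_that("monthly sub-steps converge to the Cox constant-hazard form", {
  lambda <- 0.01; H <- 5
  monthly <- risk_annual_recursion(rep(lambda / 12, 12 * H),
                                   rep(0, 12 * H), 12 * H)
  expect_equal(monthly, risk_cox(0, exp(-lambda * H)), tolerance = 1e-3)
})

test_that("fractional horizons pro-rate the final year", {
  hlc <- c(0.01, 0.02, 0.03)
  hm <- c(0.005, 0.005, 0.005)
  full2 <- risk_annual_recursion(hlc, hm, 2)
  alive2 <- (1 - hlc[1]) * (1 - hm[1]) * (1 - hlc[2]) * (1 - hm[2])
  expect_equal(risk_annual_recursion(hlc, hm, 2.5),
               full2 + alive2 * 0.5 * hlc[3], tolerance = 1e-12)
})

test_that("predict routes to each form and is deterministic", {
  s <- smoker_row()
  p <- predict_risk(toy_spec(), s)
  expect_equal(p$risk, 0.5)
  expect_equal(p$horizon, 6)
  # recursion spec matches risk_annual_recursion compositionally
  tab <- function(h) lapply(1:1, function(i)
    list(sex = "any", age_lo = 45, age_hi = 110, hazard = h))
  rec <- toy_spec(form = "annual_recursion", horizon = 10,
                  baselines = list(lc_hazard = tab(0.004),
                                   mortality_hazard = tab(0.02)))
  pr <- predict_risk(rec, s)
  expect_equal(pr$risk,
               risk_annual_recursion(rep(0.004, 10), rep(0.02, 10), 10),
               tolerance = 1e-12)
  expect_identical(predict_risk(rec, s), predict_risk(rec, s))
  # ever-only spec rejects a never smoker
  expect_error(predict_risk(toy_spec(population = "ever_only"),
                            subject_row()), "population error")
})

test_that("risks are monotone in a positive-coefficient predictor", {
  base <- toy_spec(terms = list(list(predictor = "bmi", coef = 0.3,
                                     transform = list())),
                   intercept = -4)
  risks <- vapply(seq(15, 40, by = 1), function(b) {
    predict_risk(base, subject_row(bmi = b))$risk
  }, 0)
  expect_true(all(diff(risks) > 0))
  expect_true(all(risks >= 0 & risks <= 1))
})

test_that("AUC-style scores are invariant when a spec only rescales", {
  # transformation pipeline: truncate + bin behave as specified
  spec <- toy_spec(terms = list(
    list(predictor = "pack_years", coef = 1,
         transform = list(list(op = "truncate", lo = 10, hi = 50))),
    list(predictor = "age", coef = 1,
         transform = list(list(op = "bin", breaks = c(50, 60),
                               values = c(0, 1, 2))))))
  lp <- evaluate_linear_predictor(spec, smoker_row(pack_years = 80,
                                                   age = 55L))
  expect_equal(lp, 50 + 1)
  lp2 <- evaluate_linear_predictor(spec, smoker_row(pack_years = 5,
                                                    age = 49L))
  expect_equal(lp2, 10 + 0)
})
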