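#' @title Multiple imputation and pooling
#' @description
#' A compact implementation of multiple imputation by chained equations
#' for the small, fixed set of incompletely observed predictors
#' (smoking years, quit years, cigarettes per day, BMI, height,
#' education level): predictive mean matching for continuous fields and
#' ordinal (proportional-odds) regression for education, cycling for a
#' bounded number of iterations.  Estimates across imputations are
#' combined with Rubin's rules.
#' @name imputation
NULL

# Truly-missing mask: NA on an applicable field (smoker-only fields are
# structurally NA for never smokers and are not "missing").
.missing_mask <- function(df, fld) {
  m <- is.na(df[[fld]])
  if (fld %in% smoker_only_fields()) {
    m <- m & df$smoking_status %in% c("current", "former")
  }
  m
}

# Predictive mean matching: draw each missing value from the observed
# value of one of k donors near the predicted mean.  The donor pool is a
# k-wide window around the insertion point in the sorted predictions
# (O(n log n) overall), the standard large-n approximation to the exact
# k nearest donors.
.pmm_draw <- function(yhat_obs, y_obs, yhat_mis, k = 5) {
  ord <- order(yhat_obs)
  ys <- yhat_obs[ord]
  yo <- y_obs[ord]
  n <- length(ys)
  if (n <= k) return(yo[sample.int(n, length(yhat_mis), replace = TRUE)])
  pos <- findInterval(yhat_mis, ys)
  lo <- pmin(pmax(pos - k %/% 2, 1), n - k + 1)
  off <- sample.int(k, length(yhat_mis), replace = TRUE) - 1L
  yo[lo + off]
}

# Design matrix of always-complete predictors plus current working
# values of the other chained fields (excluding `target`).
.imp_design <- function(df, target) {
  X <- data.frame(age = df$age,
                  male = as.numeric(df$sex == "male"),
                  event = as.numeric(df$event))
  for (fld in c("bmi", "height")) {
    if (fld != target) X[[fld]] <- df[[fld]]
  }
  if (target != "education_level") {
    X$edu <- match(df$education_level,
                   c("middle_school_or_below", "high_school",
                     "college_or_above"))
  }
  smoker_flds <- c("smoking_years", "quit_years", "cigarettes_per_day")
  if (target %in% smoker_flds) {
    for (fld in setdiff(smoker_flds, target)) X[[fld]] <- df[[fld]]
  }
  X
}

.impute_field <- function(df, fld) {
  mis <- .missing_mask(df, fld)
  if (!any(mis)) return(df)
  # current smokers have quit_years 0 by definition
  if (fld == "quit_years") {
    cur <- mis & df$smoking_status == "current"
    df$quit_years[cur] <- 0
    mis <- mis & !cur
    if (!any(mis)) return(df)
  }
  scope <- if (fld %in% smoker_only_fields()) {
    df$smoking_status %in% c("current", "former")
  } else rep(TRUE, nrow(df))
  if (fld == "quit_years") scope <- scope & df$smoking_status == "former"
  obs <- scope & !mis
  X <- .imp_design(df, fld)
  if (fld == "education_level") {
    y <- factor(df[[fld]][obs],
                levels = c("middle_school_or_below", "high_school",
                           "college_or_above"), ordered = TRUE)
    fit <- tryCatch(
      MASS::polr(y ~ ., data = cbind(y = y, X[obs, , drop = FALSE])),
      error = function(e) NULL)
    if (is.null(fit)) {
      p <- prop.table(table(y))
      draw <- sample(names(p), sum(mis), replace = TRUE, prob = p)
    } else {
      pr <- stats::predict(fit, newdata = X[mis, , drop = FALSE],
                           type = "probs")
      pr <- matrix(pr, nrow = sum(mis))
      draw <- levels(y)[apply(pr, 1, function(p)
        sample.int(length(p), 1, prob = p))]
    }
    df[[fld]][mis] <- draw
  } else {
    dat <- cbind(y = df[[fld]], X)
    fit <- stats::lm(y ~ ., data = dat[obs, , drop = FALSE])
    yhat_obs <- stats::predict(fit, newdata = X[obs, , drop = FALSE])
    yhat_mis <- stats::predict(fit, newdata = X[mis, , drop = FALSE])
    df[[fld]][mis] <- .pmm_draw(yhat_obs, df[[fld]][obs], yhat_mis)
  }
  df
}

#' Multiple imputation by chained equations
#'
#' Produces `m` complete cohorts; observed values are untouched.
#' Continuous fields use predictive mean matching, education uses
#' ordinal regression (with a marginal-draw fallback), cycling
#' `max_iter` times per imputation.
#'
#' @param cohort cohort with missingness confined to the six supported
#'   fields.
#' @param m number of imputations.
#' @param seed integer seed.
#' @param max_iter chained-equation cycles per imputation.
#' @return List of `m` complete `lr_cohort` objects.
#' @export
mice_impute <- function(cohort, m = 5, seed = 1L, max_iter = 10) {
  supported <- c("smoking_years", "quit_years", "cigarettes_per_day",
                 "bmi", "education_level", "height")
  df0 <- as.data.frame(cohort)
  other <- setdiff(cohort_columns(), c(supported, "id", "event", "time"))
  for (fld in other) {
    if (any(.missing_mask(df0, fld))) {
      stop("imputation error: missingness outside the supported fields (",
           fld, ")", call. = FALSE)
    }
  }
  masks <- lapply(supported, function(f) .missing_mask(df0, f))
  names(masks) <- supported
  active <- supported[vapply(masks, any, TRUE)]
  for (fld in active) {
    scope_obs <- !masks[[fld]] & !is.na(df0[[fld]])
    if (fld %in% smoker_only_fields()) {
      scope_obs <- scope_obs & df0$smoking_status %in% c("current", "former")
    }
    if (!any(scope_obs)) {
      stop("imputation error: field ", fld, " has no observed values",
           call. = FALSE)
    }
  }
  set.seed(seed)
  out <- vector("list", m)
  for (im in seq_len(m)) {
    df <- df0
    # initialize each missing value with a random observed draw
    for (fld in active) {
      mis <- masks[[fld]]
      pool <- df0[[fld]][!is.na(df0[[fld]])]
      df[[fld]][mis] <- sample(pool, sum(mis), replace = TRUE)
      if (fld == "quit_years") {
        cur <- mis & df$smoking_status == "current"
        df$quit_years[cur] <- 0
      }
    }
    iters <- if (length(active)) max_iter else 0
    for (it in seq_len(iters)) {
      for (fld in active) {
        df[[fld]][masks[[fld]]] <- NA
        df <- .impute_field(df, fld)
      }
    }
    out[[im]] <- structure(df, class = c("lr_cohort", "data.frame"),
                           provenance = c(attr(cohort, "provenance"),
                                          list(imputation = im,
                                               imputation_seed = seed)))
  }
  out
}

#' Pool estimates with Rubin's rules
#'
#' @param estimates per-imputation point estimates (length m, m >= 2).
#' @param variances per-imputation variances.
#' @return List with `estimate` (mean), `within` (W, mean variance),
#'   `between` (B, sample variance of estimates),
#'   `total` (T = W + (1 + 1/m) B) and `m`.
#' @export
rubin_pool <- function(estimates, variances) {
  m <- length(estimates)
  if (m < 2) {
    stop("pooling error: Rubin's rules need at least 2 imputations",
         call. = FALSE)
  }
  stopifnot(length(variances) == m)
  W <- mean(variances)
  B <- stats::var(estimates)
  list(estimate = mean(estimates), within = W, between = B,
       total = W + (1 + 1 / m) * B, m = m)
}
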