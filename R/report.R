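#' @title Validation reports
#' @description
#' Builds a discrimination/calibration report for one model on one
#' cohort stratum, pooling across imputations with Rubin's rules when
#' several imputed cohorts are supplied: the AUC is pooled on the
#' probability scale with its DeLong variance, the E/O ratio on the log
#' scale with the Poisson variance 1/O, and the calibration bins are
#' averaged cell-wise.
#' @name validation_report
NULL

#' Validate one model on one stratum
#'
#' @param cohorts a single `lr_cohort` or a list of imputed complete
#'   cohorts (same subjects).
#' @param spec an `lr_model_spec`.
#' @param stratum label recorded in the report (e.g. `"ever"`).
#' @param horizon evaluation horizon; defaults to the model's native
#'   horizon.  Risks are *not* rescaled when evaluating at a non-native
#'   horizon; the native-horizon risk is used as the score and the
#'   expectation, which is the documented default behaviour.
#' @param censor_handling passed to [outcome_at_horizon()].
#' @param level confidence level.
#' @return An `lr_validation_report` list: `model`, `stratum`,
#'   `horizon`, `n`, `auc`, `auc_ci`, `expected`, `observed`,
#'   `eo_ratio`, `eo_ci`, `calibration_bins`, `n_imputations`.
#' @export
validation_report <- function(cohorts, spec, stratum = "all",
                              horizon = NULL,
                              censor_handling = c("as_control",
                                                  "exclude"),
                              level = 0.95) {
  censor_handling <- match.arg(censor_handling)
  if (inherits(cohorts, "lr_cohort")) cohorts <- list(cohorts)
  if (is.null(horizon)) horizon <- spec$horizon_years
  m <- length(cohorts)
  z <- stats::qnorm(1 - (1 - level) / 2)
  auc_est <- auc_var <- log_eo <- numeric(m)
  e_sum <- o_sum <- numeric(m)
  bins_acc <- NULL
  for (i in seq_len(m)) {
    ch <- cohorts[[i]]
    oc <- outcome_at_horizon(ch, horizon, censor_handling)
    keep <- oc$keep
    pred <- predict_cohort(spec, ch)
    risks <- pred$risk[keep]
    y <- oc$outcome[keep]
    a <- auc_ci(risks, y, level = level)
    auc_est[i] <- a$auc
    auc_var[i] <- a$var
    eo <- eo_ratio(risks, y, level = level)
    log_eo[i] <- log(eo$ratio)
    e_sum[i] <- eo$expected
    o_sum[i] <- eo$observed
    b <- calibration_bins(risks, y, ids = ch$id[keep])
    bins_acc <- if (is.null(bins_acc)) b else {
      bins_acc[-1] <- bins_acc[-1] + b[-1]
      bins_acc
    }
  }
  bins <- bins_acc
  bins[-1] <- bins[-1] / m
  if (m >= 2) {
    pa <- rubin_pool(auc_est, auc_var)
    a_pt <- pa$estimate; a_se <- sqrt(pa$total)
    pe <- rubin_pool(log_eo, 1 / o_sum)
    eo_pt <- exp(pe$estimate); eo_se <- sqrt(pe$total)
  } else {
    a_pt <- auc_est[1]; a_se <- sqrt(auc_var[1])
    eo_pt <- exp(log_eo[1]); eo_se <- sqrt(1 / o_sum[1])
  }
  structure(list(
    model = spec$name, stratum = stratum, horizon = horizon,
    n = nrow(cohorts[[1]]),
    auc = a_pt,
    auc_ci = c(max(0, a_pt - z * a_se), min(1, a_pt + z * a_se)),
    expected = mean(e_sum), observed = mean(o_sum),
    eo_ratio = eo_pt,
    eo_ci = c(eo_pt * exp(-z * eo_se), eo_pt * exp(z * eo_se)),
    calibration_bins = bins,
    n_imputations = m), class = "lr_validation_report")
}

#' @export
print.lr_validation_report <- function(x, ...) {
  cat(sprintf("<validation> %s [%s, %gy, n=%d]  AUC %.3f (%.3f-%.3f)  E/O %.3f (%.3f-%.3f)\n",
              x$model, x$stratum, x$horizon, x$n, x$auc, x$auc_ci[1],
              x$auc_ci[2], x$eo_ratio, x$eo_ci[1], x$eo_ci[2]))
  invisible(x)
}
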