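# Residual metabolic rate: OLS baseline of log10 whole-organism metabolic
# rate on salinity, temperature and log10 body mass.

#' Fit the metabolic-rate baseline regression
#'
#' Ordinary least squares of `log10(mr_umol_h) ~ salinity + temp_meas +
#' log10_mass` on the records with an observed metabolic rate. The
#' residuals of this fit express whether an individual's metabolism is
#' higher or lower than expected for its size and water conditions, and
#' enter the main model as the `resid_mr` covariate.
#'
#' @param records A `pcrit_clean` data.frame from [standardize()] (or any
#'   data.frame with columns `mr_umol_h`, `salinity`, `temp_meas`,
#'   `log10_mass`). The fit is record-level, one row per measurement.
#' @return An object of class `mr_baseline`: list with `coefficients`
#'   (intercept, b_salinity, b_temp, b_logmass), `r_squared`, `n_used` and
#'   the underlying `lm` fit.
#' @export
fit_mr_baseline <- function(records) {
  ok <- !is.na(records$mr_umol_h)
  d <- records[ok, , drop = FALSE]
  if (any(d$mr_umol_h <= 0)) {
    stop("metabolic rate must be > 0 to log-transform", call. = FALSE)
  }
  if (nrow(d) < 6) {
    stop("need at least 6 records with observed metabolic rate ",
         "(4 parameters + 2)", call. = FALSE)
  }
  d$log10_mr <- log10(d$mr_umol_h)
  X <- cbind(1, d$salinity, d$temp_meas, d$log10_mass)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    cols <- c("intercept", "salinity", "temp_meas", "log10_mass")
    bad <- cols[setdiff(seq_len(ncol(X)), qr_x$pivot[seq_len(qr_x$rank)])]
    stop("rank-deficient baseline design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm(log10_mr ~ salinity + temp_meas + log10_mass, data = d)
  tss <- sum((d$log10_mr - mean(d$log10_mr))^2)
  r2 <- if (tss < 1e-12 * max(1, mean(d$log10_mr)^2)) {
    0 # constant response: nothing to explain
  } else {
    1 - sum(stats::residuals(fit)^2) / tss
  }
  out <- list(
    coefficients = stats::setNames(
      stats::coef(fit),
      c("intercept", "b_salinity", "b_temp", "b_logmass")
    ),
    r_squared = r2,
    n_used = nrow(d),
    fit = fit
  )
  class(out) <- "mr_baseline"
  out
}

#' @export
print.mr_baseline <- function(x, ...) {
  cat(sprintf(
    "<mr_baseline> n = %d, R^2 = %.3f\n", x$n_used, x$r_squared
  ))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predict baseline log10 metabolic rate
#'
#' @param baseline An `mr_baseline` fit.
#' @param records Data.frame with `salinity`, `temp_meas`, `log10_mass`.
#' @return Predicted log10 metabolic rate per record.
#' @export
predict_mr_baseline <- function(baseline, records) {
  b <- baseline$coefficients
  b[["intercept"]] + b[["b_salinity"]] * records$salinity +
    b[["b_temp"]] * records$temp_meas + b[["b_logmass"]] * records$log10_mass
}

#' Residual metabolic rate per record
#'
#' Observed minus predicted log10 metabolic rate. Records without a
#' measured metabolic rate get residual 0 (the baseline expectation) and
#' are flagged so a sensitivity refit can exclude them.
#'
#' @param records A `pcrit_clean` data.frame.
#' @param baseline An `mr_baseline` fit.
#' @return `records` with added columns `resid_mr` and `mr_imputed`.
#' @export
residual_mr <- function(records, baseline) {
  pred <- predict_mr_baseline(baseline, records)
  obs <- log10(records$mr_umol_h)
  res <- obs - pred
  imputed <- is.na(res)
  res[imputed] <- 0
  records$resid_mr <- res
  records$mr_imputed <- imputed
  records
}
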