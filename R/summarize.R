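# Posterior summaries: mean, central 95% interval, effective sample size,
# and the MAP-based Bayesian p-value.

#' MAP-based Bayesian p-value
#'
#' Ratio of the posterior density at zero to the density at the maximum a
#' posteriori point, estimated by kernel density. Values near 1 mean zero
#' is as plausible as the mode; values near 0 mean the posterior has moved
#' decisively away from zero. Used to screen predictors.
#'
#' @param draws Numeric vector of posterior draws.
#' @return p(MAP) in \[0, 1\].
#' @examples
#' p_map(rnorm(5000))       # ~1
#' p_map(rnorm(5000, 5, 1)) # ~0
#' @export
p_map <- function(draws) {
  stopifnot(is.numeric(draws), length(draws) > 10)
  d <- stats::density(draws, n = 2048)
  f0 <- if (0 < min(d$x) || 0 > max(d$x)) {
    0
  } else {
    stats::approx(d$x, d$y, xout = 0)$y
  }
  min(1, f0 / max(d$y))
}

#' Summarize a fitted model
#'
#' One row per parameter: posterior mean, central 95% credible interval,
#' effective sample size and p(MAP) (reported for fixed effects only; the
#' standard deviations are bounded away from zero by construction).
#'
#' @param fit A `pcrit_fit` from [fit_pcrit()].
#' @return Data.frame with columns `parameter`, `mean`, `q2.5`, `q97.5`,
#'   `effective_sampling`, `p_map`.
#' @export
summarize <- function(fit) {
  stopifnot(inherits(fit, "pcrit_fit"))
  d <- posterior_draws(fit)
  out <- data.frame(
    parameter = colnames(d),
    mean = colMeans(d),
    q2.5 = apply(d, 2, stats::quantile, 0.025),
    q97.5 = apply(d, 2, stats::quantile, 0.975),
    effective_sampling = round(unname(fit$ess[colnames(d)])),
    p_map = NA_real_,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  is_beta <- grepl("^b_", out$parameter)
  out$p_map[is_beta] <- apply(d[, is_beta, drop = FALSE], 2, p_map)
  bad <- out$q2.5 > out$mean | out$mean > out$q97.5
  if (any(bad)) {
    warning("posterior mean outside the central interval for: ",
            paste(out$parameter[bad], collapse = ", "), call. = FALSE)
  }
  out
}
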