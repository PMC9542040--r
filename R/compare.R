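# Candidate-model construction, PSIS-LOO cross-validation and model
# weights.

#' Build the candidate model set
#'
#' Deterministic list of competing models: a base model (temperature,
#' salinity, residual metabolic rate, relative acclimation temperature,
#' respirometry method) plus variants adding body mass and genome size with
#' and without their temperature interactions, the ontogenetic percent-mass
#' predictors (log10 percent of maximum mass, its quadratic, its
#' temperature interaction), a variant substituting maximum body mass for
#' genome size, and the final reduced model (relative acclimation and
#' respirometry dropped). Every spec carries a stable id and respects the
#' interaction-hierarchy rule.
#'
#' @param random Random terms given to every candidate (default both).
#' @param ... Passed to [model_spec()] (prior scales).
#' @return Named list of `pcrit_spec` objects.
#' @export
candidate_set <- function(random = c("phylo", "species"), ...) {
  base <- c("temp", "salinity", "resid_mr", "rel_acclim", "respirometry")
  mk <- function(id, fixed) model_spec(fixed, random = random, id = id, ...)
  list(
    base = mk("base", base),
    bm = mk("bm", c(base, "bm")),
    bm_x = mk("bm_x", c(base, "bm", "temp:bm")),
    gs = mk("gs", c(base, "gs")),
    gs_x = mk("gs_x", c(base, "gs", "temp:gs")),
    bm_gs = mk("bm_gs", c(base, "bm", "gs")),
    bm_gs_xbm = mk("bm_gs_xbm", c(base, "bm", "gs", "temp:bm")),
    bm_gs_xgs = mk("bm_gs_xgs", c(base, "bm", "gs", "temp:gs")),
    bm_gs_x2 = mk("bm_gs_x2", c(base, "bm", "gs", "temp:bm", "temp:gs")),
    pct = mk("pct", c(base, "log10_pct")),
    pct_q = mk("pct_q", c(base, "log10_pct", "log10_pct2")),
    pct_x = mk("pct_x", c(base, "log10_pct", "temp:log10_pct")),
    maxbm_subst = mk("maxbm_subst",
                     c(base, "bm", "log10_maxbm", "temp:bm",
                       "temp:log10_maxbm")),
    final = mk("final", c("temp", "gs", "bm", "salinity", "resid_mr",
                          "temp:gs", "temp:bm"))
  )
}

# Generalized-Pareto fit to sample exceedances (Zhang & Stephens 2009
# quasi-Bayes estimator, with the weak-prior shape regularization used in
# published PSIS implementations).
.gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  prior <- 3
  m <- 30L + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (prior * xstar)
  k_j <- vapply(theta, function(t) mean(log1p(-t * x)), 0)
  l_j <- n * (log(-theta / k_j) - k_j - 1)
  w_j <- exp(l_j - max(l_j))
  w_j <- w_j / sum(w_j)
  theta_hat <- sum(theta * w_j)
  k <- mean(log1p(-theta_hat * x))
  sigma <- -k / theta_hat
  k <- (k * n + 5) / (n + 10)
  list(k = k, sigma = sigma)
}

.qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

.logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Pareto-smooth one vector of log importance ratios; returns normalized
# log weights and the tail-shape diagnostic k.
.psis_smooth <- function(lr) {
  S <- length(lr)
  lr <- lr - max(lr)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  k <- NA_real_
  if (M >= 5) {
    ord <- order(lr, decreasing = TRUE)
    tail_idx <- ord[seq_len(M)]
    cutoff <- lr[ord[M + 1]]
    exceed <- exp(lr[tail_idx]) - exp(cutoff)
    if (stats::sd(exceed) > 0) {
      fit <- .gpd_fit(exceed)
      k <- fit$k
      pr <- (rank(lr[tail_idx]) - 0.5) / M
      sm <- log(.qgpd(pr, fit$k, fit$sigma) + exp(cutoff))
      lr[tail_idx] <- pmin(sm, 0) # truncate at the max raw weight (= 0)
    }
  }
  list(lw = lr - .logsumexp(lr), k = k)
}

#' PSIS-LOO cross-validation of a fitted model
#'
#' Approximate leave-one-out expected log predictive density from the
#' pointwise log-likelihood draws: per record, importance ratios
#' `1 / p(y_i | theta_s)` are stabilized by fitting a generalized Pareto
#' distribution to the upper tail (the largest `min(0.2 S, 3 sqrt(S))`
#' ratios) and replacing the tail by its fitted order statistics, truncated
#' at the largest raw ratio. The per-record Pareto shape `k` diagnoses
#' reliability; values above 0.7 are counted and reported with a warning.
#'
#' @param posterior A `pcrit_fit` (its `log_lik` matrix is used).
#' @return Object of class `pcrit_loo`: `elpd_loo`, `se`, `pointwise`
#'   (per-record elpd), `pareto_k`, `n_bad_k`, `lpd` (in-sample log
#'   pointwise predictive density), `n`.
#' @export
psis_loo <- function(posterior) {
  ll <- if (inherits(posterior, "pcrit_fit")) posterior$log_lik else posterior
  stopifnot(is.matrix(ll))
  if (all(apply(ll, 2, stats::sd) == 0)) {
    stop("degenerate posterior: identical log-likelihood draws", call. = FALSE)
  }
  n <- ncol(ll)
  S <- nrow(ll)
  elpd_i <- numeric(n)
  k_i <- numeric(n)
  lpd_i <- numeric(n)
  for (i in seq_len(n)) {
    sm <- .psis_smooth(-ll[, i])
    elpd_i[i] <- .logsumexp(sm$lw + ll[, i])
    k_i[i] <- sm$k
    lpd_i[i] <- .logsumexp(ll[, i]) - log(S)
  }
  n_bad <- sum(k_i > 0.7, na.rm = TRUE)
  if (n_bad > 0) {
    warning(n_bad, " record(s) with Pareto k > 0.7; PSIS-LOO may be ",
            "unreliable for them", call. = FALSE)
  }
  structure(list(
    elpd_loo = sum(elpd_i),
    se = sqrt(n * stats::var(elpd_i)),
    pointwise = elpd_i,
    pareto_k = k_i,
    n_bad_k = n_bad,
    lpd = sum(lpd_i),
    n = n
  ), class = "pcrit_loo")
}

#' @export
print.pcrit_loo <- function(x, ...) {
  cat(sprintf(
    "<pcrit_loo> elpd_loo = %.1f (se %.1f), n = %d, bad Pareto k: %d\n",
    x$elpd_loo, x$se, x$n, x$n_bad_k
  ))
  invisible(x)
}

#' Pseudo-BMA model weights from LOO results
#'
#' `w_m` proportional to `exp(elpd_m - max elpd)`, normalized; the simplest
#' scheme assigning each candidate a probability within the model set.
#'
#' @param results List of `pcrit_loo` objects fit to identical records.
#' @return Named numeric vector of weights summing to 1.
#' @export
loo_weights <- function(results) {
  stopifnot(length(results) >= 1)
  ns <- vapply(results, function(r) as.numeric(r$n), 0)
  if (length(unique(ns)) != 1) {
    stop("candidates were fit to different numbers of records",
         call. = FALSE)
  }
  elpd <- vapply(results, function(r) r$elpd_loo, 0)
  w <- exp(elpd - max(elpd))
  w / sum(w)
}

#' Fit and compare a set of candidate models
#'
#' Fits every candidate at the (light) screening MCMC settings, runs
#' [psis_loo()] on each, and tabulates elpd, its SE, the difference to the
#' best model, pseudo-BMA weights and the bad-Pareto-k count.
#'
#' @param records,C As in [fit_pcrit()].
#' @param specs Named list of `pcrit_spec` (default [candidate_set()]).
#' @param chains,iter,warmup Screening MCMC settings (default 2 chains of
#'   4,000 iterations, 1,000 warmup).
#' @param seed Base seed; candidate m uses `seed + m`.
#' @return List with `table` (data.frame sorted by weight), `fits`, `loos`.
#' @export
compare_models <- function(records, C, specs = candidate_set(),
                           chains = 2, iter = 4000, warmup = 1000,
                           seed = NULL) {
  fits <- list()
  loos <- list()
  for (m in seq_along(specs)) {
    id <- names(specs)[m]
    fits[[id]] <- fit_pcrit(records, specs[[m]], C, chains = chains,
                            iter = iter, warmup = warmup,
                            seed = if (!is.null(seed)) seed + m)
    loos[[id]] <- suppressWarnings(psis_loo(fits[[id]]))
  }
  w <- loo_weights(loos)
  elpd <- vapply(loos, function(r) r$elpd_loo, 0)
  tab <- data.frame(
    spec_id = names(specs),
    elpd_loo = elpd,
    se = vapply(loos, function(r) r$se, 0),
    delta_elpd = elpd - max(elpd),
    weight = w,
    n_bad_k = vapply(loos, function(r) r$n_bad_k, 0L),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  tab <- tab[order(-tab$weight), ]
  list(table = tab, fits = fits, loos = loos)
}
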