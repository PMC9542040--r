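# Variance partitioning of the fitted model and phylogenetic heritability.

#' Partition the modelled variance
#'
#' Per posterior draw, the finite-sample variance of the linear predictor
#' `X beta` over the records gives the marginal (fixed-effect) variance;
#' the phylogenetic and species variances are the squared random-effect
#' SDs (valid because the correlation matrix has unit diagonal, which is
#' asserted); the residual variance is the squared residual SD. Each
#' component divided by their sum yields draw-wise fractions that sum to 1.
#'
#' @param fit A `pcrit_fit` with both random effects.
#' @param shared Also compute the supplementary shared-variance diagnostic:
#'   per draw, the squared correlation between the record-level fixed
#'   predictor and the conditional-mean phylogenetic effect, i.e. how much
#'   of the fixed-effect signal is phylogenetically structured.
#' @return Object of class `pcrit_decomp`: `draws` (data.frame of
#'   per-draw fractions `f_marginal`, `f_phylo`, `f_species`,
#'   `f_residual` and `lambda`), `summary` (mean, median, 95% CI per
#'   quantity), and optionally `shared_mean`.
#' @export
partition <- function(fit, shared = FALSE) {
  stopifnot(inherits(fit, "pcrit_fit"))
  d <- posterior_draws(fit)
  need <- c("sd_phylo", "sd_species", "sd_resid")
  if (!all(need %in% colnames(d))) {
    stop("partition() needs a fit with phylo and species random effects",
         call. = FALSE)
  }
  if (!is.null(fit$C) && max(abs(diag(fit$C) - 1)) > 1e-8) {
    stop("correlation matrix lost its unit diagonal; phylogenetic variance ",
         "is not identifiable as sd_phylo^2", call. = FALSE)
  }
  bcols <- grep("^b_", colnames(d))
  fitted_fix <- d[, bcols, drop = FALSE] %*% t(fit$X)
  v_fix <- apply(fitted_fix, 1, stats::var)
  v_phy <- d[, "sd_phylo"]^2
  v_sp <- d[, "sd_species"]^2
  v_res <- d[, "sd_resid"]^2
  tot <- v_fix + v_phy + v_sp + v_res
  if (any(tot <= 0)) stop("zero total variance", call. = FALSE)
  fr <- data.frame(
    f_marginal = v_fix / tot,
    f_phylo = v_phy / tot,
    f_species = v_sp / tot,
    f_residual = v_res / tot,
    lambda = v_phy / (v_phy + v_sp + v_res)
  )
  sm <- t(vapply(fr, function(x) {
    c(mean = mean(x), median = stats::median(x),
      q2.5 = unname(stats::quantile(x, 0.025)),
      q97.5 = unname(stats::quantile(x, 0.975)))
  }, numeric(4)))
  out <- list(draws = fr, summary = as.data.frame(sm))
  if (shared) {
    if (is.null(fit$w_draws) || is.null(fit$C)) {
      stop("shared-variance diagnostic needs stored species effects and C",
           call. = FALSE)
    }
    out$shared_mean <- .shared_variance(fit, fitted_fix, d)
  }
  class(out) <- "pcrit_decomp"
  out
}

# Fraction of the fixed-effect variance aligned with phylogeny: squared
# correlation of X beta with the conditional-mean phylogenetic effect
# E[a | w] = sd_phylo^2 C G^{-1} w, averaged over draws.
.shared_variance <- function(fit, fitted_fix, d) {
  S <- length(fit$species)
  n_draw <- nrow(d)
  r2 <- numeric(n_draw)
  for (s in seq_len(n_draw)) {
    G <- d[s, "sd_phylo"]^2 * fit$C + diag(d[s, "sd_species"]^2, S)
    a <- d[s, "sd_phylo"]^2 * fit$C %*% solve(G, fit$w_draws[s, ])
    a_rec <- a[fit$species_idx]
    r2[s] <- if (stats::sd(a_rec) == 0 || stats::sd(fitted_fix[s, ]) == 0) {
      0
    } else {
      stats::cor(fitted_fix[s, ], a_rec)^2
    }
  }
  mean(r2)
}

#' @export
print.pcrit_decomp <- function(x, ...) {
  cat("<pcrit_decomp> posterior variance fractions:\n")
  print(round(x$summary, 3))
  if (!is.null(x$shared_mean)) {
    cat(sprintf("shared fixed/phylo variance (diagnostic): %.2f\n",
                x$shared_mean))
  }
  invisible(x)
}

#' Phylogenetic heritability
#'
#' Draw-wise `lambda = sd_phylo^2 / (sd_phylo^2 + sd_species^2 +
#' sd_resid^2)`: the proportion of the variance not explained by the fixed
#' effects that is attributable to phylogeny — the multilevel-model
#' equivalent of Pagel's lambda.
#'
#' @param fit A `pcrit_fit` with both random effects.
#' @return List with `mean`, `median`, `ci` (central 95%) and `draws`.
#' @export
heritability <- function(fit) {
  d <- posterior_draws(fit)
  need <- c("sd_phylo", "sd_species", "sd_resid")
  if (!all(need %in% colnames(d))) {
    stop("heritability() needs a fit with phylo and species random effects",
         call. = FALSE)
  }
  lam <- d[, "sd_phylo"]^2 /
    (d[, "sd_phylo"]^2 + d[, "sd_species"]^2 + d[, "sd_resid"]^2)
  list(
    mean = mean(lam),
    median = stats::median(lam),
    ci = unname(stats::quantile(lam, c(0.025, 0.975))),
    draws = lam
  )
}
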