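# Blocked Gibbs sampler for the phylogenetic multilevel model, with slice
# updates for the scale parameters and split-Rhat / ESS diagnostics.
#
# Model: y = X beta + w[species] + eps, where w = a + u combines the
# phylogenetic intercept a ~ MVN(0, sd_phylo^2 C) and the unstructured
# species intercept u ~ MVN(0, sd_species^2 I). beta and w have closed-form
# conditionals; the three scales are updated by univariate slice sampling
# on the log scale under half-Normal priors. Working in the eigenbasis of C
# makes each scale update O(S) instead of O(S^3).

# Univariate slice sampler (Neal 2003, stepping out + shrinkage).
.slice <- function(x0, logf, w = 1, max_expand = 30L, max_shrink = 100L) {
  f0 <- logf(x0)
  if (!is.finite(f0)) stop("slice sampler: non-finite density at start")
  logy <- f0 - stats::rexp(1)
  L <- x0 - w * stats::runif(1)
  R <- L + w
  k <- max_expand
  while (k > 0L && logf(L) > logy) { L <- L - w; k <- k - 1L }
  k <- max_expand
  while (k > 0L && logf(R) > logy) { R <- R + w; k <- k - 1L }
  for (i in seq_len(max_shrink)) {
    x1 <- stats::runif(1, L, R)
    if (logf(x1) >= logy) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
  x0
}

# log half-Normal(scale) prior for sigma = exp(l), including the Jacobian
# of the log transform.
.log_halfnorm_logscale <- function(l, scale) {
  s <- exp(l)
  -s^2 / (2 * scale^2) + l
}

#' Fit the Bayesian phylogenetic multilevel model
#'
#' Samples the posterior of the Gaussian multilevel model
#' `y = X beta + a\[sp\] + u\[sp\] + eps` with `a ~ MVN(0, sd_phylo^2 C)`,
#' `u ~ MVN(0, sd_species^2 I)` and iid Gaussian residuals, under
#' Normal(0, `prior_beta_sd`^2) priors on the coefficients and
#' half-Normal(0, `prior_sd_scale`) priors on the three standard
#' deviations. The response is left untransformed (kPa). Defaults mirror
#' the full analysis settings (3 chains of 15,000 iterations, half
#' warmup); model screening uses the lighter 2 x 4,000 / 1,000 setting.
#'
#' Convergence is reported per parameter as split-Rhat and effective sample
#' size; any split-Rhat above 1.01 flags the fit as non-converged (returned
#' with a warning, not discarded).
#'
#' @param records A `pcrit_clean` data.frame (with `resid_mr` if the spec
#'   uses it) carrying the response in `pcrit_kpa`.
#' @param spec A [model_spec()].
#' @param C Phylogenetic correlation matrix with species dimnames covering
#'   all species in `records`; required when the spec has the `phylo`
#'   random term.
#' @param chains,iter,warmup,thin MCMC settings; `iter` counts total
#'   iterations per chain including warmup.
#' @param seed Optional integer seed for reproducibility.
#' @param response Column holding the response (default `"pcrit_kpa"`).
#' @return Object of class `pcrit_fit`: `draws` (array kept-iterations x
#'   chains x parameters), `log_lik` (total draws x records), `w_draws`
#'   (total draws x species), `summary` via [summarize()], diagnostics
#'   (`rhat`, `ess`, `converged`), and the design bookkeeping needed by
#'   downstream modules.
#' @export
fit_pcrit <- function(records, spec, C = NULL, chains = 3, iter = 15000,
                      warmup = 7500, thin = 1, seed = NULL,
                      response = "pcrit_kpa") {
  stopifnot(inherits(spec, "pcrit_spec"))
  if (warmup >= iter) stop("warmup must be < iter", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  has_phylo <- "phylo" %in% spec$random
  has_species <- "species" %in% spec$random
  has_ranef <- has_phylo || has_species

  y <- records[[response]]
  n <- length(y)
  species_order <- NULL
  if (has_phylo) {
    if (is.null(C)) stop("spec has a phylo term but C is NULL", call. = FALSE)
    miss <- setdiff(unique(records$species), rownames(C))
    if (length(miss)) {
      stop("species missing from C: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    species_order <- intersect(rownames(C), unique(records$species))
    C <- C[species_order, species_order, drop = FALSE]
    check_correlation(C)
  }
  des <- build_design(records, spec, species_order = species_order)
  X <- des$X
  p <- ncol(X)
  S <- length(des$species)
  sidx <- des$species_idx
  n_j <- if (S > 0) tabulate(sidx, nbins = S) else integer(0)
  fsp <- if (S > 0) factor(sidx, seq_len(S)) else NULL

  # eigenbasis for the species-level covariance G = sp^2 C + ss^2 I
  if (has_phylo) {
    eg <- eigen(C, symmetric = TRUE)
    Q <- eg$vectors
    lam <- pmax(eg$values, 1e-12)
  } else if (has_ranef) {
    Q <- diag(1, S)
    lam <- rep(0, S) # G = ss^2 I
  }

  XtX <- crossprod(X)
  Xty <- drop(crossprod(X, y))
  if (has_ranef && S > 0) {
    ZtX <- rowsum(X, fsp)
    Zty <- drop(rowsum(y, fsp))
  }
  tau2 <- spec$prior_beta_sd^2
  sscale <- spec$prior_sd_scale
  beta_hat <- if (n > p) {
    drop(qr.coef(qr(X), y))
  } else {
    rep(0, p)
  }
  beta_hat[is.na(beta_hat)] <- 0

  n_keep <- floor((iter - warmup) / thin)
  par_names <- c(paste0("b_", colnames(X)),
                 if (has_phylo) "sd_phylo",
                 if (has_species) "sd_species",
                 "sd_resid")
  P <- length(par_names)
  draws <- array(NA_real_, c(n_keep, chains, P),
                 dimnames = list(NULL, NULL, par_names))
  log_lik <- matrix(NA_real_, n_keep * chains, n)
  w_draws <- if (has_ranef) matrix(NA_real_, n_keep * chains, S) else NULL

  for (ch in seq_len(chains)) {
    beta <- beta_hat + stats::rnorm(p, 0, 0.5)
    w <- rep(0, S)
    resid0 <- y - drop(X %*% beta)
    sr <- if (n > 1) max(stats::sd(resid0), 0.1) else 1
    sr <- sr * stats::runif(1, 0.5, 2)
    sp <- if (has_phylo) stats::runif(1, 0.5, 2) else 0
    ss <- if (has_species) stats::runif(1, 0.5, 2) else 0
    kept <- 0L
    for (it in seq_len(iter)) {
      if (has_ranef && S > 0) {
        # joint (beta, w) | scales: one Gaussian block, avoiding the slow
        # mixing of separate beta and species-effect updates
        g <- sp^2 * lam + ss^2
        Ginv <- Q %*% (t(Q) / g)
        Pmat <- matrix(0, p + S, p + S)
        Pmat[1:p, 1:p] <- XtX / sr^2 + diag(1 / tau2, p)
        Pmat[1:p, p + 1:S] <- t(ZtX) / sr^2
        Pmat[p + 1:S, 1:p] <- ZtX / sr^2
        Pmat[p + 1:S, p + 1:S] <- Ginv + diag(n_j / sr^2, S)
        cP <- chol(Pmat)
        rhs <- c(Xty, Zty) / sr^2
        mu <- backsolve(cP, backsolve(cP, rhs, transpose = TRUE))
        theta <- drop(mu) + drop(backsolve(cP, stats::rnorm(p + S)))
        beta <- theta[1:p]
        w <- theta[p + 1:S]
        mu_fix <- drop(X %*% beta)
        z2 <- drop(crossprod(Q, w))^2
      } else {
        Vinv <- XtX / sr^2 + diag(1 / tau2, p)
        cV <- chol(Vinv)
        bmean <- backsolve(cV, backsolve(cV, Xty / sr^2, transpose = TRUE))
        beta <- drop(bmean) + drop(backsolve(cV, stats::rnorm(p)))
        mu_fix <- drop(X %*% beta)
      }

      # sd_resid | beta, w
      resid <- y - mu_fix - (if (has_ranef && S > 0) w[sidx] else 0)
      ssr <- sum(resid^2)
      lr <- .slice(log(sr), function(l) {
        s <- exp(l)
        -n * l - ssr / (2 * s^2) + .log_halfnorm_logscale(l, sscale)
      }, w = 0.5)
      sr <- exp(lr)

      if (has_phylo && has_species) {
        lp <- .slice(log(sp), function(l) {
          g <- exp(2 * l) * lam + ss^2
          -0.5 * sum(log(g)) - 0.5 * sum(z2 / g) +
            .log_halfnorm_logscale(l, sscale)
        }, w = 0.5)
        sp <- exp(lp)
        ls <- .slice(log(ss), function(l) {
          g <- sp^2 * lam + exp(2 * l)
          -0.5 * sum(log(g)) - 0.5 * sum(z2 / g) +
            .log_halfnorm_logscale(l, sscale)
        }, w = 0.5)
        ss <- exp(ls)
      } else if (has_phylo) {
        lp <- .slice(log(sp), function(l) {
          g <- exp(2 * l) * lam
          -0.5 * sum(log(g)) - 0.5 * sum(z2 / g) +
            .log_halfnorm_logscale(l, sscale)
        }, w = 0.5)
        sp <- exp(lp)
      } else if (has_species) {
        ls <- .slice(log(ss), function(l) {
          s2 <- exp(2 * l)
          -0.5 * S * log(s2) - 0.5 * sum(z2 / s2) +
            .log_halfnorm_logscale(l, sscale)
        }, w = 0.5)
        ss <- exp(ls)
      }

      if (it > warmup && (it - warmup) %% thin == 0) {
        kept <- kept + 1L
        draws[kept, ch, ] <- c(beta,
                               if (has_phylo) sp,
                               if (has_species) ss,
                               sr)
        row <- (ch - 1L) * n_keep + kept
        log_lik[row, ] <- pointwise_loglik(beta, w, sr, y, X,
                                           if (S > 0) sidx else NULL)
        if (has_ranef) w_draws[row, ] <- w
      }
    }
  }

  rhat <- apply(draws, 3, function(m) .split_rhat(m))
  ess <- apply(draws, 3, function(m) .ess_multichain(m))
  converged <- all(is.na(rhat) | rhat < 1.01)
  if (!converged) {
    warning("split-Rhat > 1.01 for: ",
            paste(par_names[which(rhat >= 1.01)], collapse = ", "),
            " - fit flagged non-converged", call. = FALSE)
  }

  fit <- structure(list(
    draws = draws, log_lik = log_lik, w_draws = w_draws,
    par_names = par_names, spec = spec, X = X, y = y,
    species = des$species, species_idx = sidx, C = if (has_phylo) C,
    chains = chains, iter = iter, warmup = warmup, thin = thin,
    rhat = stats::setNames(rhat, par_names),
    ess = stats::setNames(ess, par_names),
    converged = converged,
    temp_range = if ("temp_meas" %in% names(records) && n > 0) {
      range(records$temp_meas)
    },
    seed = seed
  ), class = "pcrit_fit")
  fit
}

#' @export
print.pcrit_fit <- function(x, ...) {
  cat(sprintf(
    "<pcrit_fit '%s'> %d records, %d species | %d chains x %d kept draws | %s\n",
    x$spec$id, length(x$y), length(x$species), dim(x$draws)[2],
    dim(x$draws)[1],
    if (x$converged) "converged (all split-Rhat < 1.01)" else "NOT converged"
  ))
  print(summarize(x), digits = 3)
  invisible(x)
}

# Flatten the draws array to a (total draws x parameter) matrix.
#' Extract posterior draws as a matrix
#' @param fit A `pcrit_fit`.
#' @return Matrix, total kept draws (chains stacked) by parameter.
#' @export
posterior_draws <- function(fit) {
  d <- fit$draws
  out <- apply(d, 3, rbind)
  colnames(out) <- fit$par_names
  out
}

#' Posterior-mean fixed-effect vector
#' @param fit A `pcrit_fit`.
#' @return Named vector of coefficient posterior means, in design order.
#' @export
posterior_mean_beta <- function(fit) {
  d <- posterior_draws(fit)
  b <- grep("^b_", colnames(d), value = TRUE)
  stats::setNames(colMeans(d[, b, drop = FALSE]), sub("^b_", "", b))
}

# --- convergence diagnostics ------------------------------------------------

# biased autocovariance via FFT, as used in MCMC ESS estimators
.autocov <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  m <- stats::nextn(2L * n)
  f <- stats::fft(c(x, rep(0, m - n)))
  Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / m / n
}

.split_chains <- function(m) {
  n <- nrow(m)
  h <- floor(n / 2)
  cbind(m[seq_len(h), , drop = FALSE],
        m[(n - h + 1):n, , drop = FALSE])
}

#' Split-Rhat convergence diagnostic
#'
#' Classic potential-scale-reduction factor computed on split chains.
#'
#' @param m Matrix of draws, iterations by chains.
#' @return Rhat (NA for constant draws).
#' @keywords internal
.split_rhat <- function(m) {
  m <- .split_chains(m)
  n <- nrow(m)
  if (n < 4 || stats::sd(m) == 0) return(NA_real_)
  W <- mean(apply(m, 2, stats::var))
  B <- n * stats::var(colMeans(m))
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Multichain ESS with Geyer's initial monotone positive sequence,
# computed on split chains.
.ess_multichain <- function(m) {
  m <- .split_chains(m)
  n <- nrow(m)
  nc <- ncol(m)
  if (n < 4 || stats::sd(m) == 0) return(NA_real_)
  acov <- apply(m, 2, .autocov)
  W <- mean(acov[1, ]) * n / (n - 1)
  var_plus <- mean(acov[1, ]) + if (nc > 1) stats::var(colMeans(m)) else 0
  rho <- 1 - (W - rowMeans(acov) * n / (n - 1)) / var_plus
  n_pair <- floor(n / 2)
  ps <- rho[2 * seq_len(n_pair) - 1] + rho[2 * seq_len(n_pair)]
  neg <- which(ps < 0)
  if (length(neg)) ps <- ps[seq_len(neg[1] - 1)]
  if (length(ps) == 0) return(n * nc)
  ps <- cummin(ps)
  tau <- max(-1 + 2 * sum(ps), 1 / log10(n * nc + 10))
  min(n * nc / tau, n * nc * log10(n * nc))
}
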