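toy_clean <- function(n, n_species, seed = 1) {
  set.seed(seed)
  sp <- sprintf("s%03d", seq_len(n_species))
  idx <- sort(c(seq_len(n_species), sample(n_species, n - n_species,
                                           replace = TRUE)))
  data.frame(
    species = sp[idx],
    pcrit_kpa = rnorm(n, 6, 2),
    temp_meas = runif(n, 5, 32),
    rel_acclim = 0,
    salinity = sample(c(0, 35), n, replace = TRUE),
    log10_mass = rnorm(n, 1, 0.5),
    log10_gs = rnorm(n, 0, 0.25),
    log10_pct = rnorm(n, 0.7, 0.3),
    log10_maxbm = rnorm(n, 2, 0.5),
    resid_mr = rnorm(n, 0, 0.15),
    respirometry = sample(c("intermittent", "closed", "unknown"), n, TRUE),
    stringsAsFactors = FALSE
  )
}

test_that("model specs enforce the interaction hierarchy", {
  expect_error(model_spec(c("temp", "temp:gs")), "gs")
  expect_error(model_spec(c("gs", "temp:gs")), "temp")
  expect_error(model_spec("log10_pct2"), "log10_pct")
  expect_error(model_spec("wiggliness"), "unknown")
  expect_error(model_spec("temp", random = "herd"), "subset")
  s <- model_spec(c("temp", "gs", "temp:gs"))
  expect_true("intercept" %in% s$fixed)
})

test_that("design matrices follow the spec term order and encodings", {
  d <- toy_clean(10, 3)
  only_int <- build_design(d, model_spec(character(0)))
  expect_equal(unname(only_int$X[, 1]), rep(1, 10))
  expect_equal(ncol(only_int$X), 1)

  des <- build_design(d, model_spec(c("temp", "bm", "temp:bm",
                                      "respirometry")))
  expect_equal(des$X[, "temp:bm"], des$X[, "temp"] * des$X[, "bm"],
               ignore_attr = TRUE)
  # reference level: intermittent rows have zero dummies
  inter <- d$respirometry == "intermittent"
  expect_true(all(des$X[inter, c("respirometry_closed",
                                 "respirometry_unknown")] == 0))

  # grouping map: records split by species in order of first appearance
  d2 <- d[c(1, 2, 5), ]
  des2 <- build_design(d2, model_spec("temp"))
  expect_equal(length(des2$groups), length(unique(d2$species)))
  expect_equal(unlist(des2$groups[[1]], use.names = FALSE),
               which(d2$species == des2$species[1]))

  expect_error(build_design(d, model_spec("temp"),
                            species_order = c("s001")), "not in")
})

test_that("marginal likelihood matches the dense-matrix oracle", {
  for (case in 1:6) {
    set.seed(case)
    n <- sample(5:20, 1)
    S <- sample(3:5, 1)
    d <- toy_clean(n, S, seed = case + 50)
    spec <- model_spec(c("temp", "bm"))
    des <- build_design(d, spec)
    C <- correlation_matrix(
      rho_transform(grafen_heights(simulate_tree(S, seed = case)), 0.4)
    )
    dimnames(C) <- list(des$species, des$species)
    beta <- rnorm(3)
    sds <- runif(3, 0.3, 2)
    ours <- marginal_loglik(beta, sds[1], sds[2], sds[3], d$pcrit_kpa,
                            des$X, des$species_idx, C)
    oracle <- dense_mvn_loglik(beta, sds[1], sds[2], sds[3], d$pcrit_kpa,
                               des$X, des$species_idx, C)
    expect_equal(ours, oracle, tolerance = 1e-8)
    # identity correlation: phylo and species variances are exchangeable
    ident <- diag(S)
    dimnames(ident) <- dimnames(C)
    expect_equal(
      marginal_loglik(beta, sds[1], sds[2], sds[3], d$pcrit_kpa, des$X,
                      des$species_idx, ident),
      marginal_loglik(beta, sds[2], sds[1], sds[3], d$pcrit_kpa, des$X,
                      des$species_idx, ident),
      tolerance = 1e-8
    )
  }
})

test_that("zero random-effect scales collapse to iid regression density", {
  d <- toy_clean(12, 4)
  des <- build_design(d, model_spec("temp"))
  beta <- c(5, 0.1)
  iid <- sum(dnorm(d$pcrit_kpa, des$X %*% beta, 1.3, log = TRUE))
  expect_equal(
    marginal_loglik(beta, 0, 0, 1.3, d$pcrit_kpa, des$X, des$species_idx),
    iid, tolerance = 1e-10
  )
  expect_equal(
    sum(pointwise_loglik(beta, rep(0, 4), 1.3, d$pcrit_kpa, des$X,
                         des$species_idx)),
    iid, tolerance = 1e-10
  )
})

test_that("conditional and marginalized likelihoods agree when integrated", {
  # Monte-Carlo integration of the conditional over the random-effect prior
  # converges to the marginalized evaluation on a tiny dataset
  set.seed(8)
  d <- toy_clean(8, 3, seed = 8)
  spec <- model_spec("temp")
  des <- build_design(d, spec)
  C <- correlation_matrix(
    rho_transform(grafen_heights(simulate_tree(3, seed = 2)), 0.4)
  )
  dimnames(C) <- list(des$species, des$species)
  beta <- c(6, -0.02)
  sp <- 0.8; ss <- 0.5; sr <- 1.1
  G <- sp^2 * C + ss^2 * diag(3)
  L <- t(chol(G))
  M <- 200000
  ll <- vapply(seq_len(M), function(i) {
    w <- drop(L %*% rnorm(3))
    sum(pointwise_loglik(beta, w, sr, d$pcrit_kpa, des$X, des$species_idx))
  }, 0)
  mc <- log(mean(exp(ll - max(ll)))) + max(ll)
  exact <- marginal_loglik(beta, sp, ss, sr, d$pcrit_kpa, des$X,
                           des$species_idx, C)
  expect_equal(mc, exact, tolerance = 0.02)
})

test_that("fixed-effects-only fits recover OLS on clean linear data", {
  set.seed(21)
  d <- toy_clean(80, 10, seed = 21)
  d$pcrit_kpa <- 4 + 0.12 * d$temp_meas - 1.1 * d$log10_mass +
    rnorm(80, 0, 0.4)
  spec <- model_spec(c("temp", "bm"), random = character(0))
  fit <- fit_pcrit(d, spec, chains = 2, iter = 3000, warmup = 500, seed = 4)
  ols <- coef(lm(pcrit_kpa ~ temp_meas + log10_mass, data = d))
  sm <- summarize(fit)
  for (k in 1:3) {
    post_sd <- (sm$q97.5[k] - sm$q2.5[k]) / (2 * 1.96)
    se <- post_sd / sqrt(sm$effective_sampling[k])
    expect_lt(abs(sm$mean[k] - ols[k]), 5 * se + 0.05 * post_sd)
  }
  expect_true(fit$converged)
})

test_that("a data-free fit returns the prior", {
  empty <- toy_clean(10, 3)[0, ]
  spec <- model_spec("temp", random = character(0), prior_beta_sd = 10,
                     prior_sd_scale = 5)
  fit <- fit_pcrit(empty, spec, chains = 2, iter = 4000, warmup = 500,
                   seed = 9)
  d <- posterior_draws(fit)
  # beta ~ N(0, 10): mean within 0.1 prior SD, spread close to prior SD
  expect_lt(abs(mean(d[, "b_intercept"])), 1)
  expect_lt(abs(mean(d[, "b_temp"])), 1)
  expect_equal(sd(d[, "b_temp"]), 10, tolerance = 0.1)
  # sd_resid ~ half-Normal(5): mean 5 * sqrt(2/pi) ~ 3.99
  expect_equal(mean(d[, "sd_resid"]), 5 * sqrt(2 / pi), tolerance = 0.1)
})

test_that("record order does not change the posterior beyond MC error", {
  truth <- synthetic_truth(20, seed = 31)
  sim <- simulate_dataset(truth, 80, seed = 32)
  perm <- sample(nrow(sim$clean))
  f1 <- suppressWarnings(fit_pcrit(sim$clean, sim$spec, sim$C, chains = 2,
                                   iter = 2500, warmup = 500, seed = 5))
  f2 <- suppressWarnings(fit_pcrit(sim$clean[perm, ], sim$spec, sim$C,
                                   chains = 2, iter = 2500, warmup = 500,
                                   seed = 6))
  s1 <- summarize(f1)
  s2 <- summarize(f2)
  sd1 <- (s1$q97.5 - s1$q2.5) / (2 * 1.96)
  expect_true(all(abs(s1$mean - s2$mean) <
                    5 * sd1 / sqrt(pmax(s1$effective_sampling, 1)) +
                    0.05 * sd1))
})

test_that("absent species-level signal shrinks the phylo scale to zero", {
  # no species-level variation at all: the phylogenetic scale must
  # concentrate near zero rather than absorb residual noise
  truth <- synthetic_truth(40, sds = c(sd_phylo = 0, sd_species = 0,
                                       sd_resid = 1.67), seed = 77)
  sim <- simulate_dataset(truth, 300, seed = 78)
  fit <- suppressWarnings(fit_pcrit(sim$clean, sim$spec, sim$C, chains = 2,
                                    iter = 2500, warmup = 500, seed = 7))
  q50 <- median(posterior_draws(fit)[, "sd_phylo"])
  expect_lt(q50, 0.2 * truth$sds[["sd_resid"]])
})

test_that("posterior summaries report calibrated p(MAP) and ESS", {
  set.seed(13)
  expect_gt(p_map(rnorm(8000)), 0.8)
  expect_lt(p_map(rnorm(8000, 5, 0.1)), 0.001)
  # iid draws: effective sample size close to the raw draw count
  m <- matrix(rnorm(8000), 4000, 2)
  ess <- phylocrit:::.ess_multichain(m)
  expect_gt(ess, 8000 * 0.85)
  expect_lt(ess, 8000 * 1.15)
  # strongly autocorrelated draws: ESS far below the draw count
  x <- as.numeric(arima.sim(list(ar = 0.95), 4000))
  m2 <- cbind(x, as.numeric(arima.sim(list(ar = 0.95), 4000)))
  expect_lt(phylocrit:::.ess_multichain(m2), 2000)
  # split-Rhat flags disjoint chains
  bad <- cbind(rnorm(1000), rnorm(1000, 10))
  expect_gt(phylocrit:::.split_rhat(bad), 1.5)
  good <- matrix(rnorm(4000), 2000, 2)
  expect_lt(phylocrit:::.split_rhat(good), 1.01)
})

test_that("summaries keep monotone quantiles around the mean", {
  truth <- synthetic_truth(15, seed = 41)
  sim <- simulate_dataset(truth, 60, seed = 42)
  fit <- suppressWarnings(fit_pcrit(sim$clean, sim$spec, sim$C, chains = 2,
                                    iter = 1500, warmup = 500, seed = 8))
  sm <- summarize(fit)
  expect_true(all(sm$q2.5 <= sm$mean & sm$mean <= sm$q97.5))
  expect_true(all(c("b_intercept", "sd_phylo", "sd_species", "sd_resid")
                  %in% sm$parameter))
})
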