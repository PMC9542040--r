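test_that("simulated trees are pure-birth topologies with stable labels", {
  t2 <- simulate_tree(2, seed = 1)
  expect_equal(sort(t2$tip.label), c("s001", "s002"))
  expect_equal(t2$Nnode, 1)
  # determinism: same seed, identical Newick
  expect_identical(write_newick(simulate_tree(50, seed = 9)),
                   write_newick(simulate_tree(50, seed = 9)))
  expect_false(identical(write_newick(simulate_tree(50, seed = 9)),
                         write_newick(simulate_tree(50, seed = 10))))
  for (s in 1:25) {
    n <- sample(2:60, 1)
    expect_equal(length(simulate_tree(n, seed = s)$tip.label), n)
  }
})

test_that("generation is fully seed-deterministic", {
  s1 <- simulate_dataset(synthetic_truth(12, seed = 5), 40, seed = 6)
  s2 <- simulate_dataset(synthetic_truth(12, seed = 5), 40, seed = 6)
  expect_identical(s1$clean, s2$clean)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$traits, s2$traits)
  d1 <- tempfile(); d2 <- tempfile()
  write_sim(s1, d1); write_sim(s2, d2)
  for (f in c("database.csv", "traits.csv", "clean.csv", "tree.nwk")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("with all variances zero the response equals the linear predictor", {
  truth <- synthetic_truth(
    20, sds = c(sd_phylo = 0, sd_species = 0, sd_resid = 0), seed = 15
  )
  sim <- simulate_dataset(truth, 80, seed = 16)
  X <- build_design(sim$clean, sim$spec,
                    species_order = truth$tree$tip.label)$X
  mu <- drop(X %*% truth$beta)
  ok <- sim$clean$pcrit_kpa > 0.1 # clamped cells excluded
  expect_equal(sim$clean$pcrit_kpa[ok], mu[ok], tolerance = 1e-12)
  expect_equal(sim$truth$n_clamped, sum(mu < 0.1))
})

test_that("residual-only noise matches its generating variance", {
  truth <- synthetic_truth(
    50, sds = c(sd_phylo = 0, sd_species = 0, sd_resid = 1.67), seed = 21
  )
  sim <- simulate_dataset(truth, 2000, seed = 22)
  X <- build_design(sim$clean, sim$spec,
                    species_order = truth$tree$tip.label)$X
  resid <- sim$clean$pcrit_kpa - drop(X %*% truth$beta)
  expect_equal(var(resid[sim$clean$pcrit_kpa > 0.1]), 1.67^2,
               tolerance = 0.1)
})

test_that("phylogenetic effects carry the tree's correlation structure", {
  # 2000 replicate draws keep the sampling error of each of the 45
  # pairwise correlations (~0.022) well inside the 0.1 acceptance band
  tree <- simulate_tree(10, seed = 30)
  draws <- t(vapply(1:2000, function(r) {
    synthetic_truth(10, tree = tree, seed = 5000 + r)$a
  }, numeric(10)))
  C_emp <- cor(draws)
  C_true <- correlation_matrix(rho_transform(grafen_heights(tree), 0.4))
  expect_lt(max(abs(C_emp - C_true)), 0.1)
})

test_that("record allocation covers every species and the requested total", {
  truth <- synthetic_truth(25, seed = 35)
  sim <- simulate_dataset(truth, 90, seed = 36)
  expect_equal(nrow(sim$clean), 90)
  expect_setequal(unique(sim$clean$species), truth$tree$tip.label)
  expect_error(simulate_dataset(truth, 10), ">= number of species")
})

test_that("simulated raw tables feed the data-io and baseline modules", {
  truth <- synthetic_truth(12, seed = 45)
  sim <- simulate_dataset(truth, 60, seed = 46)
  d <- tempfile(); write_sim(sim, d)
  db <- suppressMessages(read_database(file.path(d, "database.csv"),
                                       file.path(d, "traits.csv")))
  expect_equal(nrow(db$records), 60)
  clean <- suppressWarnings(standardize(db))
  # kPa records standardize to themselves
  expect_equal(clean$pcrit_kpa, sim$clean$pcrit_kpa, tolerance = 1e-9)
  # the baseline regression recovers the generating plane well
  b <- fit_mr_baseline(clean)
  expect_gt(b$r_squared, 0.85)
  r <- residual_mr(clean, b)
  # recovered record-level residuals track the species-level truth
  obs <- tapply(r$resid_mr[!r$mr_imputed], r$species[!r$mr_imputed], mean)
  tru <- truth$resid_mr[names(obs)]
  expect_gt(cor(obs, tru), 0.6)
})

test_that("posterior precision improves when the sample doubles", {
  truth <- synthetic_truth(20, seed = 51)
  s_small <- simulate_dataset(truth, 100, seed = 52)
  s_big <- simulate_dataset(truth, 200, seed = 53)
  f_small <- suppressWarnings(fit_pcrit(s_small$clean, s_small$spec,
                                        s_small$C, chains = 2, iter = 1500,
                                        warmup = 500, seed = 54))
  f_big <- suppressWarnings(fit_pcrit(s_big$clean, s_big$spec, s_big$C,
                                      chains = 2, iter = 1500, warmup = 500,
                                      seed = 55))
  width <- function(f) {
    sm <- summarize(f)
    mean(sm$q97.5[grepl("^b_", sm$parameter)] -
           sm$q2.5[grepl("^b_", sm$parameter)])
  }
  expect_lt(width(f_big), width(f_small))
})

test_that("a null interaction is not declared significant", {
  beta0 <- c(intercept = 5.56, temp = -0.03, gs = -7.47, bm = -1.37,
             salinity = 0.08, resid_mr = 2.2, "temp:gs" = 0,
             "temp:bm" = 0.06)
  calm <- 0L
  n_rep <- 6
  for (r in seq_len(n_rep)) {
    truth <- synthetic_truth(30, beta = beta0, seed = 6000 + r)
    sim <- simulate_dataset(truth, 150, seed = 6100 + r)
    fit <- suppressWarnings(fit_pcrit(sim$clean, sim$spec, sim$C,
                                      chains = 2, iter = 1500, warmup = 500,
                                      seed = 6200 + r))
    sm <- summarize(fit)
    if (sm$p_map[sm$parameter == "b_temp:gs"] > 0.05) calm <- calm + 1L
  }
  expect_gte(calm, ceiling(0.8 * n_rep))
})
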