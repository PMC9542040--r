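# Synthetic-data generator: random trees, species traits and record-level
# Pcrit data drawn from the model's own generative process, with known
# truth for parameter-recovery experiments.

.default_beta <- c(
  intercept = 5.56, temp = -0.03, gs = -7.47, bm = -1.37,
  salinity = 0.08, resid_mr = 2.20, "temp:gs" = 0.44, "temp:bm" = 0.06
)
.default_sds <- c(sd_phylo = 2.22, sd_species = 1.02, sd_resid = 1.67)

.default_covariates <- list(
  temp_range = c(5, 32),        # degC; observed 25th/75th pct are 15 and 28
  mass_mean = 0.8,              # log10 g, species-level mean
  mass_species_sd = 0.7,        # between-species spread of log10 mass
  mass_record_sd = 0.25,        # within-species (ontogenetic) spread
  max_mass_margin = 0.6,        # log10 gap species mean -> species maximum
  gs_sd = 0.25,                 # log10 pg around 0
  marine_frac = 0.5,            # fraction of species in seawater
  marine_salinity = 30:36,      # PSU draw for marine records
  resid_mr_sd = 0.15,           # species-level residual metabolism
  acclim_same_frac = 0.8,       # records acclimated at the test temperature
  acclim_sd = 2,                # degC spread when acclimation differs
  baseline = c(intercept = 0.2, b_salinity = -0.002,
               b_temp = 0.015, b_logmass = 0.9),
  mr_noise_sd = 0.09,           # record-level log10 MR noise
  missing_mr_frac = 0.2         # records without a metabolic rate
)

#' Simulate a random tree topology
#'
#' Pure-birth (Yule) topology with tips labelled `s001..sNNN`. Branch
#' lengths are irrelevant downstream (Grafen heights replace them).
#'
#' @param n_tips Number of tips, >= 2.
#' @param seed Optional integer seed.
#' @return A `phylo` object.
#' @export
simulate_tree <- function(n_tips, seed = NULL) {
  stopifnot(n_tips >= 2)
  if (!is.null(seed)) set.seed(seed)
  tree <- if (n_tips == 2) {
    ape::read.tree(text = "(t1,t2);")
  } else {
    ape::rphylo(n_tips, birth = 1, death = 0)
  }
  tree$tip.label <- sprintf("s%03d", seq_len(n_tips))
  tree$edge.length <- NULL
  tree
}

#' Define a synthetic generating truth
#'
#' Fixes everything the generative model needs: a tree, the coefficient
#' vector, the three variance components, Grafen's rho, the realized
#' species-level random effects, species traits and the covariate
#' generation settings. Defaults reproduce the fitted world of the real
#' analysis: the coefficient means of the final model, sd_phylo = 2.22,
#' sd_species = 1.02, and sd_resid = 1.67 (which puts the phylogenetic
#' heritability at ~0.56).
#'
#' @param n_species Number of species (tree tips).
#' @param beta Named coefficient vector over terms of the final model.
#' @param sds Named vector `sd_phylo`, `sd_species`, `sd_resid`.
#' @param rho Grafen's rho used for the correlation matrix.
#' @param covariates Overrides for the covariate-generation settings; see
#'   the package vignette for the full list and rationale.
#' @param tree Optional `phylo` to reuse (tips must be `n_species`);
#'   default, a fresh pure-birth topology.
#' @param seed Integer seed; the truth is reproducible given it.
#' @return Object of class `pcrit_truth`.
#' @export
synthetic_truth <- function(n_species = 170, beta = .default_beta,
                            sds = .default_sds, rho = 0.4,
                            covariates = list(), tree = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cv <- utils::modifyList(.default_covariates, covariates)
  if (any(sds < 0)) stop("variance components must be >= 0", call. = FALSE)
  if (is.null(tree)) {
    tree <- simulate_tree(n_species)
  } else if (length(tree$tip.label) != n_species) {
    stop("supplied tree has a different number of tips than n_species",
         call. = FALSE)
  }
  gtree <- rho_transform(grafen_heights(tree), rho)
  C <- correlation_matrix(gtree)
  a <- if (sds[["sd_phylo"]] > 0) {
    drop(t(chol(C)) %*% stats::rnorm(n_species)) * sds[["sd_phylo"]]
  } else {
    rep(0, n_species)
  }
  u <- stats::rnorm(n_species, 0, sds[["sd_species"]])
  sp <- tree$tip.label
  mass_mean <- stats::rnorm(n_species, cv$mass_mean, cv$mass_species_sd)
  traits <- data.frame(
    species = sp,
    genome_size_pg = 10^stats::rnorm(n_species, 0, cv$gs_sd),
    max_body_mass_g = 10^(mass_mean + cv$max_mass_margin),
    stringsAsFactors = FALSE
  )
  structure(list(
    tree = tree, C = C, rho = rho, beta = beta, sds = sds,
    a = stats::setNames(a, sp), u = stats::setNames(u, sp),
    traits = traits, mass_mean = stats::setNames(mass_mean, sp),
    marine = stats::setNames(
      stats::runif(n_species) < cv$marine_frac, sp),
    resid_mr = stats::setNames(
      stats::rnorm(n_species, 0, cv$resid_mr_sd), sp),
    covariates = cv, seed = seed
  ), class = "pcrit_truth")
}

#' @export
print.pcrit_truth <- function(x, ...) {
  cat(sprintf(
    "<pcrit_truth> %d species | sd_phylo %.2f, sd_species %.2f, sd_resid %.2f | rho %.2f\n",
    length(x$a), x$sds[["sd_phylo"]], x$sds[["sd_species"]],
    x$sds[["sd_resid"]], x$rho
  ))
  invisible(x)
}

#' Simulate a record-level dataset from a synthetic truth
#'
#' Draws covariates from the documented emulation ranges (temperature
#' uniform on 5-32 degC, log10 body mass Gaussian around the species mean,
#' salinity 0 for freshwater species or 30-36 PSU for marine ones), builds
#' the final-model design, and generates
#' `y = X beta + a[sp] + u[sp] + N(0, sd_resid)`. Whole-organism metabolic
#' rates are generated from the baseline plane plus the species' residual
#' metabolism (plus record noise) so the baseline module can recover them;
#' a configurable fraction of records lacks a metabolic rate. Generated
#' Pcrit below 0.1 kPa (rare in the default regime) is clamped, and the
#' clamp count reported in the truth echo.
#'
#' @param truth A `pcrit_truth`.
#' @param n_records Total records, >= number of species; every species
#'   receives at least one record.
#' @param seed Optional integer seed (same seed, byte-identical tables).
#' @param records_per_species Optional function `(n_extra, n_species)`
#'   returning how the records beyond one-per-species are distributed;
#'   default multinomial with equal probabilities.
#' @return Object of class `pcrit_sim`: `clean` (analysis-ready
#'   `pcrit_clean` data.frame with the true `resid_mr` attached), `records`
#'   and `traits` (raw CSV schemas for the data-io module), `C`, and
#'   `truth` (augmented with `n_clamped`).
#' @export
simulate_dataset <- function(truth, n_records = 600, seed = NULL,
                             records_per_species = NULL) {
  stopifnot(inherits(truth, "pcrit_truth"))
  if (!is.null(seed)) set.seed(seed)
  cv <- truth$covariates
  sp <- truth$tree$tip.label
  S <- length(sp)
  if (n_records < S) {
    stop("n_records must be >= number of species", call. = FALSE)
  }
  extra <- if (is.null(records_per_species)) {
    drop(stats::rmultinom(1, n_records - S, rep(1 / S, S)))
  } else {
    records_per_species(n_records - S, S)
  }
  counts <- 1L + extra
  sidx <- rep(seq_len(S), counts)
  n <- length(sidx)

  temp <- stats::runif(n, cv$temp_range[1], cv$temp_range[2])
  log10_mass <- truth$mass_mean[sidx] +
    stats::rnorm(n, 0, cv$mass_record_sd)
  salinity <- ifelse(truth$marine[sidx],
                     sample(cv$marine_salinity, n, replace = TRUE), 0)
  same <- stats::runif(n) < cv$acclim_same_frac
  temp_acclim <- ifelse(same, temp, temp + stats::rnorm(n, 0, cv$acclim_sd))
  respirometry <- sample(c("intermittent", "closed", "unknown"), n,
                         replace = TRUE, prob = c(0.5, 0.4, 0.1))
  clean <- data.frame(
    species = sp[sidx],
    temp_meas = temp,
    rel_acclim = temp_acclim - temp,
    salinity = salinity,
    body_mass_g = 10^log10_mass,
    log10_mass = log10_mass,
    log10_gs = log10(truth$traits$genome_size_pg)[sidx],
    pct_max_mass = 100 * 10^log10_mass / truth$traits$max_body_mass_g[sidx],
    log10_maxbm = log10(truth$traits$max_body_mass_g)[sidx],
    resid_mr = unname(truth$resid_mr[sidx]),
    respirometry = respirometry,
    stringsAsFactors = FALSE
  )
  clean$log10_pct <- log10(clean$pct_max_mass)

  spec <- model_spec(names(truth$beta)[names(truth$beta) != "intercept"],
                     id = "final")
  X <- build_design(clean, spec, species_order = sp)$X
  stopifnot(identical(colnames(X), names(truth$beta)))
  y <- drop(X %*% truth$beta) + truth$a[sidx] + truth$u[sidx] +
    stats::rnorm(n, 0, truth$sds[["sd_resid"]])
  n_clamped <- sum(y < 0.1)
  y <- pmax(y, 0.1)
  clean$pcrit_kpa <- y

  b <- cv$baseline
  log10_mr <- b[["intercept"]] + b[["b_salinity"]] * salinity +
    b[["b_temp"]] * temp + b[["b_logmass"]] * log10_mass +
    truth$resid_mr[sidx] + stats::rnorm(n, 0, cv$mr_noise_sd)
  mr <- 10^log10_mr
  mr[stats::runif(n) < cv$missing_mr_frac] <- NA
  clean$mr_umol_h <- mr
  clean$mr_imputed <- is.na(mr)
  clean$salinity_imputed <- FALSE
  clean$source_id <- "synthetic"
  class(clean) <- c("pcrit_clean", "data.frame")

  records <- data.frame(
    species = clean$species, pcrit = clean$pcrit_kpa, pcrit_unit = "kPa",
    temp_meas = clean$temp_meas,
    temp_acclim = clean$temp_meas + clean$rel_acclim,
    salinity = clean$salinity, body_mass_g = clean$body_mass_g,
    metabolic_rate = clean$mr_umol_h, mr_unit = ifelse(
      is.na(clean$mr_umol_h), NA, "umol_O2_per_h"),
    respirometry = clean$respirometry, source_id = "synthetic",
    stringsAsFactors = FALSE
  )
  truth$n_clamped <- n_clamped
  structure(list(
    clean = clean, records = records, traits = truth$traits,
    C = truth$C, spec = spec, truth = truth
  ), class = "pcrit_sim")
}

#' @export
print.pcrit_sim <- function(x, ...) {
  cat(sprintf(
    "<pcrit_sim> %d records, %d species (%d Pcrit value(s) clamped at 0.1 kPa)\n",
    nrow(x$clean), length(unique(x$clean$species)), x$truth$n_clamped
  ))
  invisible(x)
}

#' Write a simulated dataset to CSV files plus a truth JSON
#'
#' Emits the same schemas the data-io module consumes (`database.csv`,
#' `traits.csv`), the analysis-ready table (`clean.csv`), and
#' `truth.json` with the generating parameters.
#'
#' @param sim A `pcrit_sim`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("database.csv", "traits.csv", "clean.csv",
                            "tree.nwk", "truth.json"))
  utils::write.csv(sim$records, paths[1], row.names = FALSE)
  utils::write.csv(sim$traits, paths[2], row.names = FALSE)
  utils::write.csv(sim$clean, paths[3], row.names = FALSE)
  writeLines(write_newick(sim$truth$tree), paths[4])
  jsonlite::write_json(
    list(beta = as.list(sim$truth$beta), sds = as.list(sim$truth$sds),
         rho = sim$truth$rho, seed = sim$truth$seed,
         n_clamped = sim$truth$n_clamped),
    paths[5], auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}

#' Parameter-recovery experiment
#'
#' Repeatedly simulates a dataset from a fresh truth (same coefficients
#' and variance components, new tree, random effects and covariates each
#' replicate), fits the generating model, and reports per-parameter
#' empirical 95%-interval coverage and posterior-mean bias.
#'
#' @param n_replicates Number of replicates.
#' @param n_species,n_records Problem size per replicate.
#' @param beta,sds,rho Generating values (defaults as in
#'   [synthetic_truth()]).
#' @param chains,iter,warmup MCMC settings per fit (reduced by default:
#'   2 chains of 2,000 with 500 warmup).
#' @param seed Base seed; replicate r derives seed + 1000 r.
#' @return Object of class `pcrit_recovery`: `report` (data.frame with
#'   `parameter`, `truth`, `coverage`, `bias`, `mean_sd`), plus the
#'   per-replicate posterior means, intervals and p(MAP) matrices.
#' @export
recovery_experiment <- function(n_replicates = 20, n_species = 60,
                                n_records = 300, beta = .default_beta,
                                sds = .default_sds, rho = 0.4,
                                chains = 2, iter = 2000, warmup = 500,
                                seed = 1) {
  true_vec <- c(stats::setNames(beta, paste0("b_", names(beta))), sds)
  pars <- names(true_vec)
  means <- lo <- hi <- pmap <-
    matrix(NA_real_, n_replicates, length(pars),
           dimnames = list(NULL, pars))
  for (r in seq_len(n_replicates)) {
    s <- seed + 1000L * r
    truth <- synthetic_truth(n_species, beta = beta, sds = sds, rho = rho,
                             seed = s)
    sim <- simulate_dataset(truth, n_records, seed = s + 1L)
    fit <- suppressWarnings(
      fit_pcrit(sim$clean, sim$spec, sim$C, chains = chains, iter = iter,
                warmup = warmup, seed = s + 2L)
    )
    sm <- summarize(fit)
    i <- match(pars, sm$parameter)
    means[r, ] <- sm$mean[i]
    lo[r, ] <- sm$q2.5[i]
    hi[r, ] <- sm$q97.5[i]
    pmap[r, ] <- sm$p_map[i]
  }
  report <- data.frame(
    parameter = pars,
    truth = unname(true_vec),
    coverage = colMeans(lo <= rep(true_vec, each = n_replicates) &
                          rep(true_vec, each = n_replicates) <= hi),
    bias = colMeans(means) - unname(true_vec),
    mean_sd = apply(means, 2, stats::sd),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  structure(list(report = report, means = means, lower = lo, upper = hi,
                 p_map = pmap),
            class = "pcrit_recovery")
}

#' @export
print.pcrit_recovery <- function(x, ...) {
  cat(sprintf("<pcrit_recovery> %d replicates\n", nrow(x$means)))
  print(transform(x$report,
                  truth = round(truth, 3), coverage = round(coverage, 2),
                  bias = round(bias, 3), mean_sd = round(mean_sd, 3)))
  invisible(x)
}
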