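# Shared fixtures and independent oracles for the test suite.

# --- CSV fixtures, built in code -------------------------------------------

write_db_fixture <- function(rows, dir = tempdir()) {
  # rows: data.frame in the raw database schema
  path <- file.path(dir, "db.csv")
  utils::write.csv(rows, path, row.names = FALSE)
  path
}

db_row <- function(species = "Danio rerio", pcrit = 5, pcrit_unit = "kPa",
                   temp_meas = 25, temp_acclim = 25, salinity = "0",
                   body_mass_g = 1, metabolic_rate = NA, mr_unit = NA,
                   respirometry = "intermittent", source_id = "ref1") {
  data.frame(species = species, pcrit = pcrit, pcrit_unit = pcrit_unit,
             temp_meas = temp_meas, temp_acclim = temp_acclim,
             salinity = salinity, body_mass_g = body_mass_g,
             metabolic_rate = metabolic_rate, mr_unit = mr_unit,
             respirometry = respirometry, source_id = source_id,
             stringsAsFactors = FALSE)
}

traits_row <- function(species = "Danio rerio", genome_size_pg = 1.7,
                       max_body_mass_g = 2) {
  data.frame(species = species, genome_size_pg = genome_size_pg,
             max_body_mass_g = max_body_mass_g, stringsAsFactors = FALSE)
}

write_traits_fixture <- function(rows, dir = tempdir()) {
  path <- file.path(dir, "traits.csv")
  utils::write.csv(rows, path, row.names = FALSE)
  path
}

read_fixture_db <- function(db_rows, trait_rows) {
  d <- tempfile("fix")
  dir.create(d)
  suppressMessages(read_database(
    write_db_fixture(db_rows, d), write_traits_fixture(trait_rows, d)
  ))
}

# --- dense multivariate-normal oracle --------------------------------------

# brute-force log density of y ~ MVN(X beta, sr^2 I + Z G Z'),
# built entirely from dense n x n matrices
dense_mvn_loglik <- function(beta, sp, ss, sr, y, X, sidx, C) {
  n <- length(y)
  S <- max(sidx)
  Z <- matrix(0, n, S)
  Z[cbind(seq_len(n), sidx)] <- 1
  G <- sp^2 * C + ss^2 * diag(S)
  V <- sr^2 * diag(n) + Z %*% G %*% t(Z)
  r <- y - drop(X %*% beta)
  ld <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  -0.5 * (n * log(2 * pi) + ld + drop(t(r) %*% solve(V, r)))
}

# --- path-summing phylogenetic covariance oracle ---------------------------

# covariance of tips i, j = sum of branch lengths shared on the paths
# root -> i and root -> j, walked edge by edge on the tree structure
path_sum_vcv <- function(tree) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  parent <- integer(max(tree$edge))
  elen <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  path_edges <- function(tip) {
    nodes <- integer(0)
    v <- tip
    while (v != root) {
      nodes <- c(nodes, v) # edge above v
      v <- parent[v]
    }
    nodes
  }
  paths <- lapply(seq_len(n_tip), path_edges)
  C <- matrix(0, n_tip, n_tip)
  for (i in seq_len(n_tip)) {
    for (j in seq_len(n_tip)) {
      shared <- intersect(paths[[i]], paths[[j]])
      C[i, j] <- sum(elen[shared])
    }
  }
  dimnames(C) <- list(tree$tip.label, tree$tip.label)
  C
}

# --- minimal fake posterior for deterministic downstream tests -------------

# builds a pcrit_fit whose draws are supplied directly, so summaries and
# projections can be tested against closed-form expectations
make_fake_fit <- function(draw_matrix, spec, X = NULL, y = NULL, C = NULL,
                          species = NULL, species_idx = NULL,
                          temp_range = NULL, chains = 2) {
  stopifnot(nrow(draw_matrix) %% chains == 0)
  n_keep <- nrow(draw_matrix) / chains
  draws <- array(NA_real_, c(n_keep, chains, ncol(draw_matrix)),
                 dimnames = list(NULL, NULL, colnames(draw_matrix)))
  for (ch in seq_len(chains)) {
    draws[, ch, ] <- draw_matrix[(ch - 1) * n_keep + seq_len(n_keep), ]
  }
  ess <- apply(draws, 3, phylocrit:::.ess_multichain)
  rhat <- apply(draws, 3, phylocrit:::.split_rhat)
  structure(list(
    draws = draws, log_lik = NULL, w_draws = NULL,
    par_names = colnames(draw_matrix), spec = spec, X = X, y = y,
    species = species, species_idx = species_idx, C = C,
    chains = chains, iter = n_keep, warmup = 0, thin = 1,
    ess = stats::setNames(ess, colnames(draw_matrix)),
    rhat = stats::setNames(rhat, colnames(draw_matrix)),
    converged = TRUE, temp_range = temp_range, seed = NULL
  ), class = "pcrit_fit")
}

# fake fit with point-mass draws at a given coefficient vector
point_mass_fit <- function(beta, spec, temp_range = c(5, 32)) {
  nm <- c(paste0("b_", names(beta)), "sd_phylo", "sd_species", "sd_resid")
  m <- matrix(rep(c(unname(beta), 1, 1, 1), each = 40), 40,
              dimnames = list(NULL, nm))
  # tiny jitter keeps density estimates finite without moving the mean
  set.seed(99)
  m <- m + stats::rnorm(length(m), 0, 1e-8)
  make_fake_fit(m, spec, temp_range = temp_range)
}

table1_beta <- c(
  intercept = 5.56, temp = -0.03, gs = -7.47, bm = -1.37,
  salinity = 0.08, resid_mr = 2.20, "temp:gs" = 0.44, "temp:bm" = 0.06
)

final_spec <- function() {
  model_spec(c("temp", "gs", "bm", "salinity", "resid_mr",
               "temp:gs", "temp:bm"), id = "final")
}
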