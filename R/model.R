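# Model specification, design-matrix construction and likelihood for the
# phylogenetic multilevel model of Pcrit.

.fixed_terms <- c(
  "intercept", "temp", "gs", "bm", "salinity", "resid_mr", "rel_acclim",
  "respirometry", "log10_pct", "log10_pct2", "log10_maxbm",
  "temp:gs", "temp:bm", "temp:log10_pct", "temp:log10_maxbm"
)
.term_main <- list(
  "temp:gs" = c("temp", "gs"),
  "temp:bm" = c("temp", "bm"),
  "temp:log10_pct" = c("temp", "log10_pct"),
  "temp:log10_maxbm" = c("temp", "log10_maxbm"),
  "log10_pct2" = "log10_pct"
)

#' Specify a candidate model
#'
#' A model is a set of fixed-effect terms, a set of random intercepts
#' (phylogenetic and/or unstructured species), and Gaussian prior scales.
#' Interactions (and the quadratic percent-mass term) require their main
#' effects, mirroring standard model-hierarchy practice.
#'
#' Term vocabulary: `intercept`, `temp` (measurement temperature, degC),
#' `gs` (log10 genome size, pg), `bm` (log10 body mass, g), `salinity`
#' (PSU), `resid_mr` (residual log10 metabolic rate), `rel_acclim`
#' (acclimation minus measurement temperature, degC), `respirometry`
#' (dummy-coded against reference level "intermittent"), `log10_pct`
#' (log10 percent of maximum body mass), `log10_pct2` (its square),
#' `log10_maxbm` (log10 maximum body mass, g), and the temperature
#' interactions `temp:gs`, `temp:bm`, `temp:log10_pct`,
#' `temp:log10_maxbm`.
#'
#' @param fixed Character vector of fixed terms (order preserved);
#'   `"intercept"` is added if absent.
#' @param random Subset of `c("phylo", "species")`.
#' @param id Stable identifier for reports; defaults to a terse composite.
#' @param prior_beta_sd Prior SD of the Normal(0, .) priors on all fixed
#'   coefficients, on the natural covariate scales (default 10; weakly
#'   informative for a response in kPa).
#' @param prior_sd_scale Scale of the half-Normal(0, .) priors on the three
#'   standard deviations (default 5).
#' @return Object of class `pcrit_spec`.
#' @export
model_spec <- function(fixed, random = c("phylo", "species"), id = NULL,
                       prior_beta_sd = 10, prior_sd_scale = 5) {
  fixed <- unique(c("intercept", fixed))
  unknown <- setdiff(fixed, .fixed_terms)
  if (length(unknown)) {
    stop("unknown fixed term(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  random <- unique(random)
  if (length(setdiff(random, c("phylo", "species")))) {
    stop("random terms must be a subset of {phylo, species}", call. = FALSE)
  }
  for (tm in intersect(fixed, names(.term_main))) {
    need <- setdiff(.term_main[[tm]], fixed)
    if (length(need)) {
      stop("term '", tm, "' requires main effect(s): ",
           paste(need, collapse = ", "), call. = FALSE)
    }
  }
  if (is.null(id)) {
    id <- paste(setdiff(fixed, "intercept"), collapse = "+")
    if (id == "") id <- "intercept_only"
  }
  structure(
    list(id = id, fixed = fixed, random = random,
         prior_beta_sd = prior_beta_sd, prior_sd_scale = prior_sd_scale),
    class = "pcrit_spec"
  )
}

#' @export
print.pcrit_spec <- function(x, ...) {
  cat(sprintf(
    "<pcrit_spec '%s'> fixed: %s | random: %s\n",
    x$id, paste(x$fixed, collapse = ", "),
    if (length(x$random)) paste(x$random, collapse = ", ") else "none"
  ))
  invisible(x)
}

.term_columns <- function(term, d) {
  switch(term,
    intercept = matrix(rep(1, nrow(d)), ncol = 1,
                       dimnames = list(NULL, "intercept")),
    temp = cbind(temp = d$temp_meas),
    gs = cbind(gs = d$log10_gs),
    bm = cbind(bm = d$log10_mass),
    salinity = cbind(salinity = d$salinity),
    resid_mr = cbind(resid_mr = d$resid_mr),
    rel_acclim = cbind(rel_acclim = d$rel_acclim),
    respirometry = {
      f <- factor(d$respirometry, levels = .respirometry_levels)
      if (anyNA(f)) stop("unknown respirometry level", call. = FALSE)
      cbind(respirometry_closed = as.numeric(f == "closed"),
            respirometry_unknown = as.numeric(f == "unknown"))
    },
    log10_pct = cbind(log10_pct = d$log10_pct),
    log10_pct2 = cbind(log10_pct2 = d$log10_pct^2),
    log10_maxbm = cbind(log10_maxbm = d$log10_maxbm),
    "temp:gs" = cbind("temp:gs" = d$temp_meas * d$log10_gs),
    "temp:bm" = cbind("temp:bm" = d$temp_meas * d$log10_mass),
    "temp:log10_pct" = cbind("temp:log10_pct" = d$temp_meas * d$log10_pct),
    "temp:log10_maxbm" =
      cbind("temp:log10_maxbm" = d$temp_meas * d$log10_maxbm),
    stop("unknown term: ", term, call. = FALSE)
  )
}

#' Build the design matrix and species grouping for a model
#'
#' Columns appear in spec order; the categorical respirometry method is
#' dummy-coded against the reference level `"intermittent"`. The species
#' index maps each record to its row in the phylogenetic correlation
#' matrix.
#'
#' @param records A `pcrit_clean` data.frame (with `resid_mr` attached by
#'   [residual_mr()] when the spec uses it).
#' @param spec A `pcrit_spec`.
#' @param species_order Optional character vector fixing the species order
#'   (e.g. `rownames(C)`); an error is raised for records from species not
#'   listed. Default: order of first appearance.
#' @param check_species Internal; disable the species bookkeeping for
#'   prediction-grid use.
#' @return List with `X` (n x p design matrix), `species` (ordered unique
#'   species), `species_idx` (record -> species row) and `groups`
#'   (species -> record indices).
#' @export
build_design <- function(records, spec, species_order = NULL,
                         check_species = TRUE) {
  stopifnot(inherits(spec, "pcrit_spec"))
  need <- setdiff(c("resid_mr")[("resid_mr" %in% spec$fixed)],
                  names(records))
  if (length(need)) {
    stop("records lack column(s) ", paste(need, collapse = ", "),
         "; run residual_mr() first", call. = FALSE)
  }
  X <- do.call(cbind, lapply(spec$fixed, .term_columns, d = records))
  rownames(X) <- NULL
  if (!check_species) {
    return(list(X = X, species = NULL, species_idx = NULL, groups = NULL))
  }
  species <- if (is.null(species_order)) {
    unique(records$species)
  } else {
    unseen <- setdiff(unique(records$species), species_order)
    if (length(unseen)) {
      stop("records from species not in species_order: ",
           paste(unseen, collapse = ", "), call. = FALSE)
    }
    species_order
  }
  idx <- match(records$species, species)
  list(
    X = X,
    species = species,
    species_idx = idx,
    groups = split(seq_len(nrow(records)), factor(idx, seq_along(species)))
  )
}

#' Pointwise conditional log-likelihood
#'
#' Per-record Gaussian log density given the fixed effects and the realized
#' species-level effects: `y_i ~ N(x_i' beta + w[species_i], sd_resid^2)`,
#' where `w` is the sum of the phylogenetic and unstructured species
#' intercepts. This is the vector PSIS-LOO consumes.
#'
#' @param beta Fixed-effect vector (length `ncol(X)`).
#' @param w Combined species-level effects (length = number of species);
#'   use `numeric(0)` with `species_idx = NULL` for a fixed-effects model.
#' @param sd_resid Residual SD, > 0.
#' @param y,X,species_idx Response, design matrix and record -> species map.
#' @return Numeric vector of per-record log densities.
#' @export
pointwise_loglik <- function(beta, w, sd_resid, y, X, species_idx = NULL) {
  mu <- drop(X %*% beta)
  if (!is.null(species_idx) && length(w)) mu <- mu + w[species_idx]
  stats::dnorm(y, mu, sd_resid, log = TRUE)
}

#' Marginal log-likelihood of the mixed model
#'
#' Log density of `y ~ MVN(X beta, sd_resid^2 I + Z G Z')` with
#' `G = sd_phylo^2 C + sd_species^2 I`, the random effects integrated out
#' analytically. Computed through the Woodbury identity and the matrix
#' determinant lemma on the species-level (S x S) matrices, so the cost is
#' O(S^3) rather than O(n^3).
#'
#' @param beta,sd_phylo,sd_species,sd_resid Model parameters.
#' @param y,X,species_idx Data and record -> species map.
#' @param C Phylogenetic correlation matrix in species order (set
#'   `sd_phylo = 0` and `C = NULL` for a model without the phylogenetic
#'   effect).
#' @return A single log-likelihood value.
#' @export
marginal_loglik <- function(beta, sd_phylo, sd_species, sd_resid,
                            y, X, species_idx, C = NULL) {
  n <- length(y)
  r <- y - drop(X %*% beta)
  s2 <- sd_resid^2
  if ((sd_phylo == 0 && sd_species == 0) || is.null(species_idx)) {
    return(sum(stats::dnorm(r, 0, sd_resid, log = TRUE)))
  }
  S <- max(species_idx)
  if (sd_phylo > 0) {
    if (is.null(C)) stop("C required when sd_phylo > 0", call. = FALSE)
    check_correlation(C)
    G <- sd_phylo^2 * C + diag(sd_species^2, S)
  } else {
    G <- diag(sd_species^2, S)
  }
  n_j <- tabulate(species_idx, nbins = S)
  t_j <- drop(rowsum(r, factor(species_idx, seq_len(S))))
  cG <- chol(G)
  Ginv <- chol2inv(cG)
  M <- Ginv + diag(n_j / s2, S)
  cM <- chol(M)
  logdet <- n * log(s2) + 2 * sum(log(diag(cG))) + 2 * sum(log(diag(cM)))
  u <- backsolve(cM, backsolve(cM, t_j, transpose = TRUE))
  quad <- sum(r^2) / s2 - sum(t_j * u) / s2^2
  -0.5 * (n * log(2 * pi) + logdet + quad)
}
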