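# Tree handling: Newick parsing (via ape), Grafen heights, rho rescaling,
# and the phylogenetic correlation matrix used as random-effect covariance.

#' Parse a Newick string into a tree
#'
#' Thin wrapper over [ape::read.tree()] that checks bracket balance first
#' (reporting the character offset of the first mismatch) and discards any
#' branch lengths in the input: downstream, branch lengths are always
#' reassigned by [grafen_heights()], so input lengths are irrelevant and
#' keeping them would invite accidental use.
#'
#' @param text A Newick string (polytomies allowed; branch lengths
#'   optional and ignored).
#' @return An [ape::read.tree()] `phylo` object without edge lengths.
#' @examples
#' parse_newick("((A,B),C);")
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  depth <- 0L
  chars <- strsplit(text, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) {
      stop("malformed Newick: unmatched ')' at character ", i, call. = FALSE)
    }
  }
  if (depth != 0L) {
    stop("malformed Newick: ", depth, " unclosed '(' at character ",
         nchar(text), call. = FALSE)
  }
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(tree)) stop("malformed Newick string", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    stop("tip labels are not unique", call. = FALSE)
  }
  tree$edge.length <- NULL
  tree
}

#' Write a tree to a Newick string
#'
#' @param tree A `phylo` object.
#' @return Newick string.
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree)
}

#' Prune a tree to a set of species
#'
#' Induced subtree on `keep`; internal nodes left with a single child are
#' suppressed (ape's behaviour).
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of tip labels to retain.
#' @return Pruned `phylo`.
#' @export
prune <- function(tree, keep) {
  keep <- unique(keep)
  if (length(keep) == 0) stop("keep set is empty", call. = FALSE)
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing)) {
    stop("species not in tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- ape::keep.tip(tree, keep)
  attr(out, "node_height") <- NULL
  out
}

# number of descendant tips below each node (tips themselves count 1)
.descendant_tip_counts <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  counts <- c(rep(1L, n_tip), rep(0L, tree$Nnode))
  # postorder: children before parents
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(edges))) {
    counts[edges[i, 1]] <- counts[edges[i, 1]] + counts[edges[i, 2]]
  }
  stopifnot(counts[n_tip + 1L] == n_tip) # root carries all tips
  counts
}

#' Assign Grafen node heights and branch lengths
#'
#' Sets the height of every node to the number of its descendant tips minus
#' one, normalized by `n - 1` so tips sit at height 0 and the root at
#' height 1; branch lengths are parent height minus child height. This
#' yields an ultrametric tree on an arbitrary (relative) timescale, the
#' standard fallback when divergence times are unknown.
#'
#' @param tree A rooted `phylo` with at least 2 tips.
#' @return The tree with `edge.length` set and a `node_height` attribute
#'   (vector over tip then internal node indices).
#' @examples
#' tr <- grafen_heights(parse_newick("((A,B),C);"))
#' attr(tr, "node_height")  # tips 0, inner node 0.5, root 1
#' @export
grafen_heights <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  if (n_tip < 2) stop("tree must have at least 2 tips", call. = FALSE)
  counts <- .descendant_tip_counts(tree)
  h <- (counts - 1) / (n_tip - 1)
  tree$edge.length <- h[tree$edge[, 1]] - h[tree$edge[, 2]]
  attr(tree, "node_height") <- h
  tree
}

#' Rescale node heights by Grafen's rho
#'
#' Raises every (normalized) node height to the power `rho` and recomputes
#' branch lengths. For `rho < 1` all internal heights in (0, 1) increase,
#' stretching branches near the tips and thereby up-weighting recent
#' evolutionary divergence; `rho = 1` is the identity.
#'
#' @param tree A tree with heights assigned by [grafen_heights()].
#' @param rho Positive exponent; the analysis default is 0.4.
#' @return Tree with transformed heights and branch lengths.
#' @export
rho_transform <- function(tree, rho = 0.4) {
  h <- attr(tree, "node_height")
  if (is.null(h)) {
    stop("tree has no assigned heights; call grafen_heights() first",
         call. = FALSE)
  }
  if (!is.numeric(rho) || length(rho) != 1 || rho <= 0) {
    stop("rho must be a single positive number", call. = FALSE)
  }
  h <- h^rho
  tree$edge.length <- h[tree$edge[, 1]] - h[tree$edge[, 2]]
  attr(tree, "node_height") <- h
  tree
}

#' Phylogenetic correlation matrix
#'
#' Builds the species-by-species correlation matrix implied by a
#' height-assigned tree under a Brownian-motion model: the covariance of
#' two tips is the shared root-to-MRCA path length, which for normalized
#' heights equals `1 - h(mrca(i, j))`; the diagonal is 1. The matrix is the
#' covariance structure of the phylogenetic random effect, so its unit
#' diagonal makes the phylogenetic variance parameter directly
#' interpretable.
#'
#' @param tree A tree processed by [grafen_heights()] (and usually
#'   [rho_transform()]).
#' @return Symmetric positive-semidefinite matrix with species dimnames.
#' @examples
#' tr <- rho_transform(grafen_heights(parse_newick("((A,B),C);")), 1)
#' correlation_matrix(tr)  # C[A,B] = 0.5, C[A,C] = 0
#' @export
correlation_matrix <- function(tree) {
  h <- attr(tree, "node_height")
  if (is.null(h)) {
    stop("tree has no assigned heights; call grafen_heights() first",
         call. = FALSE)
  }
  n_tip <- length(tree$tip.label)
  mrca_nodes <- ape::mrca(tree)
  C <- 1 - matrix(h[mrca_nodes], n_tip, n_tip)
  diag(C) <- 1
  dimnames(C) <- list(tree$tip.label, tree$tip.label)
  C
}

#' Build the analysis correlation matrix from a Newick tree and species list
#'
#' One-call pipeline: parse, drop data species absent from the tree (with a
#' logged list), prune the tree to the data species, assign Grafen heights,
#' apply the rho transform, and return the correlation matrix.
#'
#' @param newick Newick string or `phylo` object.
#' @param species Character vector of species in the data.
#' @param rho Grafen's rho (default 0.4).
#' @return List with `C` (correlation matrix), `tree` (processed tree) and
#'   `dropped` (data species not in the tree).
#' @export
phylo_correlation <- function(newick, species, rho = 0.4) {
  tree <- if (inherits(newick, "phylo")) newick else parse_newick(newick)
  species <- unique(species)
  dropped <- setdiff(species, tree$tip.label)
  if (length(dropped)) {
    message("species absent from tree, dropped from analysis: ",
            paste(dropped, collapse = ", "))
  }
  keep <- intersect(species, tree$tip.label)
  tree <- rho_transform(grafen_heights(prune(tree, keep)), rho)
  list(C = correlation_matrix(tree), tree = tree, dropped = dropped)
}

#' Check that a matrix is a valid phylogenetic correlation matrix
#'
#' Symmetry, unit diagonal, off-diagonals in \[0, 1\] and positive
#' semidefiniteness (smallest eigenvalue > -1e-8).
#'
#' @param C Matrix to check.
#' @return Invisibly `TRUE`; otherwise an error.
#' @export
check_correlation <- function(C) {
  if (!is.matrix(C) || nrow(C) != ncol(C)) {
    stop("C must be a square matrix", call. = FALSE)
  }
  if (max(abs(C - t(C))) > 1e-10) stop("C is not symmetric", call. = FALSE)
  if (max(abs(diag(C) - 1)) > 1e-10) {
    stop("C must have unit diagonal", call. = FALSE)
  }
  off <- C[row(C) != col(C)]
  if (any(off < -1e-10 | off > 1 + 1e-10)) {
    stop("off-diagonal entries must lie in [0, 1]", call. = FALSE)
  }
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("C is not positive semidefinite (min eigenvalue ",
         signif(min(ev), 3), ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' Profile model fit over Grafen's rho
#'
#' Refits the model once per candidate rho and reports PSIS-LOO per value,
#' a simple grid search for the tree transform that best fits the data.
#' Uses the light screening MCMC settings by default.
#'
#' @param records A `pcrit_clean` data.frame with `resid_mr` attached.
#' @param tree Newick string or `phylo` covering the data species.
#' @param spec Model to refit (default the final model from
#'   [candidate_set()]).
#' @param rhos Grid of rho values.
#' @param chains,iter,warmup,seed Passed to [fit_pcrit()].
#' @return Data.frame with `rho`, `elpd_loo`, `se`, sorted as given.
#' @export
rho_profile <- function(records, tree, spec = candidate_set()$final,
                        rhos = seq(0.1, 1, by = 0.1),
                        chains = 2, iter = 4000, warmup = 1000,
                        seed = NULL) {
  out <- data.frame(rho = rhos, elpd_loo = NA_real_, se = NA_real_)
  for (i in seq_along(rhos)) {
    pc <- phylo_correlation(tree, unique(records$species), rho = rhos[i])
    fit <- suppressWarnings(
      fit_pcrit(records, spec, pc$C, chains = chains, iter = iter,
                warmup = warmup, seed = seed)
    )
    loo <- suppressWarnings(psis_loo(fit))
    out$elpd_loo[i] <- loo$elpd_loo
    out$se[i] <- loo$se
  }
  out
}

#' Write a correlation matrix as CSV with a species-order header
#'
#' @param C Correlation matrix with species dimnames.
#' @param path Output CSV path.
#' @export
write_correlation <- function(C, path) {
  utils::write.csv(as.data.frame(C), path, row.names = TRUE)
}
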