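# Postorder pruning plan for a tree: edge matrix, base lengths, tip count.
# Precomputed once and reused across many likelihood evaluations.
pruning_plan <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  orig <- match(paste(tr$edge[, 1], tr$edge[, 2]),
                paste(tree$edge[, 1], tree$edge[, 2]))
  list(edge = tr$edge, lens = tr$edge.length, orig = orig,
       ntip = ape::Ntip(tree))
}

#' Profile log-likelihood of multivariate Brownian motion
#'
#' Log-likelihood of tip traits under multivariate Brownian motion with
#' per-edge rate scalars: tip values are MVN with covariance
#' `kron(Sigma, C)` where `C` holds shared rate-scaled path lengths. The
#' phylogenetic mean `alpha` (GLS) and trait covariance `Sigma` (ML,
#' correlations unrestricted) are profiled out analytically in a single
#' postorder pruning pass; no dense matrix is formed.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param traits tips x traits numeric matrix, rownames = tip labels.
#' @param scalars optional [rate_config()] of rate shifts.
#' @return list with `loglik`, `sigma` (ML trait covariance), `alpha`
#'   (GLS mean) and `logdetC`.
#' @export
mvbm_loglik <- function(tree, traits, scalars = NULL) {
  X <- align_traits(tree, traits)
  plan <- pruning_plan(tree)
  rates <- effective_rates(tree, scalars)
  if (any(rates <= 0)) stop("effective rates must be positive")
  lens <- plan$lens * rates[plan$orig]
  res <- mvbm_pruning(plan$edge, lens, X, plan$ntip)
  if (!res$ok) {
    stop("singular phylogenetic covariance (zero-length shared paths ",
         "collapse tips) or degenerate trait covariance")
  }
  dimnames(res$sigma) <- list(colnames(X), colnames(X))
  res$alpha <- drop(res$alpha)
  names(res$alpha) <- colnames(X)
  res[c("loglik", "sigma", "alpha", "logdetC")]
}

# Reorder a trait matrix to tip-label order; error on mismatch.
align_traits <- function(tree, traits) {
  X <- as.matrix(traits)
  if (is.null(rownames(X))) {
    if (nrow(X) != ape::Ntip(tree)) stop("traits rows must match tree tips")
    rownames(X) <- tree$tip.label
  }
  if (!setequal(rownames(X), tree$tip.label)) {
    stop("traits rows must match tree tips")
  }
  X <- X[tree$tip.label, , drop = FALSE]
  if (anyNA(X)) stop("traits contain missing values")
  storage.mode(X) <- "double"
  X
}
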