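#' Parameters of a multivariate Brownian-motion model
#'
#' @param alpha root state (phylogenetic mean), length-p numeric.
#' @param sigma p x p symmetric positive-definite per-unit-time trait
#'   covariance (Brownian variance; off-diagonals allow correlated traits).
#' @return an `mvbm_params` object.
#' @export
mvbm_params <- function(alpha, sigma) {
  sigma <- as.matrix(sigma)
  alpha <- as.numeric(alpha)
  if (nrow(sigma) != ncol(sigma) || length(alpha) != nrow(sigma)) {
    stop("alpha length must match sigma dimension")
  }
  if (max(abs(sigma - t(sigma))) > 1e-8) stop("sigma must be symmetric")
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("sigma must be positive definite")
  structure(list(alpha = alpha, sigma = sigma), class = "mvbm_params")
}

#' Simulate correlated traits under variable-rates Brownian motion
#'
#' Walks the tree root-to-tips; along an edge of length `t` with effective
#' rate `r` the trait vector gains a MVN(0, r * t * sigma) increment. With
#' no rate shifts this is homogeneous multivariate BM.
#'
#' @param tree an [ape::phylo] tree.
#' @param params an [mvbm_params()] object.
#' @param scalars optional [rate_config()] of planted rate shifts.
#' @param seed integer seed.
#' @return numeric matrix (tips x traits), rownames = tip labels.
#' @export
simulate_traits <- function(tree, params, scalars = NULL, seed = NULL) {
  stopifnot(inherits(params, "mvbm_params"))
  if (!is.null(seed)) set.seed(seed)
  p <- length(params$alpha)
  rates <- effective_rates(tree, scalars)
  n_tip <- ape::Ntip(tree)
  n_node <- n_tip + tree$Nnode
  ch <- chol(params$sigma)
  vals <- matrix(NA_real_, n_node, p)
  root <- n_tip + 1L
  vals[root, ] <- params$alpha
  # cladewise order guarantees parents are visited before children
  tr <- ape::reorder.phylo(tree, "cladewise")
  o <- match(
    paste(tr$edge[, 1], tr$edge[, 2]),
    paste(tree$edge[, 1], tree$edge[, 2])
  )
  for (k in seq_len(nrow(tr$edge))) {
    par <- tr$edge[k, 1]; chi <- tr$edge[k, 2]
    v <- tr$edge.length[k] * rates[o[k]]
    z <- stats::rnorm(p)
    vals[chi, ] <- vals[par, ] + sqrt(v) * drop(z %*% ch)
  }
  out <- vals[seq_len(n_tip), , drop = FALSE]
  rownames(out) <- tree$tip.label
  colnames(out) <- paste0("V", seq_len(p))
  out
}
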