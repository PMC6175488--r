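# Independent oracles used across the suite. These deliberately use dense
# linear algebra / brute-force search, never the package's own fast paths.

# Dense kron-MVN profile log-likelihood of multivariate BM.
dense_mvbm_loglik <- function(tree, X, rates = NULL) {
  tr <- tree
  if (!is.null(rates)) tr$edge.length <- tr$edge.length * rates
  C <- ape::vcv(tr)[rownames(X), rownames(X)]
  n <- nrow(X); p <- ncol(X)
  Ci <- solve(C); one <- rep(1, n)
  a <- drop(t(one) %*% Ci %*% X) / drop(t(one) %*% Ci %*% one)
  Xc <- sweep(X, 2, a)
  Sig <- (t(Xc) %*% Ci %*% Xc) / n
  as.numeric(-0.5 * n * p * log(2 * pi) -
               0.5 * p * determinant(C)$modulus -
               0.5 * n * determinant(Sig)$modulus - 0.5 * n * p)
}

# Brute-force minimal Procrustes distance: multi-start optimisation over
# rotations (axis-angle parameterisation), both shapes at unit centroid
# size.
brute_procrustes_distance <- function(A, B) {
  unit <- function(M) { M <- sweep(M, 2, colMeans(M)); M / sqrt(sum(M^2)) }
  A <- unit(as.matrix(A)); B <- unit(as.matrix(B))
  rotmat <- function(v) {
    th <- sqrt(sum(v^2))
    if (th < 1e-12) return(diag(3))
    k <- v / th
    K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
    diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  }
  obj <- function(v) sum((A - B %*% rotmat(v))^2)
  best <- Inf
  set.seed(424242)
  starts <- rbind(matrix(0, 1, 3),
                  matrix(stats::runif(3 * 40, -pi, pi), ncol = 3))
  for (i in seq_len(nrow(starts))) {
    o <- stats::optim(starts[i, ], obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, o$value)
  }
  sqrt(best)
}

# Dense GLS coefficients under a given covariance.
dense_gls <- function(y, X, V) {
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  drop(beta)
}

# Brute-force effective per-edge rates: walk every entry's coverage by
# explicit parent-chasing along root-to-node paths.
brute_effective_rates <- function(tree, config) {
  E <- nrow(tree$edge)
  rates <- rep(1, E)
  if (is.null(config) || nrow(config) == 0) return(rates)
  for (e in seq_len(E)) {
    # node path from the child of e up to the root
    path_edges <- e
    node <- tree$edge[e, 1]
    root <- ape::Ntip(tree) + 1
    while (node != root) {
      up <- which(tree$edge[, 2] == node)
      path_edges <- c(path_edges, up)
      node <- tree$edge[up, 1]
    }
    for (i in seq_len(nrow(config))) {
      if (config$scope[i] == "branch") {
        if (config$edge[i] == e) rates[e] <- rates[e] * config$scalar[i]
      } else if (config$edge[i] %in% path_edges) {
        rates[e] <- rates[e] * config$scalar[i]
      }
    }
  }
  rates
}

# Random similarity transform of a coordinate matrix.
random_similarity <- function(A) {
  R <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  sweep(A %*% R * stats::runif(1, 0.5, 2), 2, stats::rnorm(3, 0, 2), "+")
}

# First edge subtending a clade of crown size within [lo, hi].
find_clade_edge <- function(tree, lo, hi) {
  n <- ape::Ntip(tree)
  sz <- vapply(seq_len(nrow(tree$edge)), function(e) {
    ch <- tree$edge[e, 2]
    if (ch <= n) 1L else length(beakrates:::tips_under(tree, ch))
  }, 1L)
  which(sz >= lo & sz <= hi)[1]
}

# Tip labels of the clade under an edge.
clade_tips <- function(tree, edge_idx) {
  ch <- tree$edge[edge_idx, 2]
  n <- ape::Ntip(tree)
  if (ch <= n) tree$tip.label[ch] else
    tree$tip.label[beakrates:::tips_under(tree, ch)]
}
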