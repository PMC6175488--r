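# Reproducible eigenvector sign convention: the largest-magnitude entry
# of every eigenvector is positive.
fix_eigen_signs <- function(V) {
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

new_shape_space <- function(scores, evecs, evals, center, method,
                            data = NULL) {
  evals <- pmax(evals, 0)
  vf <- if (sum(evals) > 0) evals / sum(evals) else evals
  structure(list(scores = scores, evectors = evecs, evalues = evals,
                 var_fraction = vf, center = center, method = method,
                 data = data),
            class = "shape_space")
}

#' Principal component analysis of aligned shapes
#'
#' Eigen-decomposition of the covariance of vectorised aligned coordinates
#' (or of any specimen x variable matrix) about the mean; scores are the
#' centred data projected onto the eigenvectors. Axis variance fractions
#' sum to 1.
#'
#' @param x a [gpa()] alignment (its `aligned` array is vectorised
#'   row-wise per specimen) or an n x q numeric matrix with rownames.
#' @return a `shape_space` with scores, eigenvectors, eigenvalues and
#'   per-axis variance fractions.
#' @export
shape_pca <- function(x) {
  X <- shapes_as_matrix(x)
  if (nrow(X) < 2) stop("need at least 2 shapes")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  cv <- crossprod(Xc) / (nrow(X) - 1)
  eg <- eigen(cv, symmetric = TRUE)
  V <- fix_eigen_signs(eg$vectors)
  scores <- Xc %*% V
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  new_shape_space(scores, V, eg$values, ctr, "pca", data = X)
}

#' Phylogenetic principal component analysis
#'
#' PCA on the evolutionary covariance matrix
#' `t(X - 1a) C^-1 (X - 1a) / (n - 1)`, where `a` is the GLS phylogenetic
#' mean and `C` the Brownian-motion tip covariance of the tree (shared
#' root-to-tip path lengths). Corrects the ordinary PCA for the
#' non-independence of species due to shared ancestry. Scores are the
#' GLS-centred data projected on the eigenvectors of that matrix.
#'
#' @param x alignment or matrix as in [shape_pca()]; rows must be tree
#'   tips.
#' @param tree an [ape::phylo] tree, or a precomputed n x n covariance
#'   matrix `C`.
#' @return a `shape_space` (method `"ppca"`).
#' @export
shape_ppca <- function(x, tree) {
  X <- shapes_as_matrix(x)
  n <- nrow(X)
  C <- if (is.matrix(tree)) tree else ape::vcv(tree)
  if (nrow(C) != n) stop("tree tips and shape rows do not match")
  if (!is.null(rownames(X)) && !is.null(rownames(C))) {
    if (!setequal(rownames(X), rownames(C))) {
      stop("tree tips and shape rows do not match")
    }
    C <- C[rownames(X), rownames(X)]
  }
  ch <- chol(C)
  one <- rep(1, n)
  Ci1 <- backsolve(ch, forwardsolve(t(ch), one))
  CiX <- backsolve(ch, forwardsolve(t(ch), X))
  a <- drop(crossprod(Ci1, X)) / sum(Ci1)
  Xc <- sweep(X, 2, a)
  CiXc <- backsolve(ch, forwardsolve(t(ch), Xc))
  Ecov <- crossprod(Xc, CiXc) / (n - 1)
  Ecov <- (Ecov + t(Ecov)) / 2
  eg <- eigen(Ecov, symmetric = TRUE)
  V <- fix_eigen_signs(eg$vectors)
  scores <- Xc %*% V
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  new_shape_space(scores, V, eg$values, a, "ppca", data = X)
}

#' Select the leading axes explaining a cumulative variance fraction
#'
#' Returns the smallest k axes whose cumulative variance fraction reaches
#' `cum_var` (default 0.99, the conventional near-total-variance cut).
#'
#' @param space a `shape_space`.
#' @param cum_var target cumulative variance fraction in (0, 1].
#' @return matrix of the first k score columns (a trait matrix).
#' @export
select_axes <- function(space, cum_var = 0.99) {
  stopifnot(inherits(space, "shape_space"))
  if (cum_var <= 0 || cum_var > 1) stop("cum_var must be in (0, 1]")
  cs <- cumsum(space$var_fraction)
  if (cum_var >= 1) {
    k <- sum(space$var_fraction > 1e-12)
  } else {
    k <- which(cs >= cum_var - 1e-12)[1]
  }
  k <- max(k, 1L)
  space$scores[, seq_len(k), drop = FALSE]
}

# specimen x variable matrix from an alignment or plain matrix
shapes_as_matrix <- function(x) {
  if (is.list(x) && !is.null(x$aligned)) {
    arr <- x$aligned
    n <- dim(arr)[3]
    X <- t(vapply(seq_len(n), function(s) as.numeric(arr[, , s]),
                  numeric(dim(arr)[1] * 3)))
    rownames(X) <- dimnames(arr)[[3]]
    X
  } else {
    as.matrix(x)
  }
}
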