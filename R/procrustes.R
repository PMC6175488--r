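as_coords <- function(x) {
  if (inherits(x, "landmark_config")) x$coords else as.matrix(x)
}

# Center and scale a k x 3 coordinate matrix to centroid size 1.
center_unit <- function(A) {
  A <- sweep(A, 2, colMeans(A))
  cs <- sqrt(sum(A^2))
  if (cs <= 0) stop("degenerate configuration: zero centroid size")
  A / cs
}

# Optimal rotation R (det +1) such that B %*% R best matches A (rows are
# points). Reflections disallowed: beaks are chiral.
optimal_rotation <- function(A, B) {
  s <- svd(crossprod(B, A))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Procrustes distance between two landmark configurations
#'
#' Square root of the summed squared deviations between the two
#' configurations after removing translation, scale (both scaled to unit
#' centroid size) and rotation (optimal rotation, reflections disallowed).
#' Symmetric in its arguments and zero iff the shapes are
#' similarity-equivalent.
#'
#' @param a,b `landmark_config`s (or bare k x 3 matrices) with identical
#'   layouts.
#' @return non-negative scalar.
#' @export
procrustes_distance <- function(a, b) {
  if (inherits(a, "landmark_config") && inherits(b, "landmark_config") &&
      !same_layout(a, b)) {
    stop("landmark layouts differ")
  }
  A <- center_unit(as_coords(a))
  B <- center_unit(as_coords(b))
  if (nrow(A) != nrow(B)) stop("landmark layouts differ")
  R <- optimal_rotation(A, B)
  sqrt(sum((A - B %*% R)^2))
}

#' Generalized Procrustes alignment
#'
#' Iterative superimposition: every configuration is centered, scaled to
#' unit centroid size and rotated to the running consensus (optimal
#' rotation via SVD of the cross-covariance, reflections disallowed); the
#' consensus is the mean of the aligned shapes, rescaled to unit size. The
#' Procrustes sum of squares is non-increasing across iterations.
#'
#' @param configs list of `landmark_config`s (or k x 3 matrices) with
#'   identical layouts; at least 2.
#' @param tol stop when the consensus moves by less than this (root summed
#'   squared change).
#' @param max_iter iteration cap.
#' @return list with `aligned` (k x 3 x n array), `consensus` (k x 3),
#'   `ss` (total Procrustes sum of squares about the consensus),
#'   `iterations`, and the shared `layout` when inputs carried one.
#' @export
gpa <- function(configs, tol = 1e-8, max_iter = 200) {
  if (length(configs) < 2L) stop("gpa needs at least 2 configurations")
  layout <- if (inherits(configs[[1]], "landmark_config")) configs[[1]]
  if (!is.null(layout)) {
    for (cfg in configs) {
      if (inherits(cfg, "landmark_config") && !same_layout(layout, cfg)) {
        stop("landmark layouts differ")
      }
    }
  }
  mats <- lapply(configs, function(x) center_unit(as_coords(x)))
  k <- nrow(mats[[1]])
  if (any(vapply(mats, nrow, 1L) != k)) stop("landmark layouts differ")
  cons <- mats[[1]]
  for (it in seq_len(max_iter)) {
    mats <- lapply(mats, function(M) M %*% optimal_rotation(cons, M))
    new_cons <- Reduce(`+`, mats) / length(mats)
    new_cons <- center_unit(new_cons)
    delta <- sqrt(sum((new_cons - cons)^2))
    cons <- new_cons
    if (delta < tol) break
  }
  ss <- sum(vapply(mats, function(M) sum((M - cons)^2), 1))
  arr <- array(unlist(mats), dim = c(k, 3, length(mats)),
               dimnames = list(NULL, c("x", "y", "z"), names(configs)))
  list(aligned = arr, consensus = cons, ss = ss, iterations = it,
       layout = layout)
}

#' Average several users' markups of one specimen
#'
#' Aligns all accepted configurations by GPA and returns their pointwise
#' mean shape (in unit-centroid-size space).
#'
#' @param accepted non-empty list of `landmark_config`s, identical layouts.
#' @return a single `landmark_config` (the user-averaged shape).
#' @export
average_markups <- function(accepted) {
  if (length(accepted) == 0L) stop("no accepted configurations to average")
  if (length(accepted) == 1L) return(accepted[[1]])
  g <- gpa(accepted)
  mean_coords <- apply(g$aligned, c(1, 2), mean)
  lay <- g$layout
  if (is.null(lay)) lay <- accepted[[1]]
  if (inherits(lay, "landmark_config")) {
    out <- landmark_config(mean_coords, lay$type, lay$curve)
    attributes(out) <- utils::modifyList(attributes(lay),
                                         attributes(out))
    out
  } else {
    mean_coords
  }
}
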