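# Thin-plate-spline bending-energy matrix of a 3D reference
# configuration. Kernel U(r) = r for R^3; the bending-energy matrix is the
# upper-left k x k block of the inverse of the bordered TPS system. Its
# sign is normalised so the quadratic form is positive semi-definite
# (checked on the smallest eigenvalue).
bending_energy_matrix <- function(ref) {
  k <- nrow(ref)
  K <- as.matrix(stats::dist(ref))
  Q <- cbind(1, ref)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 4, 4)))
  Li <- tryCatch(solve(L), error = function(e) MASS_ginv(L))
  Be <- Li[seq_len(k), seq_len(k)]
  Be <- (Be + t(Be)) / 2
  ev <- eigen(Be, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) Be <- -Be
  Be
}

# small local pseudo-inverse fallback (avoids importing MASS for one call)
MASS_ginv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > max(tol * s$d[1], 0)
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Bending energy of a configuration relative to a reference
#'
#' Sum over coordinate axes of the thin-plate-spline bending-energy
#' quadratic form; zero for any affine deformation of the reference.
#'
#' @param Y k x 3 target configuration.
#' @param Be bending-energy matrix from the reference (internal), or a
#'   k x 3 reference configuration.
#' @return non-negative scalar.
#' @export
bending_energy <- function(Y, Be) {
  if (is.matrix(Be) && ncol(Be) == 3L && nrow(Be) == nrow(Y)) {
    Be <- bending_energy_matrix(Be)
  }
  sum(diag(t(Y) %*% Be %*% Y))
}

# Unit tangent vectors at semi-landmarks: central differences along the
# claimed within-curve order, anchored at the curve's fixed endpoints when
# the layout declares them.
curve_tangents <- function(coords, layout) {
  k <- nrow(coords)
  semis <- which(layout$type == "semi")
  tang <- matrix(0, k, 3)
  anchors <- attr(layout, "curve_anchors")
  for (cv in sort(unique(layout$curve[layout$curve > 0]))) {
    idx <- which(layout$curve == cv)
    if (length(idx) < 3) next
    path <- coords[idx, , drop = FALSE]
    a <- anchors[[as.character(cv)]]
    if (!is.null(a)) {
      path <- rbind(coords[a[1], ], path, coords[a[2], ])
      off <- 1L
    } else {
      off <- 0L
    }
    m <- length(idx)
    for (j in seq_len(m)) {
      lo <- j + off - 1L; hi <- j + off + 1L
      lo <- max(lo, 1L); hi <- min(hi, nrow(path))
      t_ <- path[hi, ] - path[lo, ]
      nt <- sqrt(sum(t_^2))
      if (nt > 0) tang[idx[j], ] <- t_ / nt
    }
  }
  tang[setdiff(seq_len(k), semis), ] <- 0
  tang
}

#' Slide semi-landmarks to reduce bending energy
#'
#' Each pass displaces every configuration's semi-landmarks along their
#' local curve tangents by the closed-form minimiser of the thin-plate-
#' spline bending energy of the deformation from the consensus, with the
#' displacement capped at half the local inter-point spacing (preserving
#' along-curve order); a backtracking halving step guarantees the bending
#' energy never increases. GPA is re-run after every pass.
#'
#' @param alignment output of [gpa()] whose `layout` declares curves.
#' @param n_iter number of slide + re-align passes (default 3).
#' @return an updated alignment list (as [gpa()]) with an extra element
#'   `bending`: per-pass total bending energy before and after sliding.
#' @export
slide_semilandmarks <- function(alignment, n_iter = 3) {
  layout <- alignment$layout
  if (is.null(layout)) stop("alignment carries no landmark layout")
  semis <- which(layout$type == "semi")
  if (!length(semis)) return(alignment)
  k <- nrow(alignment$consensus)
  n <- dim(alignment$aligned)[3]
  arr <- alignment$aligned
  cons <- alignment$consensus
  bend_log <- matrix(NA_real_, n_iter, 2,
                     dimnames = list(NULL, c("before", "after")))

  for (pass in seq_len(n_iter)) {
    Be <- bending_energy_matrix(cons)
    tot_before <- 0; tot_after <- 0
    for (s in seq_len(n)) {
      Y <- arr[, , s]
      tang <- curve_tangents(Y, layout)
      live <- semis[rowSums(tang[semis, , drop = FALSE]^2) > 0]
      if (!length(live)) next
      dev <- Y - cons
      e0 <- bending_energy(dev, Be)
      # normal equations of min_t || (dev + U t) ||_Be with U the
      # per-semi tangent directions
      G <- Be %*% dev
      A <- Be[live, live] * tcrossprod(tang[live, , drop = FALSE])
      b <- rowSums(tang[live, , drop = FALSE] * G[live, , drop = FALSE])
      tvec <- tryCatch(
        drop(solve(A + diag(1e-12, length(live)), -b)),
        error = function(e) rep(0, length(live)))
      # cap at half the local inter-point spacing to preserve order
      cap <- vapply(seq_along(live), function(j) {
        i <- live[j]; cv <- layout$curve[i]
        idx <- which(layout$curve == cv)
        pos <- match(i, idx)
        nb <- idx[c(max(pos - 1, 1), min(pos + 1, length(idx)))]
        0.5 * min(sqrt(rowSums((Y[nb, , drop = FALSE] -
                                  rep(Y[i, ], each = length(nb)))^2)))
      }, 1)
      tvec <- pmin(pmax(tvec, -cap), cap)
      # backtracking: never increase bending energy
      for (half in 0:20) {
        Y2 <- Y
        Y2[live, ] <- Y[live, ] + tvec * tang[live, , drop = FALSE]
        e1 <- bending_energy(Y2 - cons, Be)
        if (e1 <= e0 + 1e-12) break
        tvec <- tvec / 2
      }
      if (e1 > e0) { Y2 <- Y; e1 <- e0 }
      arr[, , s] <- Y2
      tot_before <- tot_before + e0
      tot_after <- tot_after + e1
    }
    bend_log[pass, ] <- c(tot_before, tot_after)
    # re-run GPA on the slid configurations
    cfgs <- lapply(seq_len(n), function(s) arr[, , s])
    g <- gpa(cfgs)
    arr <- g$aligned
    dimnames(arr)[[3]] <- dimnames(alignment$aligned)[[3]]
    cons <- g$consensus
  }
  out <- alignment
  out$aligned <- arr
  out$consensus <- cons
  out$ss <- sum(vapply(seq_len(n),
                       function(s) sum((arr[, , s] - cons)^2), 1))
  out$bending <- bend_log
  out
}
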