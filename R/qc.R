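# Project points onto a reference polyline; returns the cumulative
# arc-length position of the nearest point on the polyline for each row.
project_arc_position <- function(P, path) {
  segs <- diff(path)
  seg_len <- sqrt(rowSums(segs^2))
  cum <- c(0, cumsum(seg_len))
  apply(P, 1, function(pt) {
    best <- Inf; pos <- 0
    for (s in seq_len(nrow(segs))) {
      d <- pt - path[s, ]
      t <- sum(d * segs[s, ]) / sum(segs[s, ]^2)
      t <- min(max(t, 0), 1)
      q <- path[s, ] + t * segs[s, ]
      dd <- sum((pt - q)^2)
      if (dd < best) { best <- dd; pos <- cum[s] + t * seg_len[s] }
    }
    pos
  })
}

# Rotate/scale/translate B onto reference A (both reduced to unit
# centroid size first); returns the aligned copy of B.
align_to <- function(A, B) {
  A <- center_unit(A); B <- center_unit(B)
  B %*% optimal_rotation(A, B)
}

#' Quality control of multi-user markups
#'
#' Screens each user's markup of a specimen for the three failure modes of
#' crowd-sourced landmarking and reports a per-user verdict:
#'
#' * `EDGE_INVERSION` — the left and right tomial-edge curves are swapped:
#'   relabelling the user's left and right blocks (the "repair") fits the
#'   consensus of the other users clearly better than the markup as
#'   submitted. Testing the repair rather than raw block distances is
#'   robust to the rotation ambiguity a mirrored markup creates. Gross
#'   left/right asymmetry (mean deviations from the consensus differing
#'   by more than `asym_tol` relative to the larger, above an absolute
#'   floor) raises the same code.
#' * `CURVE_DISORDER` — semi-landmarks along a curve are out of order:
#'   their arc positions along the consensus curve are non-monotone
#'   (backward jumps beyond one mean inter-point spacing) or their rank
#'   order disagrees with the claimed order (Spearman < `order_min_cor`).
#' * `USER_DISCREPANCY` — the user's mean Procrustes distance to the
#'   other users is at least `d_max` (default 0.2). The rules apply
#'   sequentially: the discrepancy test runs among the users that passed
#'   the geometric checks above, so one grossly corrupted markup does not
#'   drag every honest user past the threshold.
#'
#' The reference for each user's geometric checks is the medoid of the
#' remaining users (the one with the smallest summed Procrustes distance
#' to the rest), which stays clean as long as honest users are in the
#' majority — a mean consensus would be dragged by a single scrambled
#' markup. The specimen's measurement error is the mean between-user
#' Procrustes distance, computed over accepted users when at least two
#' remain, else over all users.
#'
#' @param m a `markup_set`.
#' @param d_max between-user Procrustes distance threshold (default 0.2).
#' @param asym_tol relative left/right asymmetry tolerance (default 0.5).
#' @param asym_floor absolute floor below which asymmetry is never flagged
#'   (unit-centroid-size length units).
#' @param order_min_cor minimum Spearman correlation between claimed and
#'   projected along-curve order.
#' @return a `qc_report`: data frame `users` (user, accepted, reasons),
#'   matrix `pairwise` of Procrustes distances, scalar
#'   `measurement_error`, character `notes`.
#' @export
qc_markups <- function(m, d_max = 0.2, asym_tol = 0.5, asym_floor = 0.05,
                       order_min_cor = 0.95) {
  stopifnot(inherits(m, "markup_set"))
  users <- m$users
  n <- length(users)
  if (n < 1L) stop("markup set has no users")
  notes <- character(0)
  reasons <- stats::setNames(vector("list", n), names(users))
  for (i in seq_len(n)) reasons[[i]] <- character(0)

  D <- matrix(0, n, n, dimnames = list(names(users), names(users)))
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      D[i, j] <- D[j, i] <- procrustes_distance(users[[i]], users[[j]])
    }
  } else {
    notes <- c(notes, "single user: discrepancy test skipped")
  }

  lay <- users[[1]]
  left <- attr(lay, "left_curve")
  if (is.null(left)) left <- 2L
  right <- attr(lay, "right_curve")
  if (is.null(right)) right <- 3L
  curves <- sort(unique(lay$curve[lay$curve > 0]))

  reference_for <- function(i) {
    others <- setdiff(seq_len(n), i)
    if (!length(others)) return(NULL)
    # medoid over distances to every user (including the checked one):
    # breaks the two-other tie toward an honest markup
    med <- others[which.min(rowSums(D[others, , drop = FALSE]))]
    center_unit(users[[med]]$coords)
  }

  for (i in seq_len(n)) {
    cons <- reference_for(i)
    if (is.null(cons)) {
      notes <- c(notes,
                 "single user: inversion/order checks use own geometry only")
      next
    }
    U <- align_to(cons, users[[i]]$coords)
    li <- which(lay$curve == left); ri <- which(lay$curve == right)
    if (length(li) && length(ri) && length(li) == length(ri)) {
      raw <- users[[i]]$coords
      d_same <- procrustes_distance(cons, raw)
      repair <- raw
      repair[li, ] <- raw[ri, ]; repair[ri, ] <- raw[li, ]
      d_rep <- procrustes_distance(cons, repair)
      anchors <- attr(lay, "curve_anchors")
      if (!is.null(anchors)) {
        aL <- anchors[[as.character(left)]]
        aR <- anchors[[as.character(right)]]
        fx <- c(setdiff(aL, aR), setdiff(aR, aL))
        if (length(fx) == 2) {
          repair2 <- repair
          repair2[fx[1], ] <- repair[fx[2], ]
          repair2[fx[2], ] <- repair[fx[1], ]
          d_rep <- min(d_rep, procrustes_distance(cons, repair2))
        }
      }
      swapped <- d_rep < 0.8 * d_same
      mdist <- function(a, b) mean(sqrt(rowSums((a - b)^2)))
      mLL <- mdist(U[li, ], cons[li, ]); mRR <- mdist(U[ri, ], cons[ri, ])
      asym <- max(mLL, mRR) > asym_floor &&
        abs(mLL - mRR) > asym_tol * max(mLL, mRR)
      if (swapped || asym) {
        reasons[[i]] <- c(reasons[[i]], "EDGE_INVERSION")
      }
    }
    for (cv in curves) {
      idx <- which(lay$curve == cv)
      if (length(idx) < 3) {
        notes <- c(notes, sprintf("curve %d has < 3 points: order check skipped", cv))
        next
      }
      ref_path <- cons[idx, ]
      spacing <- mean(sqrt(rowSums(diff(ref_path)^2)))
      pos <- project_arc_position(U[idx, ], ref_path)
      backjump <- any(diff(pos) < -spacing)
      rk <- suppressWarnings(
        stats::cor(pos, seq_along(idx), method = "spearman"))
      if (backjump || (is.finite(rk) && rk < order_min_cor)) {
        reasons[[i]] <- c(reasons[[i]], "CURVE_DISORDER")
        break
      }
    }
  }

  # rule (3), applied after the geometric rules: mean distance to the
  # other geometrically clean users
  if (n >= 2) {
    geom_ok <- vapply(reasons, function(r) length(r) == 0L, TRUE)
    pool <- if (sum(geom_ok) >= 2) which(geom_ok) else seq_len(n)
    for (i in seq_len(n)) {
      others <- setdiff(pool, i)
      if (!length(others)) next
      if (mean(D[i, others]) >= d_max) {
        reasons[[i]] <- c(reasons[[i]], "USER_DISCREPANCY")
      }
    }
  }

  accepted <- vapply(reasons, function(r) length(r) == 0L, TRUE)
  me <- if (n == 1) {
    NA_real_
  } else if (sum(accepted) >= 2) {
    Dacc <- D[accepted, accepted, drop = FALSE]
    mean(Dacc[upper.tri(Dacc)])
  } else {
    mean(D[upper.tri(D)])
  }

  structure(list(
    users = data.frame(
      user = names(users), accepted = accepted,
      reasons = vapply(reasons, paste, "", collapse = ";"),
      stringsAsFactors = FALSE, row.names = NULL),
    pairwise = D, measurement_error = me, notes = unique(notes)),
    class = "qc_report")
}
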