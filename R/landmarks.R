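#' Landmark configurations
#'
#' A landmark configuration is a set of k labelled 3D points with a role
#' per point (`"fixed"` anatomical landmarks vs `"semi"` sliding
#' semi-landmarks) and, for semi-landmarks, the curve each belongs to and
#' its position along that curve (row order within a curve is the claimed
#' along-curve order).
#'
#' @param coords k x 3 numeric matrix of point coordinates.
#' @param type character vector, `"fixed"` or `"semi"` per point.
#' @param curve integer curve id per point (`NA` or -1 for fixed points).
#' @return a `landmark_config` object.
#' @export
landmark_config <- function(coords, type, curve) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be k x 3")
  k <- nrow(coords)
  if (k < 3L) stop("need at least 3 landmarks")
  if (length(type) != k || length(curve) != k) {
    stop("type and curve must have one entry per point")
  }
  if (!all(type %in% c("fixed", "semi"))) stop("type must be fixed/semi")
  curve <- as.integer(curve)
  curve[type == "fixed"] <- -1L
  structure(list(coords = unname(coords), type = type, curve = curve),
            class = "landmark_config")
}

# TRUE when two configurations share the same layout (roles + curves).
same_layout <- function(a, b) {
  nrow(a$coords) == nrow(b$coords) &&
    all(a$type == b$type) && all(a$curve == b$curve)
}

#' Template beak landmark configuration
#'
#' A synthetic cone-like upper-beak template in the standard layout: four
#' fixed landmarks (beak tip; posterior end of the dorsal midline profile;
#' posterior left and right tomial edges) and three curves of sliding
#' semi-landmarks joining the tip to each posterior landmark (dorsal
#' profile, left tomial edge, right tomial edge).
#'
#' @param n_semi semi-landmarks per curve (default 25, i.e. 75 in total).
#' @return a `landmark_config`; attributes `left_curve`/`right_curve` name
#'   the curve ids of the bilaterally paired tomial edges.
#' @export
beak_template <- function(n_semi = 25) {
  tip <- c(1, 0, 0.05)
  dorsal_end <- c(0, 0, 0.35)
  left_end <- c(0, 0.3, 0)
  right_end <- c(0, -0.3, 0)
  arc <- function(a, b, bulge, n) {
    # quadratic arc from a to b bowed along `bulge`; interior points only
    s <- seq(0, 1, length.out = n + 2)[-c(1, n + 2)]
    t(vapply(s, function(u) {
      (1 - u) * a + u * b + bulge * u * (1 - u)
    }, numeric(3)))
  }
  dorsal <- arc(tip, dorsal_end, c(0, 0, 0.25), n_semi)
  left <- arc(tip, left_end, c(-0.1, 0.12, -0.02), n_semi)
  right <- arc(tip, right_end, c(-0.1, -0.12, -0.02), n_semi)
  coords <- rbind(tip, dorsal_end, left_end, right_end, dorsal, left, right)
  type <- c(rep("fixed", 4), rep("semi", 3 * n_semi))
  curve <- c(rep(-1L, 4), rep(1L, n_semi), rep(2L, n_semi), rep(3L, n_semi))
  out <- landmark_config(coords, type, curve)
  attr(out, "left_curve") <- 2L
  attr(out, "right_curve") <- 3L
  # fixed landmarks anchoring each curve's ends (start, end), for tangents
  attr(out, "curve_anchors") <- list(`1` = c(1L, 2L), `2` = c(1L, 3L),
                                     `3` = c(1L, 4L))
  out
}

#' Write markups in the landmark CSV dialect
#'
#' Columns: specimen_id, user_id, lm_index (0-based), x, y, z,
#' lm_type (fixed/semi), curve_id (-1 for fixed).
#'
#' @param markups a `markup_set` (see [simulate_markups()]) or a named list
#'   of them.
#' @param path output CSV path.
#' @export
write_markups <- function(markups, path) {
  if (inherits(markups, "markup_set")) markups <- list(markups)
  rows <- do.call(rbind, lapply(markups, function(m) {
    do.call(rbind, lapply(names(m$users), function(u) {
      cfg <- m$users[[u]]
      data.frame(specimen_id = m$specimen_id, user_id = u,
                 lm_index = seq_len(nrow(cfg$coords)) - 1L,
                 x = cfg$coords[, 1], y = cfg$coords[, 2],
                 z = cfg$coords[, 3],
                 lm_type = cfg$type, curve_id = cfg$curve)
    }))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read markups from the landmark CSV dialect
#'
#' @param path CSV path written by [write_markups()] or compatible.
#' @return named list of `markup_set` objects, one per specimen.
#' @export
read_markups <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "user_id", "lm_index", "x", "y", "z",
            "lm_type", "curve_id")
  if (!all(need %in% names(df))) {
    stop("landmark CSV must have columns: ", paste(need, collapse = ", "))
  }
  out <- lapply(split(df, df$specimen_id), function(sp) {
    users <- lapply(split(sp, sp$user_id), function(us) {
      us <- us[order(us$lm_index), ]
      landmark_config(cbind(us$x, us$y, us$z), us$lm_type, us$curve_id)
    })
    structure(list(specimen_id = sp$specimen_id[1], users = users,
                   ledger = NULL),
              class = "markup_set")
  })
  out
}
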