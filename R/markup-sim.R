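#' Simulate multi-user markups of a template shape
#'
#' Emulates crowd-sourced landmarking: each user's configuration is the
#' template plus iid Gaussian displacement of every coordinate, with
#' optional constructed corruptions applied to flagged users. Corruption
#' modes mirror the failure modes the quality control screens for:
#'
#' * `swap_tomial_edges` — the left and right tomial-edge semi-landmark
#'   blocks are exchanged index-wise (bilateral inversion).
#' * `shuffle_curve_order` — one curve's semi-landmarks are randomly
#'   permuted (wrong along-curve order); optional field `curve`.
#' * `outlier_user` — the whole configuration is displaced so its
#'   Procrustes distance to the template hits a target (field `distance`,
#'   default 0.3), emulating a careless user.
#'
#' @param template a `landmark_config` (see [beak_template()]).
#' @param n_users number of independent users (>= 1).
#' @param noise_sd standard deviation of the per-coordinate Gaussian
#'   displacement, in the template's length units.
#' @param corruptions list of lists, each with fields `user` (index),
#'   `type` (one of the modes above) and mode-specific options.
#' @param seed integer seed.
#' @param specimen_id specimen label.
#' @return a `markup_set`: `specimen_id`, `users` (named list of
#'   configurations `u1..`), and `ledger` (data frame of applied
#'   corruptions; the QC ground truth).
#' @export
simulate_markups <- function(template, n_users = 3, noise_sd = 0.01,
                             corruptions = list(), seed = NULL,
                             specimen_id = "spec1") {
  stopifnot(inherits(template, "landmark_config"))
  if (n_users < 1L) stop("need at least one user")
  for (cr in corruptions) {
    if (is.null(cr$user) || cr$user < 1 || cr$user > n_users) {
      stop("corruption references a missing user index")
    }
  }
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(template$coords)
  users <- vector("list", n_users)
  names(users) <- paste0("u", seq_len(n_users))
  for (u in seq_len(n_users)) {
    coords <- template$coords +
      matrix(stats::rnorm(k * 3, sd = noise_sd), k, 3)
    users[[u]] <- landmark_config(coords, template$type, template$curve)
  }
  led <- data.frame(user = integer(), type = character(),
                    stringsAsFactors = FALSE)
  left <- attr(template, "left_curve")
  right <- attr(template, "right_curve")
  for (cr in corruptions) {
    u <- cr$user
    cfg <- users[[u]]
    if (cr$type == "swap_tomial_edges") {
      if (is.null(left) || is.null(right)) {
        stop("template does not declare left/right curves")
      }
      li <- which(cfg$curve == left)
      ri <- which(cfg$curve == right)
      tmp <- cfg$coords[li, ]
      cfg$coords[li, ] <- cfg$coords[ri, ]
      cfg$coords[ri, ] <- tmp
    } else if (cr$type == "shuffle_curve_order") {
      cv <- if (!is.null(cr$curve)) cr$curve else
        sample(unique(cfg$curve[cfg$curve > 0]), 1)
      idx <- which(cfg$curve == cv)
      perm <- sample(length(idx))
      while (all(perm == seq_along(idx))) perm <- sample(length(idx))
      cfg$coords[idx, ] <- cfg$coords[idx[perm], ]
    } else if (cr$type == "outlier_user") {
      target <- if (!is.null(cr$distance)) cr$distance else 0.3
      disp <- matrix(stats::rnorm(k * 3), k, 3)
      # fixed-point rescale of the displacement until the Procrustes
      # distance to the template hits the target
      s <- 0.01
      for (i in 1:40) {
        d <- procrustes_distance(template$coords, cfg$coords + s * disp)
        if (abs(d - target) < 1e-6) break
        s <- s * target / d
      }
      cfg$coords <- cfg$coords + s * disp
    } else {
      stop("unknown corruption type: ", cr$type)
    }
    users[[u]] <- cfg
    led <- rbind(led, data.frame(user = u, type = cr$type,
                                 stringsAsFactors = FALSE))
  }
  structure(list(specimen_id = specimen_id, users = users, ledger = led),
            class = "markup_set")
}
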