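#' Rate-scalar configurations
#'
#' A rate-scalar configuration assigns multiplicative rate scalars to edges
#' of a tree, each with scope `"branch"` (the single edge) or `"clade"`
#' (the edge plus every descendant edge). The effective rate of an edge is
#' the product of all scalars whose scope covers it, defaulting to 1.
#'
#' @param edge integer edge indices (rows of `tree$edge`).
#' @param scope character, each `"branch"` or `"clade"`.
#' @param scalar strictly positive scalars.
#' @return a `rate_config` object (data frame with columns edge, scope,
#'   scalar).
#' @export
rate_config <- function(edge = integer(), scope = character(),
                        scalar = numeric()) {
  stopifnot(length(edge) == length(scope), length(edge) == length(scalar))
  scope <- as.character(scope)
  if (!all(scope %in% c("branch", "clade"))) {
    stop("scope must be 'branch' or 'clade'")
  }
  if (any(scalar <= 0)) stop("scalars must be strictly positive")
  br <- edge[scope == "branch"]
  if (anyDuplicated(br)) stop("at most one branch-scope scalar per edge")
  structure(data.frame(edge = as.integer(edge), scope = scope,
                       scalar = as.numeric(scalar)),
            class = c("rate_config", "data.frame"))
}

#' Effective per-edge rates implied by a configuration
#'
#' @param tree an [ape::phylo] tree.
#' @param config a [rate_config()] (NULL means no shifts).
#' @return numeric vector, one effective rate per edge of `tree`.
#' @export
effective_rates <- function(tree, config = NULL) {
  rates <- rep(1, nrow(tree$edge))
  if (is.null(config) || nrow(config) == 0L) return(rates)
  if (any(config$edge < 1L | config$edge > nrow(tree$edge))) {
    stop("configuration references edges outside the tree")
  }
  for (i in seq_len(nrow(config))) {
    cov <- if (config$scope[i] == "branch") config$edge[i] else
      descendant_edges(tree, config$edge[i], include_self = TRUE)
    rates[cov] <- rates[cov] * config$scalar[i]
  }
  rates
}

#' Plant random rate shifts on a tree
#'
#' Samples a ground-truth configuration for recovery experiments: shift
#' locations are distinct edges drawn uniformly, scalars are log-uniform on
#' `scalar_range` (mirroring the inference prior so recovery tests are
#' well-posed).
#'
#' @param tree an [ape::phylo] tree.
#' @param n_branch number of single-branch shifts.
#' @param n_clade number of clade (branch + descendants) shifts.
#' @param scalar_range positive `(lo, hi)` bounds for the log-uniform
#'   scalar draw.
#' @param seed integer seed.
#' @return a [rate_config()] with `n_branch + n_clade` entries.
#' @export
plant_rate_shifts <- function(tree, n_branch = 0, n_clade = 0,
                              scalar_range = c(exp(-3), exp(3)),
                              seed = NULL) {
  n_edges <- nrow(tree$edge)
  n_tot <- n_branch + n_clade
  if (n_tot > n_edges) stop("more shifts than edges on the tree")
  if (scalar_range[1] <= 0 || scalar_range[2] < scalar_range[1]) {
    stop("scalar_range must satisfy 0 < lo <= hi")
  }
  if (!is.null(seed)) set.seed(seed)
  if (n_tot == 0L) return(rate_config())
  edges <- sample.int(n_edges, n_tot)
  scalars <- exp(stats::runif(n_tot, log(scalar_range[1]),
                              log(scalar_range[2])))
  rate_config(edge = edges,
              scope = rep(c("branch", "clade"), c(n_branch, n_clade)),
              scalar = scalars)
}
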