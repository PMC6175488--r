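#' Maximum-likelihood relative clade rates
#'
#' Fits one multiplicative rate per labelled monophyletic clade (all edges
#' of the clade's crown group; optionally including the stem edge) against
#' a background rate of 1, by numerical maximisation of the profile
#' multivariate Brownian likelihood over the log rates. Labels with fewer
#' than `min_size` members are dropped (the conventional minimum of five
#' representatives by default).
#'
#' @param tree an [ape::phylo] tree.
#' @param traits tips x traits matrix.
#' @param clades named character vector, species -> clade label; `NA`
#'   labels mark background species (rate fixed at 1).
#' @param min_size minimum clade size retained (default 5).
#' @param include_stem scale the clade's stem edge too (default FALSE:
#'   crown group only).
#' @return a `clade_rate_fit`: named `rates`, `loglik`, `loglik_null`
#'   (single-rate model), ML `sigma` and `alpha`, and `dropped` labels.
#' @export
ml_clade_rates <- function(tree, traits, clades, min_size = 5,
                           include_stem = FALSE) {
  X <- align_traits(tree, traits)
  clades <- clades[tree$tip.label]
  names(clades) <- tree$tip.label
  sizes <- table(clades, useNA = "no")
  keep <- names(sizes)[sizes >= min_size]
  dropped <- setdiff(names(sizes), keep)
  if (length(dropped)) {
    message("dropping clade(s) under min_size: ",
            paste(dropped, collapse = ", "))
  }
  if (!length(keep)) stop("no clade meets min_size")

  edge_sets <- lapply(keep, function(lab) {
    tips <- names(clades)[!is.na(clades) & clades == lab]
    if (!ape::is.monophyletic(tree, tips)) {
      stop("clade '", lab, "' is not monophyletic; tips: ",
           paste(tips, collapse = ", "))
    }
    mrca <- ape::getMRCA(tree, tips)
    crown <- which(tree$edge[, 1] == mrca)
    crown <- sort(unique(unlist(lapply(crown, function(e) {
      descendant_edges(tree, e, include_self = TRUE)
    }))))
    if (include_stem) {
      stem <- which(tree$edge[, 2] == mrca)
      crown <- sort(unique(c(stem, crown)))
    }
    crown
  })
  names(edge_sets) <- keep

  plan <- pruning_plan(tree)
  nll <- function(logr) {
    if (any(abs(logr) > 30)) return(1e10)
    lr <- numeric(nrow(tree$edge))
    for (j in seq_along(edge_sets)) {
      lr[edge_sets[[j]]] <- lr[edge_sets[[j]]] + logr[j]
    }
    ll <- mvbm_pruning_ll(plan$edge, plan$lens * exp(lr)[plan$orig], X,
                          plan$ntip)
    if (!is.finite(ll)) 1e10 else -ll
  }
  ll0 <- -nll(numeric(length(keep)))
  fit <- stats::optim(numeric(length(keep)), nll, method = "BFGS",
                      control = list(maxit = 500))
  # a nested optimum can never be worse than the single-rate start
  if (-fit$value < ll0) {
    fit$par <- numeric(length(keep)); fit$value <- -ll0
  }
  # recompute sigma/alpha at the fitted rates
  lr <- numeric(nrow(tree$edge))
  for (j in seq_along(edge_sets)) {
    lr[edge_sets[[j]]] <- lr[edge_sets[[j]]] + fit$par[j]
  }
  res <- mvbm_pruning(plan$edge, plan$lens * exp(lr)[plan$orig], X,
                      plan$ntip)
  structure(list(rates = stats::setNames(exp(fit$par), keep),
                 loglik = -fit$value, loglik_null = ll0,
                 sigma = res$sigma, alpha = drop(res$alpha),
                 edge_sets = edge_sets, dropped = dropped),
            class = "clade_rate_fit")
}
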