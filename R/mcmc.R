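#' Settings for the variable-rates MCMC
#'
#' Defaults are desk-scale: 200 000 iterations thinned every 100 with a
#' 50% burn-in, a Poisson(2) prior on the number of rate shifts, and a
#' log-uniform scalar prior on `exp(c(-7, 7))` (uninformative over
#' plausible rate magnitudes).
#'
#' @param n_iter total iterations.
#' @param thin record every `thin`-th iteration.
#' @param burn_in fraction of iterations discarded (in `[0, 1)`).
#' @param prior_shift_mean Poisson prior mean for the shift count.
#' @param log_scalar_bounds scalar prior support on the log scale.
#' @param move_weights proposal probabilities (birth, death, resize, move).
#' @param resize_step random-walk step (log scale) of the resize move.
#' @param seed integer seed.
#' @return an `mcmc_settings` list.
#' @export
mcmc_settings <- function(n_iter = 2e5, thin = 100, burn_in = 0.5,
                          prior_shift_mean = 2,
                          log_scalar_bounds = c(-7, 7),
                          move_weights = c(birth = 0.2, death = 0.2,
                                           resize = 0.45, move = 0.15),
                          resize_step = 1, seed = 1) {
  if (burn_in < 0 || burn_in >= 1) stop("burn_in must be in [0, 1)")
  if (thin < 1) stop("thin must be >= 1")
  if (log_scalar_bounds[2] <= log_scalar_bounds[1]) {
    stop("log_scalar_bounds must be increasing")
  }
  mw <- move_weights / sum(move_weights)
  structure(list(n_iter = as.integer(n_iter), thin = as.integer(thin),
                 burn_in = burn_in, prior_shift_mean = prior_shift_mean,
                 log_scalar_bounds = log_scalar_bounds, move_weights = mw,
                 resize_step = resize_step, seed = as.integer(seed)),
            class = "mcmc_settings")
}

reflect_into <- function(x, lo, hi) {
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  lo + ifelse(y > w, 2 * w - y, y)
}

#' Reversible-jump MCMC over branch and clade rate scalars
#'
#' Samples configurations of multiplicative rate scalars on a fixed tree
#' under the variable-rates Brownian-motion model: each shift scales
#' either a single branch or a target branch plus all its descendants.
#' The shift count has a Poisson prior, shift locations are uniform over
#' free (edge, scope) slots, and scalar values are log-uniform. Moves are
#' add-shift (branch or clade slot), delete-shift, resize (reflected
#' random walk on the log scalar) and move-to-adjacent-edge, accepted by
#' Metropolis-Hastings with the matching proposal terms. The trait
#' covariance and phylogenetic mean are profiled out of the likelihood at
#' every evaluation ([mvbm_loglik()]), so the sampled state is the shift
#' configuration alone and effective rates are relative to a background
#' of 1.
#'
#' @param tree an [ape::phylo] tree (>= 4 tips).
#' @param traits tips x traits matrix.
#' @param settings an [mcmc_settings()].
#' @param prior_only if TRUE the likelihood term is dropped (samples the
#'   prior; used for sampler validation).
#' @return a `rate_posterior`: post-burn-in thinned samples of per-edge
#'   effective rates (`rates`, samples x edges), shift counts `k`,
#'   log-likelihood and log-prior traces, the sampled configurations
#'   (`entries`), per-move acceptance rates, tip edge bookkeeping and the
#'   settings used.
#' @export
variable_rates_mcmc <- function(tree, traits, settings = mcmc_settings(),
                                prior_only = FALSE) {
  stopifnot(inherits(settings, "mcmc_settings"))
  if (ape::Ntip(tree) < 4) stop("need at least 4 tips")
  X <- align_traits(tree, traits)
  plan <- pruning_plan(tree)
  E <- nrow(tree$edge)
  M <- 2L * E
  lo <- settings$log_scalar_bounds[1]
  hi <- settings$log_scalar_bounds[2]
  mu <- settings$prior_shift_mean
  mw <- settings$move_weights
  set.seed(settings$seed)

  cover <- all_descendant_edge_sets(tree, include_self = TRUE)
  # edge adjacency: edges sharing a node
  adj <- lapply(seq_len(E), function(e) {
    nodes <- tree$edge[e, ]
    setdiff(which(tree$edge[, 1] %in% nodes | tree$edge[, 2] %in% nodes), e)
  })

  ll_of <- function(lr) {
    if (prior_only) return(0)
    mvbm_pruning_ll(plan$edge, plan$lens * exp(lr)[plan$orig], X, plan$ntip)
  }

  # state
  s_edge <- integer(0); s_scope <- integer(0); s_logsc <- numeric(0)
  occ <- matrix(FALSE, E, 2)
  lr <- numeric(E)
  ll <- ll_of(lr)
  if (!is.finite(ll)) stop("initial likelihood is not finite")

  cover_of <- function(i) {
    if (s_scope[i] == 1L) s_edge[i] else cover[[s_edge[i]]]
  }

  n_iter <- settings$n_iter
  burn <- floor(settings$burn_in * n_iter)
  keep_at <- seq_len(n_iter)
  keep_at <- keep_at[keep_at > burn & keep_at %% settings$thin == 0]
  n_keep <- length(keep_at)
  rates_out <- matrix(NA_real_, n_keep, E)
  k_out <- integer(n_keep); ll_out <- numeric(n_keep)
  lp_out <- numeric(n_keep)
  entries_out <- vector("list", n_keep)
  rec <- 0L
  acc <- c(birth = 0, death = 0, resize = 0, move = 0)
  tries <- c(birth = 0, death = 0, resize = 0, move = 0)
  guard_at <- max(1L, floor(0.1 * n_iter))

  log_prior_k <- function(k) {
    stats::dpois(k, mu, log = TRUE) - lchoose(M, k) - k * log(hi - lo)
  }

  for (it in seq_len(n_iter)) {
    K <- length(s_edge)
    mv <- sample.int(4L, 1L, prob = mw)
    if (mv == 1L && K < M) {              # birth
      tries[1] <- tries[1] + 1
      free <- which(!occ)
      slot <- free[sample.int(length(free), 1L)]
      e <- ((slot - 1L) %% E) + 1L
      sc <- ((slot - 1L) %/% E) + 1L
      val <- stats::runif(1, lo, hi)
      cov_idx <- if (sc == 1L) e else cover[[e]]
      lr2 <- lr; lr2[cov_idx] <- lr2[cov_idx] + val
      ll2 <- ll_of(lr2)
      logA <- (ll2 - ll) + log(mu) + log(mw[2]) - log(mw[1]) - log(K + 1)
      if (is.finite(ll2) && log(stats::runif(1)) < logA) {
        s_edge <- c(s_edge, e); s_scope <- c(s_scope, sc)
        s_logsc <- c(s_logsc, val)
        occ[e, sc] <- TRUE; lr <- lr2; ll <- ll2
        acc[1] <- acc[1] + 1
      }
    } else if (mv == 2L && K > 0) {       # death
      tries[2] <- tries[2] + 1
      i <- sample.int(K, 1L)
      cov_idx <- cover_of(i)
      lr2 <- lr; lr2[cov_idx] <- lr2[cov_idx] - s_logsc[i]
      ll2 <- ll_of(lr2)
      logA <- (ll2 - ll) + log(mw[1]) - log(mw[2]) + log(K) - log(mu)
      if (is.finite(ll2) && log(stats::runif(1)) < logA) {
        occ[s_edge[i], s_scope[i]] <- FALSE
        s_edge <- s_edge[-i]; s_scope <- s_scope[-i]
        s_logsc <- s_logsc[-i]
        lr <- lr2; ll <- ll2
        acc[2] <- acc[2] + 1
      }
    } else if (mv == 3L && K > 0) {       # resize
      tries[3] <- tries[3] + 1
      i <- sample.int(K, 1L)
      val <- reflect_into(s_logsc[i] + stats::rnorm(1, 0, settings$resize_step),
                          lo, hi)
      cov_idx <- cover_of(i)
      lr2 <- lr; lr2[cov_idx] <- lr2[cov_idx] + (val - s_logsc[i])
      ll2 <- ll_of(lr2)
      if (is.finite(ll2) && log(stats::runif(1)) < (ll2 - ll)) {
        s_logsc[i] <- val; lr <- lr2; ll <- ll2
        acc[3] <- acc[3] + 1
      }
    } else if (mv == 4L && K > 0) {       # move to adjacent edge
      tries[4] <- tries[4] + 1
      i <- sample.int(K, 1L)
      sc <- s_scope[i]
      cand <- adj[[s_edge[i]]]
      cand <- cand[!occ[cand, sc]]
      if (length(cand)) {
        e_new <- cand[sample.int(length(cand), 1L)]
        n_fwd <- length(cand)
        cov_old <- cover_of(i)
        cov_new <- if (sc == 1L) e_new else cover[[e_new]]
        lr2 <- lr
        lr2[cov_old] <- lr2[cov_old] - s_logsc[i]
        lr2[cov_new] <- lr2[cov_new] + s_logsc[i]
        ll2 <- ll_of(lr2)
        back <- adj[[e_new]]
        occ2 <- occ; occ2[s_edge[i], sc] <- FALSE; occ2[e_new, sc] <- TRUE
        n_rev <- sum(!occ2[back, sc])
        logA <- (ll2 - ll) + log(n_fwd) - log(n_rev)
        if (is.finite(ll2) && n_rev > 0 &&
            log(stats::runif(1)) < logA) {
          occ <- occ2; s_edge[i] <- e_new
          lr <- lr2; ll <- ll2
          acc[4] <- acc[4] + 1
        }
      }
    }
    if (it == guard_at && sum(tries) > 50 && sum(acc) == 0) {
      stop("chain is not mixing: 0 acceptances after 10% of iterations (",
           sum(tries), " proposals)")
    }
    if (rec < n_keep && it == keep_at[rec + 1L]) {
      rec <- rec + 1L
      rates_out[rec, ] <- exp(lr)
      k_out[rec] <- length(s_edge)
      ll_out[rec] <- ll
      lp_out[rec] <- log_prior_k(length(s_edge))
      entries_out[[rec]] <- if (length(s_edge)) {
        rate_config(s_edge, c("branch", "clade")[s_scope], exp(s_logsc))
      } else {
        rate_config()
      }
    }
  }

  ntip <- ape::Ntip(tree)
  tip_edge <- match(seq_len(ntip), tree$edge[, 2])
  structure(list(tree = tree, rates = rates_out, k = k_out,
                 loglik = ll_out, logprior = lp_out,
                 entries = entries_out,
                 tip_edges = tip_edge, tip_labels = tree$tip.label,
                 acceptance = ifelse(tries > 0, acc / tries, NA),
                 settings = settings, prior_only = prior_only),
            class = "rate_posterior")
}

#' Posterior branch-rate summaries and tip rates
#'
#' Elementwise median of the effective rate of every edge across the
#' post-burn-in posterior samples; tip rates are the medians of the
#' terminal edges, keyed by tip label, and serve as species-specific
#' rates of evolution.
#'
#' @param post a `rate_posterior` from [variable_rates_mcmc()].
#' @return list with `edges` (data frame: edge, parent, child, length,
#'   median_rate, is_tip, tip_label) and `tip_rates` (named vector).
#' @export
summarize_rates <- function(post) {
  stopifnot(inherits(post, "rate_posterior"))
  if (nrow(post$rates) < 1) stop("posterior holds no samples")
  med <- apply(post$rates, 2, stats::median)
  tree <- post$tree
  is_tip <- tree$edge[, 2] <= ape::Ntip(tree)
  tip_label <- rep(NA_character_, nrow(tree$edge))
  tip_label[post$tip_edges] <- post$tip_labels
  edges <- data.frame(edge = seq_len(nrow(tree$edge)),
                      parent = tree$edge[, 1], child = tree$edge[, 2],
                      length = tree$edge.length, median_rate = med,
                      is_tip = is_tip, tip_label = tip_label,
                      stringsAsFactors = FALSE)
  tip_rates <- stats::setNames(med[post$tip_edges], post$tip_labels)
  list(edges = edges, tip_rates = tip_rates)
}
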