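#' Gelman-Rubin potential scale reduction factor
#'
#' PSRF = sqrt(((n - 1)/n * W + B/n) / W) with W the mean within-chain
#' variance and B = n * var(chain means) the between-chain variance
#' estimator. Values below 1.1 are conventionally read as between-chain
#' convergence.
#'
#' @param chains list of >= 2 equal-length numeric traces.
#' @return PSRF scalar.
#' @export
gelman_rubin <- function(chains) {
  if (!is.list(chains) || length(chains) < 2) stop("need >= 2 chains")
  n <- unique(vapply(chains, length, 1L))
  if (length(n) != 1) stop("chains must have equal length")
  if (n < 2) stop("chains must have length >= 2")
  W <- mean(vapply(chains, stats::var, 1))
  if (W <= 0) stop("zero within-chain variance")
  B <- n * stats::var(vapply(chains, mean, 1))
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size of an MCMC trace
#'
#' ESS = n / tau with integrated autocorrelation time
#' tau = 2 * sum(Gamma_k) - 1, where Gamma_k = rho(2k) + rho(2k + 1) and
#' the sum runs over the initial positive sequence (truncated at the
#' first non-positive pair; Geyer's estimator). Clamped at n, matching
#' the convention that an iid trace has ESS = n. Values of at least 200
#' are conventionally read as within-chain convergence.
#'
#' @param trace numeric vector, length >= 10.
#' @return ESS scalar.
#' @export
effective_sample_size <- function(trace) {
  n <- length(trace)
  if (n < 10) stop("trace must have length >= 10")
  if (stats::var(trace) <= 0) stop("constant trace")
  lag_max <- 200L
  repeat {
    lag_max <- min(lag_max, n - 1L)
    rho <- stats::acf(trace, lag.max = lag_max, plot = FALSE,
                      demean = TRUE)$acf[, 1, 1]
    # pairs Gamma_k = rho(2k) + rho(2k+1), k = 0, 1, ...
    npair <- (length(rho) - 1L) %/% 2L + 1L
    gam <- vapply(seq_len(npair) - 1L, function(k) {
      r1 <- rho[2 * k + 1]
      r2 <- if (2 * k + 2 <= length(rho)) rho[2 * k + 2] else 0
      r1 + r2
    }, 1)
    cut <- which(gam <= 0)[1]
    if (!is.na(cut) || lag_max >= n - 1L) break
    lag_max <- lag_max * 4L
  }
  gam <- if (is.na(cut)) gam else gam[seq_len(cut - 1L)]
  tau <- max(2 * sum(gam) - 1, 1)
  min(n / tau, n)
}
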