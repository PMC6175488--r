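# Pagel-lambda phylogenetic covariance: off-diagonal entries of the BM
# covariance scaled by lambda, diagonal untouched.
lambda_cov <- function(C, lambda) {
  V <- lambda * C
  diag(V) <- diag(C)
  V
}

gls_fit_at <- function(y, X, C, lambda) {
  n <- length(y)
  V <- lambda_cov(C, lambda)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  w <- function(M) backsolve(ch, forwardsolve(t(ch), M))
  ViX <- w(X); Viy <- w(y)
  XtViX <- crossprod(X, ViX)
  beta <- tryCatch(solve(XtViX, crossprod(X, Viy)),
                   error = function(e) NULL)
  if (is.null(beta)) return(NULL)
  e <- y - X %*% beta
  Vie <- w(e)
  rss <- drop(crossprod(e, Vie))
  sigma2_ml <- rss / n
  logdetV <- 2 * sum(log(diag(ch)))
  ll <- -0.5 * n * log(2 * pi) - 0.5 * n * log(sigma2_ml) -
    0.5 * logdetV - 0.5 * n
  list(beta = drop(beta), rss = rss, XtViX = XtViX, logLik = ll,
       chol = ch, w = w)
}

#' Phylogenetic generalized least squares with Pagel's lambda
#'
#' GLS regression with residual covariance `lambda * C` off the diagonal
#' and `diag(C)` on it, where `C` is the Brownian tip covariance of the
#' tree. `lambda` is either fixed or estimated by profile maximum
#' likelihood (grid over 0..1 in steps of 0.01, refined by golden-section
#' search). Categorical predictors expand to treatment contrasts and
#' interactions to product terms via the standard formula interface.
#'
#' @param formula model formula; variables looked up in `data`.
#' @param data data frame with rownames (or a `species` column) matching
#'   the tree's tip labels.
#' @param tree an [ape::phylo] tree.
#' @param lambda `"ML"` (default) or a fixed value in `[0, 1]`.
#' @return a `pgls_fit`: `coefficients` table (estimate, SE, t, two-sided
#'   p), `lambda`, `logLik`, `df` (model, residual), `adj_r2`, `n`.
#' @export
pgls <- function(formula, data, tree, lambda = "ML") {
  data <- as.data.frame(data)
  if (!is.null(data$species)) rownames(data) <- data$species
  common <- intersect(tree$tip.label, rownames(data))
  if (!length(common)) stop("no species shared between tree and data")
  if (length(common) < nrow(data) || length(common) < ape::Ntip(tree)) {
    tree <- ape::keep.tip(tree, common)
  }
  data <- data[tree$tip.label, , drop = FALSE]
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  n <- length(y)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("design is rank deficient; aliased terms: ",
         paste(aliased, collapse = ", "))
  }
  C <- ape::vcv(tree)[rownames(data), rownames(data)]

  prof <- function(l) {
    f <- gls_fit_at(y, X, C, l)
    if (is.null(f)) -Inf else f$logLik
  }
  if (identical(lambda, "ML")) {
    grid <- seq(0, 1, by = 0.01)
    lls <- vapply(grid, prof, 1)
    i <- which.max(lls)
    lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, length(grid))]
    gr <- (sqrt(5) - 1) / 2
    a <- lo; b <- hi
    x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
    f1 <- prof(x1); f2 <- prof(x2)
    for (k in 1:40) {
      if (f1 < f2) {
        a <- x1; x1 <- x2; f1 <- f2
        x2 <- a + gr * (b - a); f2 <- prof(x2)
      } else {
        b <- x2; x2 <- x1; f2 <- f1
        x1 <- b - gr * (b - a); f1 <- prof(x1)
      }
      if (b - a < 1e-6) break
    }
    lam <- (a + b) / 2
    if (prof(grid[i]) > prof(lam)) lam <- grid[i]
  } else {
    lam <- as.numeric(lambda)
    if (lam < 0 || lam > 1) stop("lambda must be in [0, 1]")
  }

  fit <- gls_fit_at(y, X, C, lam)
  if (is.null(fit)) stop("singular phylogenetic covariance at lambda = ", lam)
  k <- ncol(X)
  sigma2 <- fit$rss / (n - k)
  covb <- sigma2 * solve(fit$XtViX)
  se <- sqrt(diag(covb))
  tval <- fit$beta / se
  pval <- 2 * stats::pt(-abs(tval), df = n - k)
  # GLS R^2 against the intercept-only GLS fit under the same covariance
  f0 <- gls_fit_at(y, matrix(1, n, 1), C, lam)
  r2 <- 1 - fit$rss / f0$rss
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - k)
  coefs <- data.frame(term = colnames(X), estimate = fit$beta, se = se,
                      t = tval, p = pval, row.names = NULL,
                      stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, lambda = lam, logLik = fit$logLik,
                 df = c(model = k - 1, residual = n - k),
                 adj_r2 = adj_r2, r2 = r2, n = n,
                 fitted = drop(X %*% fit$beta), formula = formula),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("PGLS fit: lambda = %.3f, d.f. = %d,%d, adjusted R2 = %.2f\n",
              x$lambda, x$df["model"], x$df["residual"], x$adj_r2))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R2_j) where R2_j is the coefficient of determination
#' of predictor j regressed (with intercept) on all other predictors.
#' Perfectly collinear predictors are reported as `Inf` rather than
#' raising an error.
#'
#' @param design numeric predictor matrix or data frame (>= 2 columns,
#'   each with positive variance).
#' @return named numeric vector of VIFs.
#' @export
vif <- function(design) {
  X <- as.matrix(design)
  if (ncol(X) < 2) stop("need at least 2 predictors")
  if (any(apply(X, 2, stats::var) <= 0)) {
    stop("every predictor needs positive variance")
  }
  out <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 1)
  names(out) <- colnames(X)
  out
}

#' Simulate a predictor table with a known PGLS structure
#'
#' Generates the standard species-level predictor set with realistic
#' positivity and a response `design %*% betas + error` whose error is
#' MVN with a Pagel-lambda tree covariance — ground truth for PGLS
#' recovery experiments.
#'
#' @param tree an [ape::phylo] tree (supplies species and ages).
#' @param betas named coefficients on transformed predictor columns (e.g.
#'   `c(log_age = -0.5)`); unnamed predictors get coefficient 0.
#' @param lambda Pagel's lambda of the error covariance, in `[0, 1]`.
#' @param noise_sd marginal error standard deviation scale.
#' @param seed integer seed.
#' @return list: `predictors` (data frame of raw variables),
#'   `design` (transformed/log columns used for the response),
#'   `response` (named vector), `betas`, `lambda`.
#' @export
simulate_predictors <- function(tree, betas = c(log_age = -0.5),
                                lambda = 0.6, noise_sd = 0.3,
                                seed = NULL) {
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n <- ape::Ntip(tree)
  sp <- tree$tip.label
  age <- species_ages(tree)
  pred <- data.frame(
    species = sp,
    body_mass = stats::rlnorm(n, 3.5, 1),
    generation_length = stats::rlnorm(n, 1.2, 0.35),
    range_size = stats::rlnorm(n, 12, 1.2),
    island_proportion = stats::rbeta(n, 0.4, 3),
    mean_temperature = stats::rnorm(n, 16, 7),
    mean_uvb = stats::rlnorm(n, 1.6, 0.4),
    n_competitors = stats::rpois(n, 1.5),
    age = as.numeric(age[sp]),
    measurement_error = abs(stats::rnorm(n, 0.05, 0.02)),
    clade = paste0("cl", 1 + (seq_len(n) %% 3)),
    migratory = sample(c("resident", "migrant"), n, TRUE, c(0.8, 0.2)),
    stringsAsFactors = FALSE)
  design <- data.frame(
    log_age = log(pred$age),
    log_body_mass = log(pred$body_mass),
    log_generation_length = log(pred$generation_length),
    log_range_size = log(pred$range_size),
    log_n_competitors = log1p(pred$n_competitors),
    island_proportion = pred$island_proportion,
    mean_temperature = pred$mean_temperature,
    mean_uvb = pred$mean_uvb,
    measurement_error = pred$measurement_error,
    row.names = sp)
  b <- stats::setNames(numeric(ncol(design)), colnames(design))
  if (length(betas)) {
    if (is.null(names(betas)) || !all(names(betas) %in% names(b))) {
      stop("betas must be named by design columns: ",
           paste(names(b), collapse = ", "))
    }
    b[names(betas)] <- betas
  }
  C <- ape::vcv(tree)[sp, sp]
  V <- lambda_cov(C / mean(diag(C)), lambda)
  err <- drop(crossprod(chol(V), stats::rnorm(n))) * noise_sd
  response <- drop(as.matrix(design) %*% b) + err
  names(response) <- sp
  list(predictors = pred, design = design, response = response,
       betas = b, lambda = lambda)
}
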