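# Derived stage seeds: one global seed reproduces a whole run.
stage_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 131 + k * 7919) %% 2147483647)
}

#' Write a shape space to CSV files
#'
#' Emits `consensus.csv` (or the GLS center for pPCA), `eigenvalues.csv`
#' (eigenvalue + variance fraction per axis) and `scores.csv`
#' (specimen x PC1..PCk).
#'
#' @param space a `shape_space`.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @export
write_shape_space <- function(space, dir, prefix = space$method) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(center = space$center),
                   file.path(dir, paste0(prefix, "_center.csv")),
                   row.names = FALSE)
  utils::write.csv(data.frame(axis = seq_along(space$evalues),
                              eigenvalue = space$evalues,
                              var_fraction = space$var_fraction),
                   file.path(dir, paste0(prefix, "_eigenvalues.csv")),
                   row.names = FALSE)
  sc <- data.frame(species = rownames(space$scores), space$scores,
                   row.names = NULL, check.names = FALSE)
  utils::write.csv(sc, file.path(dir, paste0(prefix, "_scores.csv")),
                   row.names = FALSE)
  invisible(dir)
}

#' Write a QC report as CSV
#' @param report a `qc_report`.
#' @param path output CSV path.
#' @export
write_qc_report <- function(report, path) {
  df <- report$users
  df$measurement_error <- report$measurement_error
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write posterior samples as JSON lines
#'
#' One sample per line: record index, shift count, log-likelihood,
#' log-prior and the shift entries.
#'
#' @param post a `rate_posterior`.
#' @param path output path.
#' @export
write_rate_posterior <- function(post, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(post$k)) {
    rec <- list(sample = i, k = post$k[i], loglik = post$loglik[i],
                logprior = post$logprior[i],
                entries = as.data.frame(post$entries[[i]]))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Write branch-rate summaries as CSV
#' @param summary output of [summarize_rates()].
#' @param path output CSV path.
#' @export
write_rate_summary <- function(summary, path) {
  utils::write.csv(summary$edges, path, row.names = FALSE)
  invisible(path)
}

#' Write a PGLS fit as a coefficient table plus metadata
#'
#' The CSV mirrors the conventional presentation (Predictor, Slope, SE,
#' t, P); a JSON sidecar holds lambda, degrees of freedom, adjusted R2
#' and n.
#'
#' @param fit a `pgls_fit`.
#' @param path output CSV path (`.json` sidecar written alongside).
#' @export
write_pgls_fit <- function(fit, path) {
  tab <- data.frame(Predictor = fit$coefficients$term,
                    Slope = fit$coefficients$estimate,
                    SE = fit$coefficients$se,
                    t = fit$coefficients$t,
                    P = fit$coefficients$p)
  utils::write.csv(tab, path, row.names = FALSE)
  meta <- list(lambda = fit$lambda, df_model = unname(fit$df["model"]),
               df_residual = unname(fit$df["residual"]),
               adj_r2 = fit$adj_r2, logLik = fit$logLik, n = fit$n)
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
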