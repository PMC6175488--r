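#' Configuration for a full pipeline run
#'
#' Every tunable has a documented default equal to the conventional value
#' where one exists: QC distance threshold 0.2, cumulative variance cut
#' 0.99, PSRF gate 1.1, ESS gate 200, minimum clade size 5, burn-in 0.5.
#'
#' @param seed global seed; every stage seed derives from it.
#' @param n_tips,p_modes,n_users,noise_sd synthetic-data sizes: tips,
#'   latent shape modes evolving on the tree, users per specimen, markup
#'   noise.
#' @param corrupt_fraction fraction of specimens given one corrupted user.
#' @param d_max QC between-user Procrustes distance threshold.
#' @param cum_var cumulative variance fraction for axis selection.
#' @param max_axes cap on the number of retained axes (markup noise can
#'   spread a long tail of near-zero axes; rate inference uses at most
#'   this many leading components, default 8).
#' @param mcmc an [mcmc_settings()] (seed overridden by the derived
#'   stage seed).
#' @param n_chains independent MCMC chains for the convergence gate.
#' @param psrf_max,ess_min convergence gates (warn, not fail).
#' @param min_clade_size minimum clade size for clade-level analyses.
#' @param lambda PGLS lambda mode (`"ML"` or fixed value).
#' @param grid_dims,cell_km,occupancy,island_fraction grid parameters.
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1, n_tips = 32, p_modes = 2, n_users = 3,
                       noise_sd = 0.01, corrupt_fraction = 0.2,
                       d_max = 0.2, cum_var = 0.99, max_axes = 8,
                       mcmc = mcmc_settings(n_iter = 5000, thin = 10),
                       n_chains = 2, psrf_max = 1.1, ess_min = 200,
                       min_clade_size = 5, lambda = "ML",
                       grid_dims = c(12, 12), cell_km = 110,
                       occupancy = 0.15, island_fraction = 0.2) {
  structure(as.list(environment()), class = "run_config")
}

# Partition tips into monophyletic clades by splitting any clade larger
# than max_size into its child subtrees.
partition_clades <- function(tree, max_size = NULL) {
  n <- ape::Ntip(tree)
  if (is.null(max_size)) max_size <- max(5, ceiling(n / 4))
  root <- n + 1L
  labels <- stats::setNames(rep(NA_character_, n), tree$tip.label)
  todo <- tree$edge[tree$edge[, 1] == root, 2]
  nxt <- 0L
  while (length(todo)) {
    node <- todo[1]; todo <- todo[-1]
    tips <- tips_under(tree, node)
    if (length(tips) > max_size && node > n) {
      todo <- c(todo, tree$edge[tree$edge[, 1] == node, 2])
    } else {
      nxt <- nxt + 1L
      labels[tree$tip.label[tips]] <- sprintf("clade%02d", nxt)
    }
  }
  labels
}

tips_under <- function(tree, node) {
  n <- ape::Ntip(tree)
  if (node <= n) return(node)
  out <- integer(0); todo <- node
  while (length(todo)) {
    ch <- tree$edge[tree$edge[, 1] %in% todo, 2]
    out <- c(out, ch[ch <= n])
    todo <- ch[ch > n]
  }
  sort(out)
}

#' Species shapes evolving on a tree
#'
#' Builds one true landmark configuration per species: latent shape-mode
#' scores evolve by Brownian motion on the tree and displace the template
#' along fixed orthonormal deformation modes. Ties the morphometric
#' stages to the phylogeny so downstream PCA axes recover heritable
#' variation.
#'
#' @param tree an [ape::phylo] tree.
#' @param template a `landmark_config`.
#' @param p_modes number of latent modes.
#' @param amplitude displacement scale per unit score.
#' @param scalars optional [rate_config()] of planted rate shifts.
#' @param seed integer seed.
#' @return list: `shapes` (named list of configurations), `scores`
#'   (true mode scores), `modes` (3k x p matrix).
#' @export
simulate_species_shapes <- function(tree, template, p_modes = 2,
                                    amplitude = 0.05, scalars = NULL,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(template$coords)
  modes <- qr.Q(qr(matrix(stats::rnorm(3 * k * p_modes), 3 * k)))
  params <- mvbm_params(numeric(p_modes), diag(p_modes))
  scores <- simulate_traits(tree, params, scalars = scalars)
  shapes <- lapply(tree$tip.label, function(sp) {
    disp <- matrix(modes %*% scores[sp, ], k, 3) * amplitude
    landmark_config(template$coords + disp, template$type,
                    template$curve)
  })
  names(shapes) <- tree$tip.label
  for (i in seq_along(shapes)) {
    attributes(shapes[[i]]) <- utils::modifyList(attributes(template),
                                                 attributes(shapes[[i]]))
  }
  list(shapes = shapes, scores = scores, modes = modes)
}

#' Run the full pipeline end to end
#'
#' Chains every stage on synthetic data: simulate tree, species shapes
#' and multi-user markups; QC and user-average each specimen; GPA with
#' semi-landmark sliding; PCA and pPCA trait spaces with cumulative-
#' variance axis selection; variable-rates MCMC (multiple chains with
#' PSRF/ESS convergence gates that warn, never abort); branch-rate
#' summaries and tip rates; ML clade rates; species- and clade-level
#' predictor tables; PGLS fits and VIFs. Artifacts and a manifest are
#' written under `out_dir`.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @return invisibly, a list of the main in-memory results.
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("run")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- c(sprintf("seed: %d", config$seed),
                sprintf("package: beakrates %s",
                        as.character(utils::packageVersion("beakrates"))))
  warn <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
  }

  tree <- stage("simulate_tree",
                simulate_tree(config$n_tips, seed = stage_seed(config$seed, 1)))
  write_newick(tree, file.path(out_dir, "tree.nwk"))
  manifest <- c(manifest, sprintf("stage simulate_tree: %d tips", config$n_tips))

  truth <- stage("simulate_shapes",
                 simulate_species_shapes(tree, beak_template(),
                                         p_modes = config$p_modes,
                                         seed = stage_seed(config$seed, 2)))

  set.seed(stage_seed(config$seed, 3))
  n_corrupt <- round(config$corrupt_fraction * config$n_tips)
  corrupt_sp <- sample(tree$tip.label, n_corrupt)
  types <- c("swap_tomial_edges", "shuffle_curve_order", "outlier_user")
  markups <- lapply(tree$tip.label, function(sp) {
    cr <- if (sp %in% corrupt_sp) {
      list(list(user = sample.int(config$n_users, 1),
                type = sample(types, 1)))
    } else list()
    simulate_markups(truth$shapes[[sp]], n_users = config$n_users,
                     noise_sd = config$noise_sd, corruptions = cr,
                     seed = stage_seed(config$seed, 1000 + match(sp, tree$tip.label)),
                     specimen_id = sp)
  })
  names(markups) <- tree$tip.label
  manifest <- c(manifest, sprintf("stage simulate_markups: %d specimens, %d corrupted",
                                  length(markups), n_corrupt))

  qc <- stage("qc", lapply(markups, qc_markups, d_max = config$d_max))
  qc_df <- do.call(rbind, lapply(names(qc), function(sp) {
    df <- qc[[sp]]$users
    df$specimen <- sp
    df$measurement_error <- qc[[sp]]$measurement_error
    df
  }))
  utils::write.csv(qc_df, file.path(out_dir, "qc_report.csv"),
                   row.names = FALSE)
  n_rej <- sum(!qc_df$accepted)
  manifest <- c(manifest, sprintf("stage qc: %d users rejected", n_rej))

  averaged <- stage("average", lapply(names(markups), function(sp) {
    keep <- qc[[sp]]$users$accepted
    if (!any(keep)) {
      warn <<- c(warn, sprintf("specimen %s: all users rejected, kept all", sp))
      keep <- rep(TRUE, length(keep))
    }
    average_markups(markups[[sp]]$users[keep])
  }))
  names(averaged) <- names(markups)

  ali <- stage("gpa", gpa(averaged))
  ali <- stage("slide", slide_semilandmarks(ali, n_iter = 3))
  manifest <- c(manifest, sprintf("stage gpa+slide: ss = %.6g", ali$ss))

  pca_space <- stage("pca", shape_pca(ali))
  ppca_space <- stage("ppca", shape_ppca(ali, tree))
  write_shape_space(pca_space, out_dir, "pca")
  write_shape_space(ppca_space, out_dir, "ppca")
  traits <- select_axes(pca_space, config$cum_var)
  k_sel <- ncol(traits)
  traits <- traits[, seq_len(min(k_sel, config$max_axes)), drop = FALSE]
  manifest <- c(manifest,
                sprintf("stage select_axes: %d axes reach %.2f of variance, %d retained",
                        k_sel, config$cum_var, ncol(traits)))

  chains <- stage("rates_mcmc", lapply(seq_len(config$n_chains), function(ch) {
    st <- config$mcmc
    st$seed <- stage_seed(config$seed, 20 + ch)
    variable_rates_mcmc(tree, traits, st)
  }))
  ll_traces <- lapply(chains, `[[`, "loglik")
  psrf <- if (length(chains) >= 2) {
    tryCatch(gelman_rubin(ll_traces), error = function(e) NA_real_)
  } else NA_real_
  ess <- tryCatch(effective_sample_size(ll_traces[[1]]),
                  error = function(e) 0)
  if (is.finite(psrf) && psrf >= config$psrf_max) {
    warn <- c(warn, sprintf("PSRF %.3f >= %.2f: between-chain convergence not reached",
                            psrf, config$psrf_max))
  }
  if (ess < config$ess_min) {
    warn <- c(warn, sprintf("ESS %.1f < %d: within-chain convergence not reached",
                            ess, config$ess_min))
  }
  manifest <- c(manifest, sprintf("stage rates_mcmc: PSRF = %.3f, ESS = %.1f",
                                  psrf, ess))
  post <- chains[[1]]
  post$rates <- do.call(rbind, lapply(chains, `[[`, "rates"))
  post$k <- unlist(lapply(chains, `[[`, "k"))
  post$loglik <- unlist(lapply(chains, `[[`, "loglik"))
  post$logprior <- unlist(lapply(chains, `[[`, "logprior"))
  post$entries <- do.call(c, lapply(chains, `[[`, "entries"))
  rates <- stage("summarize_rates", summarize_rates(post))
  write_rate_summary(rates, file.path(out_dir, "branch_rates.csv"))
  write_rate_posterior(post, file.path(out_dir, "posterior.jsonl"))

  clades <- partition_clades(tree)
  clade_fit <- stage("ml_clade_rates",
                     ml_clade_rates(tree, traits, clades,
                                    min_size = config$min_clade_size))
  manifest <- c(manifest, sprintf("stage ml_clade_rates: %d clades fitted",
                                  length(clade_fit$rates)))

  grid <- stage("simulate_grid",
                simulate_range_grid(config$n_tips,
                                    grid_dims = config$grid_dims,
                                    cell_km = config$cell_km,
                                    occupancy = config$occupancy,
                                    island_fraction = config$island_fraction,
                                    seed = stage_seed(config$seed, 4),
                                    species = tree$tip.label))
  set.seed(stage_seed(config$seed, 5))
  me <- vapply(qc, `[[`, 1, "measurement_error")
  extra <- data.frame(species = tree$tip.label,
                      body_mass = stats::rlnorm(config$n_tips, 3.5, 1),
                      generation_length = stats::rlnorm(config$n_tips, 1.2, 0.35),
                      measurement_error = as.numeric(me[tree$tip.label]),
                      clade = clades[tree$tip.label],
                      migratory = grid$species$migratory,
                      stringsAsFactors = FALSE)
  sp_tab <- stage("build_species_table",
                  build_species_table(tree, rates$tip_rates, grid, extra))
  manifest <- c(manifest, sprintf("stage build_species_table: %d species, %d dropped",
                                  nrow(sp_tab$table), sp_tab$n_dropped))

  dat <- sp_tab$table
  dat$log_rate <- sp_tab$response
  sp_formula <- log_rate ~ log_age + log_body_mass +
    log_generation_length + mean_temperature + mean_uvb +
    log_range_size + island_proportion + log_n_competitors +
    measurement_error
  sp_fit <- stage("pgls_species",
                  pgls(sp_formula, dat, tree, lambda = config$lambda))
  write_pgls_fit(sp_fit, file.path(out_dir, "species_pgls.csv"))
  num_cols <- setdiff(all.vars(sp_formula), "log_rate")
  vifs <- stage("vif", vif(as.matrix(dat[, num_cols])))
  utils::write.csv(data.frame(predictor = names(vifs), vif = vifs),
                   file.path(out_dir, "species_vif.csv"), row.names = FALSE)

  cl_tab <- stage("build_clade_table",
                  build_clade_table(tree, clade_fit, traits, grid, clades,
                                    min_size = config$min_clade_size))
  utils::write.csv(cl_tab, file.path(out_dir, "clade_table.csv"),
                   row.names = FALSE)
  cl_fit <- NULL
  if (nrow(cl_tab) >= 8) {
    # representative-tip tree: one member per clade carries its label
    reps <- vapply(cl_tab$clade, function(lab) {
      names(clades)[clades == lab][1]
    }, "")
    cl_tree <- ape::keep.tip(tree, reps)
    cl_dat <- cl_tab
    cl_dat$log_rate <- log(cl_dat$rate)
    rownames(cl_dat) <- reps[cl_dat$clade]
    cl_fit <- stage("pgls_clades",
                    pgls(log_rate ~ log_age + log_distinctiveness +
                           log_richness + log_mean_range_size +
                           island_species_proportion + log_mean_competition,
                         cl_dat, cl_tree, lambda = config$lambda))
    write_pgls_fit(cl_fit, file.path(out_dir, "clade_pgls.csv"))
  } else {
    manifest <- c(manifest, "stage pgls_clades: skipped (< 8 clades)")
  }

  manifest <- c(manifest,
                if (length(warn)) paste("warning:", warn) else "warnings: none",
                "stages: simulate qc average gpa slide pca ppca select_axes rates_mcmc summarize_rates ml_clade_rates simulate_grid build_species_table pgls_species vif build_clade_table pgls_clades")
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(list(tree = tree, qc = qc, alignment = ali, pca = pca_space,
                 ppca = ppca_space, traits = traits, posterior = post,
                 rates = rates, clade_fit = clade_fit,
                 species_fit = sp_fit, clade_fit_pgls = cl_fit,
                 vif = vifs, psrf = psrf, ess = ess,
                 warnings = warn, out_dir = out_dir))
}
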