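#' Morphospace distinctiveness of a clade
#'
#' Euclidean distance between the clade's centroid and the grand centroid
#' of all species over the supplied trait axes (the principal components
#' retained by [select_axes()]). Translation-invariant.
#'
#' @param traits species x axes score matrix with rownames.
#' @param members character vector of clade member species.
#' @return non-negative scalar.
#' @export
clade_distinctiveness <- function(traits, members) {
  traits <- as.matrix(traits)
  if (!length(members)) stop("empty clade member set")
  if (!all(members %in% rownames(traits))) {
    stop("members missing from trait matrix: ",
         paste(setdiff(members, rownames(traits)), collapse = ", "))
  }
  sqrt(sum((colMeans(traits[members, , drop = FALSE]) -
              colMeans(traits))^2))
}

#' Assemble the species-level predictor table
#'
#' Joins tip rates with tree-derived species ages, grid-derived range
#' summaries and competition indices, and user-supplied extras, applying
#' the conventional log transforms (body mass, generation length, range
#' size, age; competitor counts as `log(x + 1)` since they can be zero).
#' Species missing from any source are dropped and counted.
#'
#' @param tree an [ape::phylo] tree.
#' @param tip_rates named vector of species-specific rates (e.g. from
#'   [summarize_rates()]).
#' @param grid a `grid_range_map` covering the species.
#' @param extra data frame with columns species, body_mass,
#'   generation_length, measurement_error, clade, migratory.
#' @param log_rate log-transform the response tip rate (default TRUE).
#' @return list: `table` (predictor data frame, rownames = species),
#'   `response` (named vector of (log) tip rates), `n_dropped`.
#' @export
build_species_table <- function(tree, tip_rates, grid, extra,
                                log_rate = TRUE) {
  ages <- species_ages(tree)
  sp <- Reduce(intersect, list(tree$tip.label, names(tip_rates),
                               names(grid$ranges), extra$species))
  n_dropped <- length(unique(c(tree$tip.label, names(tip_rates),
                               extra$species))) - length(sp)
  if (!length(sp)) stop("no species shared across all sources")
  if (n_dropped > 0) {
    message(n_dropped, " species dropped (missing from >= 1 source)")
  }
  ex <- extra[match(sp, extra$species), ]
  rs <- lapply(sp, function(s) range_summaries(grid, s))
  comp <- vapply(sp, function(s) competition_index(grid, s), 1)
  tab <- data.frame(
    species = sp,
    log_age = log(ages[sp]),
    log_body_mass = log(ex$body_mass),
    log_generation_length = log(ex$generation_length),
    mean_temperature = vapply(rs, `[[`, 1, "mean_temperature"),
    mean_uvb = vapply(rs, `[[`, 1, "mean_uvb"),
    log_range_size = log(vapply(rs, `[[`, 1, "range_size")),
    island_proportion = vapply(rs, `[[`, 1, "island_proportion"),
    log_n_competitors = log1p(comp),
    measurement_error = ex$measurement_error,
    clade = ex$clade,
    migratory = ex$migratory,
    row.names = sp, stringsAsFactors = FALSE)
  response <- tip_rates[sp]
  if (log_rate) response <- log(response)
  list(table = tab, response = response, n_dropped = n_dropped)
}

#' Assemble the clade-level summary table
#'
#' One row per retained clade (at least `min_size` members): relative
#' rate, log morphospace distinctiveness, log species richness, log crown
#' age (height of the clade's most recent common ancestor), log mean
#' range size, proportion of island species (species with more than half
#' their range on islands) and log mean competition index.
#'
#' @param tree an [ape::phylo] ultrametric tree.
#' @param clade_rates a `clade_rate_fit` from [ml_clade_rates()].
#' @param traits species x axes score matrix (for distinctiveness).
#' @param grid a `grid_range_map`.
#' @param clades named vector species -> clade label.
#' @param min_size minimum clade size (default 5).
#' @return data frame, one row per retained clade.
#' @export
build_clade_table <- function(tree, clade_rates, traits, grid, clades,
                              min_size = 5) {
  labs <- names(clade_rates$rates)
  rows <- lapply(labs, function(lab) {
    members <- names(clades)[!is.na(clades) & clades == lab]
    if (length(members) < min_size) return(NULL)
    mrca <- ape::getMRCA(tree, members)
    age <- node_height(tree, mrca)
    rs <- lapply(members, function(s) range_summaries(grid, s))
    comp <- vapply(members, function(s) competition_index(grid, s), 1)
    data.frame(
      clade = lab,
      rate = unname(clade_rates$rates[lab]),
      log_distinctiveness = log(clade_distinctiveness(traits, members)),
      log_richness = log(length(members)),
      log_age = log(age),
      log_mean_range_size = log(mean(vapply(rs, `[[`, 1, "range_size"))),
      island_species_proportion =
        mean(vapply(rs, `[[`, 1, "island_proportion") > 0.5),
      log_mean_competition = log1p(mean(comp)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no clade meets min_size")
  rownames(out) <- out$clade
  out
}
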