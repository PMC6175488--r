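#' Simulate an equal-area occupancy grid with species ranges
#'
#' Abstract equal-area grid (unit squares of side `cell_km`) carrying an
#' island flag and smooth synthetic temperature and UVB fields per cell.
#' Each species' range is grown by seeded flood-fill from a random cell
#' (contiguous, spatially autocorrelated ranges); species carry family,
#' diet-class, foraging-class and migratory-status labels drawn from
#' finite vocabularies.
#'
#' @param n_species number of species.
#' @param grid_dims `c(nx, ny)` cells.
#' @param cell_km cell side length in km (default 110, the conventional
#'   resolution for co-occurrence grids).
#' @param occupancy expected fraction of the grid each species occupies
#'   (in `(0, 1]`).
#' @param n_families number of family labels.
#' @param n_guilds number of diet and of foraging classes.
#' @param island_fraction fraction of cells flagged as island.
#' @param seed integer seed.
#' @param species optional character vector of species names.
#' @return a `grid_range_map`: `cells` data frame (id, x, y, area_km2,
#'   is_island, temperature, uvb), `ranges` (named list of occupied cell
#'   ids) and `species` data frame (species, family, diet, foraging,
#'   migratory).
#' @export
simulate_range_grid <- function(n_species, grid_dims = c(12, 12),
                                cell_km = 110, occupancy = 0.15,
                                n_families = 4, n_guilds = 3,
                                island_fraction = 0.2, seed = NULL,
                                species = NULL) {
  nx <- grid_dims[1]; ny <- grid_dims[2]
  if (nx < 1 || ny < 1) stop("grid_dims must be >= 1")
  if (occupancy <= 0 || occupancy > 1) stop("occupancy must be in (0, 1]")
  if (island_fraction < 0 || island_fraction > 1) {
    stop("island_fraction must be in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  ncell <- nx * ny
  xy <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  # smooth fields: latitudinal gradient plus low-frequency ripples
  temperature <- 28 - 35 * ((xy$y - 0.5) / ny - 0.5)^2 +
    2 * sin(2 * pi * xy$x / nx) + stats::rnorm(ncell, 0, 0.5)
  uvb <- 6 - 8 * ((xy$y - 0.5) / ny - 0.5)^2 +
    0.5 * cos(2 * pi * xy$x / nx) + stats::rnorm(ncell, 0, 0.2)
  cells <- data.frame(id = seq_len(ncell), x = xy$x, y = xy$y,
                      area_km2 = cell_km^2,
                      is_island = stats::runif(ncell) < island_fraction,
                      temperature = temperature, uvb = uvb)
  if (is.null(species)) species <- sprintf("t%d", seq_len(n_species))
  if (length(species) != n_species) stop("species names length mismatch")

  neighbours <- function(id) {
    x <- cells$x[id]; y <- cells$y[id]
    nb <- c(if (x > 1) id - 1L, if (x < nx) id + 1L,
            if (y > 1) id - nx, if (y < ny) id + nx)
    nb
  }
  grow_range <- function(size) {
    start <- sample.int(ncell, 1L)
    occ <- start
    frontier <- setdiff(neighbours(start), occ)
    while (length(occ) < size && length(frontier)) {
      nxt <- frontier[sample.int(length(frontier), 1L)]
      occ <- c(occ, nxt)
      frontier <- setdiff(unique(c(frontier, neighbours(nxt))), occ)
    }
    sort(occ)
  }
  sizes <- pmax(1L, stats::rbinom(n_species, ncell, occupancy))
  ranges <- lapply(sizes, grow_range)
  names(ranges) <- species

  spdf <- data.frame(
    species = species,
    family = paste0("fam", sample.int(n_families, n_species, TRUE)),
    diet = paste0("diet", sample.int(n_guilds, n_species, TRUE)),
    foraging = paste0("for", sample.int(n_guilds, n_species, TRUE)),
    migratory = sample(c("resident", "migrant"), n_species, TRUE,
                       prob = c(0.8, 0.2)),
    stringsAsFactors = FALSE)
  structure(list(cells = cells, ranges = ranges, species = spdf),
            class = "grid_range_map")
}

#' Potential-competition index of a focal species
#'
#' For every grid cell the focal species occupies, counts the other
#' species present in that cell that share its family, diet class and
#' foraging class; returns the mean of these counts across the focal's
#' occupied cells.
#'
#' @param grid a `grid_range_map`.
#' @param focal species name.
#' @return non-negative scalar.
#' @export
competition_index <- function(grid, focal) {
  occ <- grid$ranges[[focal]]
  if (is.null(occ) || !length(occ)) stop("focal species absent from grid")
  sp <- grid$species
  me <- sp[sp$species == focal, ]
  peers <- sp$species[sp$species != focal &
                        sp$family == me$family &
                        sp$diet == me$diet &
                        sp$foraging == me$foraging]
  if (!length(peers)) return(0)
  counts <- vapply(occ, function(cell) {
    sum(vapply(peers, function(p) cell %in% grid$ranges[[p]], TRUE))
  }, 1)
  mean(counts)
}

#' Range summaries of a focal species
#'
#' @param grid a `grid_range_map`.
#' @param focal species name.
#' @return list: `range_size` (summed cell area, km2),
#'   `island_proportion` (island area share of the range),
#'   `mean_temperature` and `mean_uvb` (unweighted cell means).
#' @export
range_summaries <- function(grid, focal) {
  occ <- grid$ranges[[focal]]
  if (is.null(occ) || !length(occ)) stop("focal species absent from grid")
  cc <- grid$cells[match(occ, grid$cells$id), ]
  list(range_size = sum(cc$area_km2),
       island_proportion = sum(cc$area_km2[cc$is_island]) /
         sum(cc$area_km2),
       mean_temperature = mean(cc$temperature),
       mean_uvb = mean(cc$uvb))
}
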