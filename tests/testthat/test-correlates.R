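# hand-built grid for the deterministic toys
toy_grid <- function(ranges, species_df, n_cells = 4, island = NULL,
                     temp = 20, cell_km = 1) {
  if (is.null(island)) island <- rep(FALSE, n_cells)
  cells <- data.frame(id = seq_len(n_cells), x = seq_len(n_cells), y = 1,
                      area_km2 = cell_km^2, is_island = island,
                      temperature = rep(temp, n_cells),
                      uvb = rep(5, n_cells))
  structure(list(cells = cells, ranges = ranges, species = species_df),
            class = "grid_range_map")
}

test_that("species ages read terminal branch lengths off the tree", {
  cherry <- ape::read.tree(text = "(A:1.0,B:1.0);")
  expect_equal(species_ages(cherry), c(A = 1, B = 1))

  cat_tree <- ape::read.tree(text = "(((A:0.5,B:1.5):1,C:2.5):1,D:3.5);")
  ages <- species_ages(cat_tree)
  expect_equal(ages[c("A", "B", "C", "D")],
               c(A = 0.5, B = 1.5, C = 2.5, D = 3.5))

  # invariant to the order tips appear in the Newick string
  perm <- ape::read.tree(text = "(D:3.5,((B:1.5,A:0.5):1,C:2.5):1);")
  expect_equal(species_ages(perm)[names(ages)], ages)
})

test_that("competition index counts confamilial guild-sharing co-occurrers", {
  spdf <- data.frame(species = c("s1", "s2", "s3"),
                     family = c("f1", "f1", "f2"),
                     diet = c("d1", "d1", "d1"),
                     foraging = c("g1", "g1", "g1"),
                     migratory = "resident", stringsAsFactors = FALSE)
  # focal alone
  g <- toy_grid(list(s1 = 1:2), spdf[1, ])
  expect_equal(competition_index(g, "s1"), 0)

  # focal in cells 1-2; one matching competitor in cell 1 only -> 0.5
  g2 <- toy_grid(list(s1 = 1:2, s2 = 1L), spdf[1:2, ])
  expect_equal(competition_index(g2, "s1"), 0.5)

  # same cells but different family -> 0
  g3 <- toy_grid(list(s1 = 1:2, s3 = 1:2), spdf[c(1, 3), ])
  expect_equal(competition_index(g3, "s1"), 0)

  # identical 4-cell ranges, shared guild: 1 competitor in each cell
  g4 <- toy_grid(list(s1 = 1:4, s2 = 1:4), spdf[1:2, ])
  expect_equal(competition_index(g4, "s1"), 1)
  expect_equal(competition_index(g4, "s2"), 1)

  expect_error(competition_index(g4, "absent"), "absent")
})

test_that("range summaries aggregate area, islands and climate", {
  spdf <- data.frame(species = "s1", family = "f1", diet = "d1",
                     foraging = "g1", migratory = "resident")
  g <- toy_grid(list(s1 = 1:4), spdf,
                island = c(TRUE, FALSE, FALSE, FALSE))
  rs <- range_summaries(g, "s1")
  expect_equal(rs$island_proportion, 0.25)
  expect_equal(rs$mean_temperature, 20)
  expect_equal(rs$range_size, 4)
  g1 <- toy_grid(list(s1 = 3L), spdf, cell_km = 110)
  expect_equal(range_summaries(g1, "s1")$range_size, 110^2)
})

test_that("clade distinctiveness is the centroid distance in score space", {
  tr_sc <- rbind(a = c(3, 4), b = c(3, 4), c = c(-3, -4), d = c(-3, -4))
  expect_equal(clade_distinctiveness(tr_sc, c("a", "b")), 5)
  expect_equal(clade_distinctiveness(tr_sc, rownames(tr_sc)), 0)
  shifted <- sweep(tr_sc, 2, c(10, -7), "+")
  expect_equal(clade_distinctiveness(shifted, c("a", "b")), 5)
  expect_error(clade_distinctiveness(tr_sc, character(0)), "empty")
})

test_that("species table assembles the standard predictors with logs", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  spdf <- data.frame(species = c("A", "B", "C"),
                     family = "f1", diet = "d1", foraging = "g1",
                     migratory = "resident", stringsAsFactors = FALSE)
  g <- toy_grid(list(A = 1:2, B = 1L, C = 2:3), spdf,
                island = c(TRUE, FALSE, FALSE, FALSE))
  extra <- data.frame(species = c("A", "B", "C", "D"),
                      body_mass = c(1, 1, 1, 1),
                      generation_length = c(1, 1, 1, 1),
                      measurement_error = c(0.02, 0.03, 0.04, 0.05),
                      clade = "x", migratory = "resident",
                      stringsAsFactors = FALSE)
  rates <- c(A = 2, B = 1, C = 3, D = 4)
  expect_message(
    st <- build_species_table(tr, rates, g, extra),
    "dropped")  # D missing from the grid
  expect_equal(sort(rownames(st$table)), c("A", "B", "C"))
  expect_equal(st$n_dropped, 1)
  expect_setequal(
    setdiff(colnames(st$table), c("species", "clade", "migratory")),
    c("log_age", "log_body_mass", "log_generation_length",
      "mean_temperature", "mean_uvb", "log_range_size",
      "island_proportion", "log_n_competitors", "measurement_error"))
  # all-ones inputs log to zero
  expect_equal(unname(st$table["A", "log_body_mass"]), 0)
  expect_equal(unname(st$response["A"]), log(2))
})

test_that("clade table enforces the minimum size and reads MRCA ages", {
  tr <- simulate_tree(12, seed = 30)
  e <- find_clade_edge(tr, 6, 9)
  tipsA <- clade_tips(tr, e)
  cl <- stats::setNames(ifelse(tr$tip.label %in% tipsA, "A", "B"),
                        tr$tip.label)
  if (sum(cl == "B") >= 5 &&
      !ape::is.monophyletic(tr, names(cl)[cl == "B"])) {
    cl[cl == "B"] <- NA
  }
  X <- simulate_traits(tr, mvbm_params(c(0, 0), diag(2)), seed = 31)
  fit <- ml_clade_rates(tr, X, cl, min_size = 5)
  spdf <- data.frame(species = tr$tip.label, family = "f1", diet = "d1",
                     foraging = "g1", migratory = "resident",
                     stringsAsFactors = FALSE)
  g <- simulate_range_grid(12, grid_dims = c(5, 5), occupancy = 0.3,
                           seed = 32, species = tr$tip.label)
  tab <- build_clade_table(tr, fit, X, g, cl, min_size = 5)
  expect_equal(nrow(tab), length(fit$rates))
  mrca <- ape::getMRCA(tr, tipsA)
  expect_equal(tab["A", "log_age"],
               log(beakrates:::node_height(tr, mrca)))
  expect_equal(tab["A", "log_richness"], log(length(tipsA)))
})

test_that("PGLS matches OLS at lambda 0 and dense GLS at lambda 1", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  d <- data.frame(y = c(1, 2, 4, 5), x = c(0, 1, 2, 3),
                  row.names = c("A", "B", "C", "D"))
  f0 <- pgls(y ~ x, d, tr, lambda = 0)
  ols <- stats::lm(y ~ x, d)
  expect_equal(f0$coefficients$estimate, unname(stats::coef(ols)),
               tolerance = 1e-8)

  f1 <- pgls(y ~ x, d, tr, lambda = 1)
  C <- ape::vcv(tr)[rownames(d), rownames(d)]
  beta <- dense_gls(d$y, cbind(1, d$x), C)
  expect_equal(f1$coefficients$estimate, unname(beta), tolerance = 1e-10)

  expect_error(pgls(y ~ x + I(2 * x), d, tr, lambda = 0), "rank deficient")
})

test_that("ML lambda attains the profile optimum and recovers the truth", {
  set.seed(40)
  tr <- simulate_tree(80, seed = 41)
  sim <- simulate_predictors(tr, betas = c(log_age = -0.5), lambda = 0.6,
                             seed = 42)
  d <- sim$design; d$y <- sim$response
  fml <- pgls(y ~ log_age, d, tr, lambda = "ML")
  for (lf in c(0, 0.3, 0.7, 1)) {
    expect_gte(fml$logLik, pgls(y ~ log_age, d, tr, lambda = lf)$logLik - 1e-6)
  }
  co <- fml$coefficients[fml$coefficients$term == "log_age", ]
  expect_lt(abs(co$estimate + 0.5), 4 * co$se)

  # independent route: nlme::gls with a Pagel correlation structure
  dd <- d; dd$sp <- rownames(d)
  gfit <- nlme::gls(y ~ log_age, data = dd,
                    correlation = ape::corPagel(0.5, tr, form = ~sp),
                    method = "ML")
  expect_equal(unname(fml$coefficients$estimate),
               unname(stats::coef(gfit)), tolerance = 1e-3)
  expect_equal(fml$lambda,
               unname(stats::coef(gfit$modelStruct$corStruct,
                                  unconstrained = FALSE)),
               tolerance = 0.02)
})

test_that("PGLS handles factors and interaction terms", {
  set.seed(43)
  tr <- simulate_tree(60, seed = 44)
  sim <- simulate_predictors(tr, betas = c(log_age = -0.5), lambda = 0.5,
                             seed = 45)
  d <- sim$design
  d$migratory <- sim$predictors$migratory
  d$y <- sim$response
  f <- pgls(y ~ log_age * migratory, d, tr, lambda = "ML")
  expect_setequal(f$coefficients$term,
                  c("(Intercept)", "log_age", "migratoryresident",
                    "log_age:migratoryresident"))
  expect_equal(unname(f$df["residual"]), 60 - 4)
})

test_that("VIF follows its closed form and flags exact collinearity", {
  set.seed(50)
  # two predictors with sample correlation exactly 0.9
  z1 <- stats::rnorm(200)
  z2 <- stats::rnorm(200)
  z1 <- drop(scale(z1)); z2 <- drop(scale(stats::resid(stats::lm(z2 ~ z1))))
  x2 <- 0.9 * z1 + sqrt(1 - 0.81) * z2
  v <- vif(cbind(a = z1, b = x2))
  expect_equal(unname(v), rep(1 / (1 - 0.81), 2), tolerance = 1e-8)

  # exactly orthogonal (and centred) predictors: VIF 1
  Q <- qr.Q(qr(cbind(1, matrix(stats::rnorm(200 * 3), 200))))[, 2:4]
  expect_equal(unname(vif(Q)), rep(1, 3), tolerance = 1e-8)

  # duplicated column: infinity flag, not an error
  v2 <- vif(cbind(z1, z1, z2))
  expect_true(is.infinite(v2[1]) && is.infinite(v2[2]))

  # agreement with an independent regression-based computation
  M <- matrix(stats::rnorm(300), 100)
  M[, 2] <- M[, 2] + 0.5 * M[, 1]
  v3 <- vif(M)
  for (j in 1:3) {
    r2 <- summary(stats::lm(M[, j] ~ M[, -j]))$r.squared
    expect_equal(unname(v3[j]), 1 / (1 - r2), tolerance = 1e-8)
  }
})
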