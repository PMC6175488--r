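test_that("Procrustes distance is a similarity-invariant pseudo-metric", {
  tpl <- beak_template()
  expect_equal(procrustes_distance(tpl, tpl), 0)

  set.seed(1)
  for (i in 1:5) {
    b <- random_similarity(tpl$coords)
    expect_lt(procrustes_distance(tpl$coords, b), 1e-9)
  }
  # symmetry and triangle inequality on random triples
  for (i in 1:10) {
    A <- matrix(stats::rnorm(30), 10)
    B <- matrix(stats::rnorm(30), 10)
    C <- matrix(stats::rnorm(30), 10)
    dab <- procrustes_distance(A, B)
    expect_equal(dab, procrustes_distance(B, A), tolerance = 1e-9)
    expect_lte(dab,
               procrustes_distance(A, C) + procrustes_distance(C, B) + 1e-6)
  }
})

test_that("Procrustes distance matches a brute-force rotation search", {
  # planar triangles: equilateral vs right isosceles
  eq <- cbind(c(0, 1, 0.5), c(0, 0, sqrt(3) / 2), 0)
  ri <- cbind(c(0, 1, 0), c(0, 0, 1), 0)
  expect_equal(procrustes_distance(eq, ri),
               brute_procrustes_distance(eq, ri), tolerance = 1e-6)
  set.seed(7)
  tpl <- beak_template()
  b <- tpl$coords + matrix(stats::rnorm(length(tpl$coords), 0, 0.05),
                           nrow(tpl$coords))
  expect_equal(procrustes_distance(tpl$coords, b),
               brute_procrustes_distance(tpl$coords, b), tolerance = 1e-6)
})

test_that("GPA is a fixed point on aligned data and collapses similarity copies", {
  tpl <- beak_template()
  set.seed(2)
  noisy <- lapply(1:4, function(i) {
    tpl$coords + matrix(stats::rnorm(length(tpl$coords), 0, 0.01),
                        nrow(tpl$coords))
  })
  g1 <- gpa(noisy)
  aligned_cfgs <- lapply(seq_len(dim(g1$aligned)[3]),
                         function(s) g1$aligned[, , s])
  g2 <- gpa(aligned_cfgs)
  expect_equal(g2$aligned, g1$aligned, tolerance = 1e-6)
  expect_equal(g2$ss, g1$ss, tolerance = 1e-8)

  copies <- lapply(1:10, function(i) random_similarity(tpl$coords))
  expect_lt(gpa(copies)$ss, 1e-10)

  # invariance (up to a global rotation) to input order and to
  # pre-transforming an input by a similarity transform
  g3 <- gpa(noisy[c(3, 1, 4, 2)])
  expect_equal(g3$ss, g1$ss, tolerance = 1e-8)
  expect_lt(procrustes_distance(g3$consensus, g1$consensus), 1e-6)
  noisy2 <- noisy; noisy2[[2]] <- random_similarity(noisy[[2]])
  expect_equal(gpa(noisy2)$ss, g1$ss, tolerance = 1e-8)
})

test_that("two-shape GPA reduces to the pairwise superimposition", {
  tpl <- beak_template()
  set.seed(3)
  b <- tpl$coords + matrix(stats::rnorm(length(tpl$coords), 0, 0.01),
                           nrow(tpl$coords))
  d <- procrustes_distance(tpl$coords, b)
  g <- gpa(list(tpl$coords, b))
  expect_equal(g$ss, d^2 / 2, tolerance = 1e-3)
})

test_that("user averaging recovers the template from symmetric or noisy users", {
  tpl <- beak_template()
  expect_equal(average_markups(list(tpl))$coords, tpl$coords)

  # symmetric displacements cancel to second order: keep them small so
  # the average lands on the template within strict tolerance
  delta <- matrix(stats::rnorm(length(tpl$coords), 0, 1e-4),
                  nrow(tpl$coords))
  u1 <- landmark_config(tpl$coords + delta, tpl$type, tpl$curve)
  u2 <- landmark_config(tpl$coords - delta, tpl$type, tpl$curve)
  avg <- average_markups(list(u1, u2))
  expect_lt(procrustes_distance(avg, tpl), 1e-6)

  set.seed(4)
  s <- 0.01
  users <- lapply(1:3, function(i) {
    landmark_config(tpl$coords +
                      matrix(stats::rnorm(length(tpl$coords), 0, s),
                             nrow(tpl$coords)),
                    tpl$type, tpl$curve)
  })
  d_users <- vapply(users, function(u) procrustes_distance(u, tpl), 1)
  expect_lt(procrustes_distance(average_markups(users), tpl), mean(d_users))
  expect_error(average_markups(list()), "no accepted")
})

test_that("semi-landmark sliding lowers bending energy and is stationary", {
  tpl <- beak_template()
  tr <- simulate_tree(6, seed = 8)
  shapes <- simulate_species_shapes(tr, tpl, amplitude = 0.01,
                                    seed = 9)$shapes
  g <- gpa(shapes)
  sl <- slide_semilandmarks(g, n_iter = 3)
  expect_true(all(sl$bending[, "after"] <= sl$bending[, "before"] + 1e-12))
  expect_lt(sl$bending[1, "after"], sl$bending[1, "before"])

  # shapes already at the consensus: nothing moves
  cons_cfgs <- lapply(1:3, function(i) {
    landmark_config(g$consensus, tpl$type, tpl$curve)
  })
  g0 <- gpa(cons_cfgs)
  sl0 <- slide_semilandmarks(g0, n_iter = 1)
  expect_equal(sl0$aligned, g0$aligned, tolerance = 1e-8)
  expect_lt(sl0$bending[1, "after"], 1e-12)

  # independent coordinate-descent line search cannot beat the closed
  # form by more than 5%
  Be <- beakrates:::bending_energy_matrix(g$consensus)
  lay <- g$layout
  semis <- which(lay$type == "semi")
  # coordinate-descent line search under the same order-preserving cap
  # (half the local inter-point spacing)
  oracle_energy <- function(Y) {
    tang <- beakrates:::curve_tangents(Y, lay)
    caps <- vapply(semis, function(j) {
      cv <- lay$curve[j]
      idx <- which(lay$curve == cv)
      pos <- match(j, idx)
      nb <- idx[c(max(pos - 1, 1), min(pos + 1, length(idx)))]
      0.5 * min(sqrt(rowSums((Y[nb, , drop = FALSE] -
                                rep(Y[j, ], each = length(nb)))^2)))
    }, 1)
    Y2 <- Y
    shift <- stats::setNames(numeric(length(semis)), semis)
    for (sweep_i in 1:5) {
      for (jj in seq_along(semis)) {
        j <- semis[jj]
        u <- tang[j, ]
        if (sum(u^2) == 0) next
        f <- function(t) {
          Yt <- Y2; Yt[j, ] <- Y2[j, ] + t * u
          bending_energy(Yt - g$consensus, Be)
        }
        lo <- -caps[jj] - shift[jj]; hi <- caps[jj] - shift[jj]
        if (hi - lo < 1e-10) next
        t_star <- stats::optimize(f, c(lo, hi))$minimum
        Y2[j, ] <- Y2[j, ] + t_star * u
        shift[jj] <- shift[jj] + t_star
      }
    }
    bending_energy(Y2 - g$consensus, Be)
  }
  one_pass <- slide_semilandmarks(g, n_iter = 1)
  e_oracle <- sum(vapply(seq_len(dim(g$aligned)[3]), function(s) {
    oracle_energy(g$aligned[, , s])
  }, 1))
  expect_lt(one_pass$bending[1, "after"], e_oracle * 1.05)
})

test_that("PCA recovers planted spectra and conserves variance", {
  set.seed(5)
  # single direction of variation
  base <- matrix(stats::rnorm(12), 1)
  X1 <- outer(stats::rnorm(8), drop(base)) +
    matrix(rep(stats::rnorm(12), each = 8), 8)
  p1 <- shape_pca(X1)
  expect_equal(p1$var_fraction[1], 1, tolerance = 1e-9)

  X <- matrix(stats::rnorm(60), 6)
  p <- shape_pca(X)
  expect_equal(sum(p$var_fraction), 1, tolerance = 1e-9)
  # reconstruction from all axes reproduces the centred data
  Xc <- sweep(X, 2, p$center)
  expect_equal(p$scores %*% t(p$evectors), Xc, tolerance = 1e-9)
  expect_equal(unname(colMeans(p$scores)), numeric(ncol(p$scores)),
               tolerance = 1e-9)

  # planted eigen-spectrum recovered proportionally: zero-mean
  # orthonormal score columns scaled to the target eigenvalues
  n <- 9
  Z <- qr.Q(qr(cbind(1, matrix(stats::rnorm(n * 3), n))))[, 2:4] *
    sqrt(n - 1)
  lam <- c(1, 0.5, 0.1)
  Q <- qr.Q(qr(matrix(stats::rnorm(25), 5)))
  Xp <- Z %*% diag(sqrt(lam)) %*% t(Q[, 1:3])
  pp <- shape_pca(Xp)
  expect_equal(pp$evalues[1:3] / pp$evalues[1], lam / lam[1],
               tolerance = 1e-6)
  expect_lt(max(abs(pp$evalues[4:5])), 1e-12)
})

test_that("pPCA reduces to PCA when shared ancestry vanishes", {
  set.seed(6)
  star <- ape::stree(6, "star"); star$edge.length <- rep(1, 6)
  X <- matrix(stats::rnorm(18), 6,
              dimnames = list(star$tip.label, NULL))
  p1 <- shape_pca(X)
  p2 <- shape_ppca(X, star)
  expect_lt(max(abs(abs(p1$scores) - abs(p2$scores))), 1e-8)
  expect_equal(drop(p2$center), colMeans(X), tolerance = 1e-9)

  # literal identity covariance: exact equality with PCA up to the
  # (n-1) scaling shared by both
  p3 <- shape_ppca(X, diag(6))
  expect_lt(max(abs(abs(p1$scores) - abs(p3$scores))), 1e-10)
})

test_that("pPCA equals the dense GLS computation and phytools", {
  set.seed(7)
  tr <- simulate_tree(8, seed = 77)
  X <- simulate_traits(tr, mvbm_params(c(0, 0, 0),
                                       diag(3) + 0.3), seed = 78)
  p <- shape_ppca(X, tr)
  # dense oracle
  C <- ape::vcv(tr)[rownames(X), rownames(X)]
  Ci <- solve(C); one <- rep(1, 8)
  a <- drop(t(one) %*% Ci %*% X) / drop(t(one) %*% Ci %*% one)
  Xc <- sweep(X, 2, a)
  Ecov <- t(Xc) %*% Ci %*% Xc / 7
  eg <- eigen((Ecov + t(Ecov)) / 2, symmetric = TRUE)
  expect_equal(p$evalues, eg$values, tolerance = 1e-10)
  # GLS-centred scores have zero GLS mean
  gls_mean <- drop(t(one) %*% Ci %*% p$scores) / drop(t(one) %*% Ci %*% one)
  expect_equal(unname(gls_mean), numeric(3), tolerance = 1e-9)
  # independent implementation: phytools
  pp <- phytools::phyl.pca(tr, X, method = "BM", mode = "cov")
  expect_equal(unname(p$evalues), unname(diag(pp$Eval)), tolerance = 1e-8)
  expect_equal(abs(unname(p$scores)), abs(unname(pp$S)), tolerance = 1e-8)
})

test_that("axis selection honours the cumulative-variance rule", {
  # craft data whose variance fractions are exactly (.5,.3,.15,.04,.01)
  set.seed(8)
  fr <- c(0.5, 0.3, 0.15, 0.04, 0.01)
  n <- 12
  Z <- scale(matrix(stats::rnorm(n * 5), n), TRUE, FALSE)
  Z <- qr.Q(qr(Z))[, 1:5] * sqrt(n - 1)
  X <- Z %*% diag(sqrt(fr))
  sp <- shape_pca(X)
  expect_equal(sp$var_fraction[1:5], fr, tolerance = 1e-9)
  expect_equal(ncol(select_axes(sp, 0.99)), 4)
  expect_equal(ncol(select_axes(sp, 1)), 5)
  one_axis <- shape_pca(outer(stats::rnorm(6), c(1, 2)))
  expect_equal(ncol(select_axes(one_axis, 0.5)), 1)
})
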