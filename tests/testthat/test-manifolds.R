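# Geometry oracles use small synthetic manifold sets built in code
# (constructors in helper-fixtures.R).

test_that("result manifolds partition the 380 problems into 19 clouds of 20", {
  probs <- enumerate_problems()
  set.seed(1)
  mr <- matrix(rnorm(380 * 10), 380, 10)
  ms <- extract_result_manifolds(mr, probs)
  expect_length(ms, 19)
  expect_true(all(vapply(ms, nrow, integer(1)) == 20))
  # result 0: one addition + nineteen subtractions; result 18 the reverse
  expect_equal(sum(probs$result == 0 & probs$operator == "add"), 1)
  expect_equal(sum(probs$result == 18 & probs$operator == "sub"), 1)
  # disjoint union recovers all rows
  expect_equal(sort(unname(unlist(lapply(ms, rowSums)))),
               sort(rowSums(mr)))
  expect_error(extract_result_manifolds(mr[-1, ], probs), "differ")
})

test_that("point manifolds reach the classical two-patterns-per-unit capacity", {
  ms <- point_manifold_set(P = 12, N = 40)
  geo <- manifold_geometry_mft(ms, n_samples = 400, seed = 3)
  expect_equal(geo$capacity, 2, tolerance = 0.15)
  expect_lt(geo$radius, 1e-6)
  expect_equal(geo$dimension, 1, tolerance = 0.2)
})

test_that("empirical dichotomy capacity matches the Cover limit for points", {
  ms <- point_manifold_set(P = 14, N = 30, seed = 5)
  cap <- capacity_empirical(ms, n_dichotomies = 60,
                            grid = c(3, 5, 7, 9, 11, 14), seed = 7)
  expect_equal(cap$capacity, 2, tolerance = 0.3)
  # fraction separable is monotone (non-increasing violations only by noise)
  fr <- cap$fractions$frac_separable
  expect_gt(fr[length(fr)], fr[1])
})

test_that("mean-field and empirical capacity agree on ellipsoid manifolds", {
  ms <- ellipsoid_manifold_set(P = 10, N = 120, D = 3, radius = 0.4)
  geo <- manifold_geometry_mft(ms, n_samples = 300, seed = 1)
  cap <- capacity_empirical(ms, n_dichotomies = 50,
                            grid = c(3, 4, 5, 6, 8, 10, 12), seed = 2)
  expect_lt(abs(geo$capacity - cap$capacity) / cap$capacity, 0.2)
})

test_that("dimensionality is bounded by the embedding subspace", {
  ms <- ellipsoid_manifold_set(P = 8, N = 60, D = 4, radius = 0.6, seed = 8)
  geo <- manifold_geometry_mft(ms, n_samples = 300, seed = 4)
  # anchors live in the D-dim residual subspace plus the center direction
  expect_lte(geo$dimension, 4 + 1 + 0.3)
  expect_gte(geo$dimension, 1)
})

test_that("shrinking manifolds toward their centroids raises capacity", {
  ms <- ellipsoid_manifold_set(P = 10, N = 80, D = 3, radius = 0.8, seed = 6)
  shrunk <- make_manifold_set(lapply(ms, function(pts) {
    ctr <- colMeans(pts)
    sweep(sweep(pts, 2, ctr) * 0.1, 2, ctr, "+")
  }))
  g1 <- manifold_geometry_mft(ms, n_samples = 250, seed = 9)
  g2 <- manifold_geometry_mft(shrunk, n_samples = 250, seed = 9)
  expect_gt(g2$capacity, g1$capacity)
  expect_lt(g2$radius, g1$radius)
})

test_that("geometry is invariant to rotation; radius scales linearly", {
  ms <- ellipsoid_manifold_set(P = 6, N = 30, D = 3, radius = 0.5, seed = 10)
  Q <- qr.Q(qr(matrix(rnorm(30 * 30), 30, 30)))
  rot <- make_manifold_set(lapply(ms, function(p) p %*% Q))
  g1 <- manifold_geometry_mft(ms, n_samples = 250, seed = 2)
  g2 <- manifold_geometry_mft(rot, n_samples = 250, seed = 2)
  expect_equal(g2$capacity, g1$capacity, tolerance = 1e-6)
  expect_equal(g2$radius, g1$radius, tolerance = 1e-6)
  expect_equal(g2$dimension, g1$dimension, tolerance = 1e-6)
  expect_equal(g2$center_correlation, g1$center_correlation, tolerance = 1e-6)
  # uniform scaling: capacity and dimension unchanged, radius unchanged too
  # (radius is measured relative to the center norm); center correlation fixed
  sc <- make_manifold_set(lapply(ms, function(p) 3.7 * p))
  g3 <- manifold_geometry_mft(sc, n_samples = 250, seed = 2)
  expect_equal(g3$capacity, g1$capacity, tolerance = 1e-6)
  expect_equal(g3$radius, g1$radius, tolerance = 1e-6)
})

test_that("center correlation reflects centroid alignment", {
  # orthogonal centered centroids
  P <- 4; N <- 12
  ctrs <- diag(P) %*% matrix(0, P, N)
  pts <- lapply(seq_len(P), function(i) {
    v <- rep(0, N); v[i] <- 1
    matrix(v, 3, N, byrow = TRUE)
  })
  ms <- make_manifold_set(pts)
  # after centering, 4 orthogonal unit vectors minus their mean are not
  # exactly orthogonal; use antipodal pairs on two axes instead
  pts2 <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  ms2 <- make_manifold_set(lapply(pts2, function(v)
    matrix(c(v, rep(0, 8)), 2, 10, byrow = TRUE)))
  expect_lt(center_correlation(ms2), 0.35)
  # collinear centroids
  ms3 <- make_manifold_set(lapply(c(-2, -1, 1, 2), function(s)
    matrix(s * c(1, rep(0, 9)), 2, 10, byrow = TRUE)))
  expect_equal(center_correlation(ms3), 1)
  # random isotropic centroids in high dimension are nearly orthogonal
  set.seed(11)
  ms4 <- make_manifold_set(lapply(1:10, function(i)
    matrix(rnorm(2000), 2, 2000, byrow = FALSE)))
  expect_lt(center_correlation(ms4), 0.15)
})

test_that("the separability certificate is exact on crafted cases", {
  # two linearly separable clouds (homogeneous separator exists)
  set.seed(12)
  a <- cbind(rnorm(20, 3), rnorm(20, 3))
  b <- -a
  Z <- t(rbind(a, -b) * 1)       # all signed points in the same halfspace
  expect_true(min_norm_hull_cpp(Z, 20000, 1e-16)$separable)
  # origin inside the hull: not separable
  sq <- rbind(c(1, 1), c(-1, 1), c(1, -1), c(-1, -1))
  expect_false(min_norm_hull_cpp(t(sq), 20000, 1e-16)$separable)
})
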