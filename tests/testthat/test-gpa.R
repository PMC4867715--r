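test_that("centroid size is the root summed squared deviation from the centroid", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(centroid_size(sq), sqrt(2), tolerance = 1e-12)
  sh <- rand_shape(15, seed = 1)
  expect_equal(centroid_size(sh * 3.7), 3.7 * centroid_size(sh),
               tolerance = 1e-12)
  expect_equal(centroid_size(sweep(sh, 2, c(5, -2), `+`)),
               centroid_size(sh), tolerance = 1e-12)
  expect_error(centroid_size(matrix(1, 15, 2)), "degenerate")
})

test_that("superimposition recovers similarity transforms exactly", {
  sh <- rand_shape(15, seed = 2)
  target <- sim_transform(sh, theta = pi / 6, s = 3, t = c(2, -1))
  fit <- superimpose(sh, target)
  expect_lt(fit$residual, 1e-12)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-12)

  mirrored <- sh %*% diag(c(-1, 1))
  expect_gt(superimpose(sh, mirrored)$residual, 0.01)
  expect_lt(superimpose(sh, mirrored, allow_reflection = TRUE)$residual,
            1e-12)
  expect_error(superimpose(sh, rand_shape(10)), "mismatch")
})

test_that("superimposition residual matches a 0.1-degree rotation grid search", {
  set.seed(3)
  for (i in 1:10) {
    a <- rand_shape(15)
    b <- rand_shape(15)
    expect_equal(superimpose(a, b)$residual, grid_search_residual(a, b),
                 tolerance = 1e-5)
  }
})

test_that("Procrustes distance is a symmetric shape metric", {
  set.seed(4)
  a <- rand_shape(15)
  b <- sim_transform(a, theta = 1.2, s = 0.4, t = c(3, 3))
  expect_lt(procrustes_distance(a, b), 1e-12)
  for (i in 1:10) {
    x <- rand_shape(15); y <- rand_shape(15)
    expect_equal(procrustes_distance(x, y), procrustes_distance(y, x),
                 tolerance = 1e-12)
    # cross-check against the superimposition code path
    expect_equal(procrustes_distance(x, y),
                 sqrt(superimpose(x, y)$residual), tolerance = 1e-12)
  }
})

test_that("distances agree with the closed-form complex preshape oracle", {
  set.seed(5)
  for (i in 1:50) {
    k <- sample(c(3L, 15L), 1)   # triangles and full configurations
    a <- rand_shape(k)
    b <- rand_shape(k)
    expect_equal(procrustes_distance(a, b), complex_procrustes_oracle(a, b),
                 tolerance = 1e-9)
  }
})

test_that("the distance matrix passes metric checks", {
  set.seed(6)
  shapes <- lapply(1:12, function(i) rand_shape(15))
  d <- procrustes_dist_matrix(shapes)
  expect_equal(d, t(d), tolerance = 1e-12)
  expect_equal(diag(d), rep(0, 12))
  for (i in 1:50) {
    ijk <- sample(12, 3)
    expect_lte(d[ijk[1], ijk[2]],
               d[ijk[1], ijk[3]] + d[ijk[3], ijk[2]] + 1e-9)
  }
})

test_that("GPA handles the degenerate two-copy case and the two-shape case", {
  sh <- rand_shape(15, seed = 7)
  copies <- list(a = sim_transform(sh, 0.3, 2, c(1, 1)),
                 b = sim_transform(sh, -1.1, 0.5, c(-4, 2)))
  g <- gpa(copies)
  expect_true(g$converged)
  expect_same_shape(g$consensus, sh, tol = 1e-9)
  expect_lt(sum((g$coords[, , 1] - g$coords[, , 2])^2), 1e-18)

  two <- list(x = rand_shape(15, seed = 8), y = rand_shape(15, seed = 9))
  g2 <- gpa(two)
  d1 <- procrustes_distance(g2$coords[, , 1], g2$consensus)
  d2 <- procrustes_distance(g2$coords[, , 2], g2$consensus)
  expect_equal(d1, d2, tolerance = 1e-9)

  expect_error(gpa(list(sh)), "at least 2")
})

test_that("GPA output satisfies its geometric invariants", {
  set.seed(10)
  shapes <- lapply(1:25, function(i)
    molar_template() + matrix(rnorm(30, sd = 0.05), ncol = 2))
  g <- gpa(shapes)
  expect_true(g$converged)
  # aligned centroids at the origin
  for (i in seq_along(shapes))
    expect_lt(max(abs(colMeans(g$coords[, , i]))), 1e-9)
  # consensus at unit centroid size
  expect_equal(centroid_size(g$consensus), 1, tolerance = 1e-9)
  # tangent rows orthogonal to the consensus direction
  cvec <- as.vector(t(g$consensus))
  expect_lt(max(abs(g$tangent %*% cvec)), 1e-9)
  # objective non-increasing across iterations
  expect_true(all(diff(g$objective) <= 1e-12))
})

test_that("GPA is invariant to specimen order and input similarity transforms", {
  set.seed(11)
  shapes <- lapply(1:20, function(i)
    molar_template() + matrix(rnorm(30, sd = 0.04), ncol = 2))
  names(shapes) <- sprintf("s%02d", 1:20)
  g1 <- gpa(shapes)
  perm <- sample(20)
  mangled <- lapply(shapes[perm], function(s)
    sim_transform(s, runif(1, 0, 2 * pi), runif(1, 0.2, 5), rnorm(2, 0, 10)))
  g2 <- gpa(mangled)
  expect_lt(procrustes_distance(g1$consensus, g2$consensus), 1e-6)
})

test_that("tangent projection agrees with Procrustes residuals for small noise", {
  set.seed(12)
  shapes <- lapply(1:15, function(i)
    molar_template() + matrix(rnorm(30, sd = 0.001), ncol = 2))
  g <- gpa(shapes)
  for (i in 1:15) {
    dev <- as.vector(t(g$coords[, , i] - g$consensus))
    expect_lt(max(abs(g$tangent[i, ] - dev)), 1e-5)
  }
})
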