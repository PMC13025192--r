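test_that("the configured scale set is exactly {1, 2}", {
  expect_equal(octavd:::frangi_scales(frangi_params()), c(1, 2))
})

test_that("Hessian eigenvalues vanish on constants and recover quadratic curvature", {
  ev <- hessian_eigenvalues(matrix(0.7, 40, 40), sigma = 1.5)
  expect_equal(max(abs(ev$lambda1)), 0, tolerance = 1e-12)
  expect_equal(max(abs(ev$lambda2)), 0, tolerance = 1e-12)

  n <- 41
  quad <- outer(rep(1, n), (seq_len(n) - 21)^2)   # I(r, c) = c^2
  for (sigma in c(1, 2)) {
    ev <- hessian_eigenvalues(quad, sigma)
    interior <- (ceiling(4 * sigma) + 1):(n - ceiling(4 * sigma))
    expect_equal(ev$lambda2[interior, interior],
                 matrix(2 * sigma^2, length(interior), length(interior)),
                 tolerance = 1e-9)
    expect_equal(max(abs(ev$lambda1[interior, interior])), 0, tolerance = 1e-9)
  }
})

test_that("eigenvalue magnitude fields are equivariant under 90-degree rotation", {
  set.seed(4)
  n <- 48
  img <- matrix(runif(n * n), n, n)
  rot90 <- function(m) t(m)[n:1, ]   # counterclockwise
  ev <- hessian_eigenvalues(img, 1.5)
  evr <- hessian_eigenvalues(rot90(img), 1.5)
  interior <- 10:(n - 9)
  expect_equal(rot90(abs(ev$lambda2))[interior, interior],
               abs(evr$lambda2)[interior, interior], tolerance = 1e-6)
  expect_equal(rot90(abs(ev$lambda1))[interior, interior],
               abs(evr$lambda1)[interior, interior], tolerance = 1e-6)
})

test_that("vesselness is zero on constants and concentrates on ridge centerlines", {
  v0 <- frangi_vesselness(matrix(0.3, 50, 50))
  expect_equal(max(v0$values), 0)

  img <- ridge_image(128, rows = 60:61)
  v <- frangi_vesselness(img)
  interior_cols <- 20:108
  on_ridge <- mean(v$values[60:61, interior_cols])
  off_ridge <- mean(v$values[setdiff(15:113, 55:66), interior_cols])
  expect_gt(on_ridge, 10 * max(off_ridge, 1e-12))
})

test_that("an isotropic blob scores below an equal-amplitude ridge (blobness penalty)", {
  n <- 101
  g <- exp(-(seq_len(n) - 51)^2 / (2 * 2^2))
  blob <- outer(g, g)
  ridge <- ridge_image(n, rows = 50:52)
  vb <- frangi_vesselness(blob)$values[51, 51]
  vr <- frangi_vesselness(ridge)$values[51, 51]
  expect_lt(vb, vr)
})

test_that("reducing image contrast never increases vesselness (pixelwise)", {
  set.seed(11)
  img <- matrix(runif(60 * 60), 60, 60)
  v1 <- frangi_vesselness(img)$values
  for (alpha in c(0.2, 0.5, 0.9)) {
    va <- frangi_vesselness(alpha * img)$values
    expect_true(all(va <= v1 + 1e-9))
  }
})

test_that("adding the coarse scale can only increase the response (max over scales)", {
  set.seed(12)
  img <- matrix(runif(60 * 60), 60, 60)
  v12 <- frangi_vesselness(img, frangi_params(sigma_min = 1, sigma_max = 2))$values
  v1 <- frangi_vesselness(img, frangi_params(sigma_min = 1, sigma_max = 1.5))$values
  expect_true(all(v12 >= v1 - 1e-12))
})

test_that("wider ridges select the coarser scale at the centerline", {
  argmax_scale <- function(width) {
    rows <- 60:(60 + width - 1)
    img <- ridge_image(128, rows = rows)
    v1 <- frangi_vesselness(img, frangi_params(sigma_max = 1))$values
    v2 <- frangi_vesselness(img, frangi_params(sigma_min = 2))$values
    center <- 60 + (width - 1) %/% 2
    mean(v2[center, 20:108] > v1[center, 20:108])
  }
  expect_lt(argmax_scale(2), 0.5)   # width 2: fine scale wins at most pixels
  expect_gt(argmax_scale(4), 0.5)   # width 4: coarse scale wins
})

test_that("inversion flips values, flags the map, and refuses double application", {
  v <- frangi_vesselness(ridge_image(64, rows = 30:31))
  vi <- invert_vesselness(v)
  expect_equal(vi$values, 1 - v$values)
  expect_true(vi$inverted)
  expect_error(invert_vesselness(vi), "already inverted")
  back <- invert_vesselness(v)   # fresh object: involution on values
  expect_equal(1 - back$values, v$values)
})
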