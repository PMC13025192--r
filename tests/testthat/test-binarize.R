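test_that("window statistics match a naive loop on masked random inputs", {
  set.seed(21)
  v <- matrix(runif(30 * 26), 30, 26)
  valid <- matrix(runif(30 * 26) > 0.2, 30, 26)
  got <- octavd:::window_stats(v, valid, 7)
  want <- naive_window_stats(v, valid, 7)
  expect_equal(got$n, want$n)
  expect_equal(got$mean, want$mean, tolerance = 1e-12)
  expect_equal(got$sd, want$sd, tolerance = 1e-10)
})

test_that("Phansalkar threshold matches its closed form at reference points", {
  expect_equal(phansalkar_threshold(0.5, 0), 0.5 * (1 + 2 * exp(-5) - 0.25),
               tolerance = 1e-9)
  expect_equal(phansalkar_threshold(0, 0), 0)
  expect_equal(phansalkar_threshold(0.5, 0.5),
               0.5 * (1 + 2 * exp(-5) + 0.25 * (0.5 - 1)), tolerance = 1e-9)
})

test_that("Phansalkar classification: constants yield background, checkerboards split", {
  roi <- full_roi(31)
  flat <- matrix(0, 31, 31)
  expect_false(any(threshold_phansalkar(flat, roi)$mask))

  cb <- outer(1:31, 1:31, function(r, c) (r + c) %% 2)
  mask <- threshold_phansalkar(cb, roi)$mask
  interior <- 10:22
  expect_true(all(mask[interior, interior][cb[interior, interior] == 0]))
  expect_false(any(mask[interior, interior][cb[interior, interior] == 1]))
})

test_that("adaptive mean: strict inequality against the local mean; sensitivity is monotone", {
  roi <- full_roi(31)
  expect_false(any(threshold_adaptive_mean(matrix(0.4, 31, 31), roi)$mask))

  v <- matrix(0.4, 31, 31)
  v[16, 16] <- 0.39
  m <- threshold_adaptive_mean(v, roi)$mask
  expect_true(m[16, 16])

  set.seed(22)
  img <- matrix(runif(31 * 31), 31, 31)
  n_mid <- sum(threshold_adaptive_mean(img, roi, adaptive_mean_params())$mask)
  n_strict <- sum(threshold_adaptive_mean(img, roi,
                                          adaptive_mean_params(sensitivity = 1))$mask)
  expect_lte(n_strict, n_mid)
})

test_that("global mean thresholding uses the valid-pixel mean with a strict cut", {
  roi <- full_roi(1, 3)
  v <- matrix(c(0.2, 0.4, 0.6), 1, 3)
  m <- threshold_global_mean(v, roi)$mask
  expect_identical(as.vector(m), c(TRUE, FALSE, FALSE))
  expect_false(any(threshold_global_mean(matrix(0.7, 5, 5), full_roi(5))$mask))
  half <- matrix(rep(c(0, 1), each = 18), 6, 6)
  mask <- threshold_global_mean(half, full_roi(6))$mask
  expect_identical(mask, half == 0)
})

test_that("both Otsu variants agree exactly with the exhaustive 256-cut oracle", {
  set.seed(23)
  # 60 random full windows through the sliding implementation
  for (rep in 1:60) {
    vals <- sample(0:255, 225, replace = TRUE)
    if (rep %% 3 == 0) vals <- sample(c(0L, 255L), 225, replace = TRUE)
    q <- matrix(vals, 15, 15)
    thr <- octavd:::cpp_local_otsu(q, matrix(TRUE, 15, 15), 15)
    expect_identical(thr[8, 8], oracle_otsu_cut(q))
  }
  # 20 random small images through the global variant
  for (rep in 1:20) {
    q <- sample(0:255, 400, replace = TRUE)
    expect_identical(octavd:::cpp_global_otsu(q), oracle_otsu_cut(q))
  }
})

test_that("local Otsu splits a binary window at the dark class and handles degeneracy", {
  roi <- full_roi(15)
  bin <- matrix(rep(c(0, 1), length.out = 225), 15, 15)
  mask <- threshold_local_otsu(bin, roi)$mask
  expect_identical(mask, bin == 0)
  expect_false(any(threshold_local_otsu(matrix(0.5, 15, 15), roi)$mask))
})

test_that("global Otsu separates a bimodal histogram and warns on constants", {
  v <- matrix(c(rep(10 / 255, 100), rep(200 / 255, 100)), 10, 20)
  roi <- full_roi(10, 20)
  mask <- threshold_global_otsu(v, roi)$mask
  expect_identical(mask, v < 0.5)
  expect_warning(empty <- threshold_global_otsu(matrix(0.3, 8, 8), full_roi(8)),
                 "empty mask")
  expect_false(any(empty$mask))
})

test_that("no method ever marks an invalid pixel", {
  set.seed(24)
  v <- matrix(runif(40 * 40), 40, 40)
  valid <- matrix(runif(40 * 40) > 0.4, 40, 40)
  roi <- full_roi(40, valid = valid)
  for (m in octavd:::VD_METHODS) {
    mask <- apply_threshold(v, roi, m)$mask
    expect_false(any(mask & !valid))
  }
})

test_that("symmetric criteria give identical masks under the bright-object convention", {
  set.seed(25)
  v <- matrix(runif(40 * 40), 40, 40)
  valid <- matrix(runif(40 * 40) > 0.3, 40, 40)
  roi <- full_roi(40, valid = valid)
  inv <- 1 - v

  dark <- threshold_global_mean(inv, roi)$mask
  bright <- valid & v > mean(v[valid])
  expect_identical(dark, bright)

  # global Otsu: mirrored exhaustive maximizer on the non-inverted image,
  # vessel = bright class, ties to the largest cut (mirror of smallest)
  q <- octavd:::quantize_8bit(v)
  qv <- q[valid]
  best <- -1; best_c <- 255L
  for (cc in 254:0) {
    lo <- qv[qv <= cc]; hi <- qv[qv > cc]
    if (!length(lo) || !length(hi)) next
    bc <- length(lo) * length(hi) * (mean(lo) - mean(hi))^2
    if (bc > best * (1 + 1e-12)) { best <- bc; best_c <- cc }
  }
  bright_otsu <- valid & q > best_c
  dark_otsu <- threshold_global_otsu(1 - v, roi)$mask
  expect_identical(dark_otsu, bright_otsu)
})

test_that("all five methods recover at least 90% of a noise-free ridge centerline", {
  n <- 128
  img <- enface_image(ridge_image(n, rows = 60:61), width_mm = 4.5,
                      normalize = FALSE)
  fazm <- matrix(FALSE, n, n); fazm[64, 64] <- TRUE
  faz <- faz_mask(fazm)
  roi <- build_roi(img, faz)
  quads <- build_quadrants(roi)
  vi <- invert_vesselness(rescale_vesselness(
    frangi_vesselness(img$pixels * roi$valid_mask), roi))
  centerline <- matrix(FALSE, n, n); centerline[60:61, ] <- TRUE
  target <- centerline & quads$ring
  for (m in octavd:::VD_METHODS) {
    mask <- apply_threshold(vi, roi, m)$mask
    expect_gt(sum(mask & target) / sum(target), 0.9, label = m)
  }
})
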