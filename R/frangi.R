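#' Frangi filter parameters
#'
#' Defaults are the operating point used throughout the package: scales
#' 1--2 px with a multiplicative step of 2 (hence sigma in {1, 2}),
#' blobness sensitivity `beta1 = 0.5` and structureness sensitivity
#' `beta2 = 15`, bright-vessel polarity.
#'
#' @param sigma_min Smallest Gaussian scale in px.
#' @param sigma_max Largest Gaussian scale in px.
#' @param scale_ratio Multiplicative step between successive scales (> 1).
#' @param beta1 Blobness sensitivity (suppresses blob-like responses).
#' @param beta2 Structureness sensitivity (suppresses low-contrast noise).
#' @param bright_vessels If `TRUE` respond to bright tubes on dark
#'   background (requires the large Hessian eigenvalue to be negative).
#' @param intensity_scale Factor applied to the unit-interval image before
#'   the Hessian enters the structureness term (default 255). The
#'   sensitivity constant `beta2 = 15` is calibrated for 8-bit dynamic
#'   range (its classic value in Frangi-filter implementations); on a
#'   unit-interval Hessian it would reduce the structureness term to
#'   `S^2 / 450` and collapse the map's dynamic range. The blobness ratio
#'   is scale-free and unaffected.
#' @return A list of class `frangi_params`.
#' @export
frangi_params <- function(sigma_min = 1, sigma_max = 2, scale_ratio = 2,
                          beta1 = 0.5, beta2 = 15, bright_vessels = TRUE,
                          intensity_scale = 255) {
  stopifnot(sigma_min > 0, sigma_min <= sigma_max, scale_ratio > 1,
            beta1 > 0, beta2 > 0, intensity_scale > 0)
  structure(list(sigma_min = sigma_min, sigma_max = sigma_max,
                 scale_ratio = scale_ratio, beta1 = beta1, beta2 = beta2,
                 bright_vessels = isTRUE(bright_vessels),
                 intensity_scale = intensity_scale),
            class = "frangi_params")
}

frangi_scales <- function(params) {
  s <- params$sigma_min
  out <- c()
  while (s <= params$sigma_max + 1e-12) {
    out <- c(out, s)
    s <- s * params$scale_ratio
  }
  out
}

# 1-D Gaussian and derivative kernels sampled on -R..R (R = ceil(4 sigma)),
# with discrete moment corrections so that polynomial inputs give exact
# derivatives: g sums to 1; g' has zero sum and first moment -1 (correlation
# with g' realizes -d/dx; signs cancel in the mixed Hessian term); g'' has
# zero sum and second moment 2.
gauss_kernels <- function(sigma) {
  R <- ceiling(4 * sigma)
  x <- seq(-R, R)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  g1 <- -x / sigma^2 * g
  g1 <- g1 - mean(g1)
  g1 <- g1 * (-1 / sum(x * g1))
  g2 <- (x^2 - sigma^2) / sigma^4 * g
  g2 <- g2 - mean(g2)
  g2 <- g2 * (2 / sum(x^2 * g2))
  list(g = g, g1 = g1, g2 = g2, radius = R)
}

# Dense operator matrix applying 1-D correlation with `kernel` along the
# first dimension of an n-row matrix, with whole-sample symmetric
# (reflective) boundary handling. Apply along columns via transposition.
conv_op <- function(n, kernel) {
  R <- (length(kernel) - 1L) / 2L
  K <- matrix(0, n, n)
  for (o in -R:R) {
    w <- kernel[o + R + 1L]
    src <- seq_len(n) + o
    src[src < 1L] <- 2L - src[src < 1L]
    src[src > n] <- 2L * n - src[src > n]
    K[cbind(seq_len(n), src)] <- K[cbind(seq_len(n), src)] + w
  }
  K
}

sep_filter <- function(img, krow, kcol) {
  conv_op(nrow(img), krow) %*% img %*% t(conv_op(ncol(img), kcol))
}

#' Scale-normalized Hessian eigenvalues of an image
#'
#' Computes the Gaussian-derivative Hessian at scale `sigma`, normalized by
#' `sigma^2` (gamma = 2), and returns the closed-form eigenvalues of the
#' symmetric 2x2 matrix at every pixel, ordered `|lambda1| <= |lambda2|`.
#' Boundary handling is reflective; kernels are truncated at 4 sigma.
#'
#' @param img Numeric matrix, intensities in `[0, 1]`.
#' @param sigma Scale in px (> 0).
#' @return List with matrices `lambda1` and `lambda2`.
#' @export
hessian_eigenvalues <- function(img, sigma) {
  stopifnot(sigma > 0)
  k <- gauss_kernels(sigma)
  s2 <- sigma^2
  Hrr <- s2 * sep_filter(img, k$g2, k$g)
  Hcc <- s2 * sep_filter(img, k$g, k$g2)
  Hrc <- s2 * sep_filter(img, k$g1, k$g1)
  # eigenvalues of [[Hrr, Hrc], [Hrc, Hcc]]
  mid <- (Hrr + Hcc) / 2
  disc <- sqrt(((Hrr - Hcc) / 2)^2 + Hrc^2)
  e1 <- mid - disc
  e2 <- mid + disc
  swap <- abs(e1) > abs(e2)
  lambda1 <- ifelse(swap, e2, e1)
  lambda2 <- ifelse(swap, e1, e2)
  list(lambda1 = lambda1, lambda2 = lambda2)
}

#' Multiscale Frangi vesselness
#'
#' For each scale the blobness ratio `R_B = lambda1 / lambda2` and
#' structureness `S = sqrt(lambda1^2 + lambda2^2)` combine into
#' `exp(-R_B^2 / (2 beta1^2)) * (1 - exp(-S^2 / (2 beta2^2)))`, zeroed
#' where the polarity test fails (bright vessels require `lambda2 < 0`;
#' `lambda2 == 0` also fails, which defines `R_B = 0` there and avoids
#' 0/0). The final map is the pixelwise maximum over scales.
#'
#' @param img Numeric matrix in `[0, 1]`, or an [enface_image].
#' @param params A [frangi_params].
#' @return Object of class `vesselness_map` with fields `values` (in
#'   `[0, 1]`), `params`, `inverted = FALSE`.
#' @export
frangi_vesselness <- function(img, params = frangi_params()) {
  if (inherits(img, "enface_image")) img <- img$pixels
  b1 <- 2 * params$beta1^2
  b2 <- 2 * params$beta2^2
  best <- array(0, dim(img))
  for (sigma in frangi_scales(params)) {
    ev <- hessian_eigenvalues(img * params$intensity_scale, sigma)
    l1 <- ev$lambda1; l2 <- ev$lambda2
    ok <- if (params$bright_vessels) l2 < 0 else l2 > 0
    rb2 <- ifelse(l2 == 0, 0, (l1 / ifelse(l2 == 0, 1, l2))^2)
    s2 <- l1^2 + l2^2
    v <- exp(-rb2 / b1) * (1 - exp(-s2 / b2))
    v[!ok] <- 0
    best <- pmax(best, v)
  }
  structure(list(values = best, params = params, inverted = FALSE),
            class = "vesselness_map")
}

#' Invert a vesselness map
#'
#' `values' = 1 - values`; vessels become the dark class, which is the
#' polarity the binarization stage assumes. Double inversion of the same
#' object is a contract error (build a fresh map to undo).
#'
#' @param map A `vesselness_map`.
#' @return The inverted map with `inverted = TRUE`.
#' @export
invert_vesselness <- function(map) {
  stopifnot(inherits(map, "vesselness_map"))
  if (isTRUE(map$inverted)) stop("vesselness map is already inverted")
  map$values <- 1 - map$values
  map$inverted <- TRUE
  map
}

#' Rescale a vesselness map over the analyzed region
#'
#' Min-max normalizes the raw Frangi response over the valid (analyzed)
#' pixels so that the subsequent inversion and thresholding operate on the
#' full unit dynamic range; values elsewhere are clipped to `[0, 1]`.
#' With `beta2 = 15` on unit-interval images the raw response occupies a
#' thin band near zero, so without this rescale the 8-bit quantization in
#' the Otsu variants would collapse the histogram to a single level.
#'
#' @param map A non-inverted `vesselness_map`.
#' @param roi An `roi_context`; normalization statistics come from its
#'   valid pixels only.
#' @return The rescaled map.
#' @export
rescale_vesselness <- function(map, roi) {
  stopifnot(inherits(map, "vesselness_map"), !isTRUE(map$inverted))
  v <- map$values[roi$valid_mask]
  lo <- min(v); hi <- max(v)
  if (hi == lo) {
    warning("constant vesselness over the ROI; rescale degenerates to zeros")
    map$values <- array(0, dim(map$values))
  } else {
    map$values <- pmax(pmin((map$values - lo) / (hi - lo), 1), 0)
  }
  map
}
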