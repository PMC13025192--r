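#' @useDynLib octavd, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Parameter constructors for the thresholding methods
#'
#' Defaults are the standard operating point for parafoveal OCTA
#' binarization after vesselness inversion: 15 x 15 windows, Phansalkar
#' `k = 0.25, p = 2, q = 10, R = 1`, adaptive-mean sensitivity 0.5.
#'
#' @param window Odd window side length in px (>= 3).
#' @param k,p,q,R Phansalkar constants: local-deviation weight,
#'   exponential amplitude, exponential rate, and dynamic range of the
#'   standard deviation.
#' @param levels Histogram bin count for the local Otsu variant (fixed at
#'   256 by the 8-bit quantization).
#' @param sensitivity Adaptive-mean sensitivity in `[0, 1]`; 0.5 is pure
#'   local-mean thresholding, lower values demand darker pixels.
#' @name threshold_params
NULL

#' @rdname threshold_params
#' @export
phansalkar_params <- function(window = 15, k = 0.25, p = 2, q = 10, R = 1) {
  check_window(window)
  stopifnot(R > 0)
  list(window = as.integer(window), k = k, p = p, q = q, R = R)
}

#' @rdname threshold_params
#' @export
local_otsu_params <- function(window = 15, levels = 256) {
  check_window(window)
  stopifnot(levels == 256)
  list(window = as.integer(window), levels = 256L)
}

#' @rdname threshold_params
#' @export
adaptive_mean_params <- function(window = 15, sensitivity = 0.5) {
  check_window(window)
  stopifnot(sensitivity >= 0, sensitivity <= 1)
  list(window = as.integer(window), sensitivity = sensitivity)
}

check_window <- function(window) {
  if (window < 3 || window %% 2 != 1)
    stop("window must be odd and >= 3")
  invisible(window)
}

VD_METHODS <- c("phansalkar", "local_otsu", "adaptive_mean",
                "global_mean", "global_otsu")

# strict "vessel iff intensity < T" with a guard against floating-point
# noise from the summed-area tables, so exact ties (constant regions)
# deterministically classify as background
TIE_EPS <- 1e-12
below_threshold <- function(v, thr) v < thr - TIE_EPS

new_vessel_mask <- function(mask, method, roi) {
  structure(list(mask = mask, method = method, valid = roi$valid_mask),
            class = "binary_vessel_mask")
}

map_values <- function(map) {
  if (inherits(map, "vesselness_map")) map$values else map
}

# Sliding-window sums via summed-area tables with clipped borders.
# Returns the sum over the (window x window) neighborhood intersected with
# the image for each pixel.
box_sum <- function(m, window) {
  half <- (window - 1L) / 2L
  nr <- nrow(m); nc <- ncol(m)
  cs <- rbind(0, apply(m, 2, cumsum))
  r1 <- pmin(seq_len(nr) + half, nr) + 1L
  r0 <- pmax(seq_len(nr) - half, 1L)
  rows <- cs[r1, , drop = FALSE] - cs[r0, , drop = FALSE]
  cs2 <- cbind(0, t(apply(rows, 1, cumsum)))
  c1 <- pmin(seq_len(nc) + half, nc) + 1L
  c0 <- pmax(seq_len(nc) - half, 1L)
  cs2[, c1, drop = FALSE] - cs2[, c0, drop = FALSE]
}

# Valid-pixel window statistics: list(n, mean, sd). Pixels outside the
# validity mask never enter the sums; sd is the population form, zero where
# fewer than two valid pixels fall in the window.
window_stats <- function(v, valid, window) {
  vz <- ifelse(valid, v, 0)
  n <- box_sum(valid * 1, window)
  s1 <- box_sum(vz, window)
  s2 <- box_sum(vz * vz, window)
  m <- ifelse(n > 0, s1 / pmax(n, 1), 0)
  var <- ifelse(n > 1, pmax(0, s2 / pmax(n, 1) - m^2), 0)
  list(n = n, mean = m, sd = sqrt(var))
}

# half-up 8-bit quantization (base round() is round-half-even)
quantize_8bit <- function(v) {
  q <- floor(v * 255 + 0.5)
  storage.mode(q) <- "integer"
  pmin(pmax(q, 0L), 255L)
}

#' Phansalkar threshold as a function of local statistics
#'
#' `T = m * (1 + p * exp(-q * m) + k * (s / R - 1))`, vectorized over `m`
#' and `s`.
#'
#' @param m Local mean(s) in `[0, 1]`.
#' @param s Local (population) standard deviation(s).
#' @param params See [threshold_params].
#' @export
phansalkar_threshold <- function(m, s, params = phansalkar_params()) {
  m * (1 + params$p * exp(-params$q * m) + params$k * (s / params$R - 1))
}

#' Phansalkar local adaptive thresholding
#'
#' Per valid pixel, with `m` and `s` the mean and (population) standard
#' deviation of valid pixels in the centered window, the threshold is
#' `T = m * (1 + p * exp(-q * m) + k * (s / R - 1))`. Vessels are the dark
#' class of the inverted vesselness map: vessel iff intensity strictly
#' below `T`. Windows with fewer than two valid pixels yield background.
#'
#' @param map A `vesselness_map` (inverted, per the pipeline convention)
#'   or a plain matrix in `[0, 1]`.
#' @param roi An `roi_context`.
#' @param params Method parameters, see [threshold_params].
#' @return A `binary_vessel_mask`.
#' @export
threshold_phansalkar <- function(map, roi, params = phansalkar_params()) {
  v <- map_values(map)
  st <- window_stats(v, roi$valid_mask, params$window)
  thr <- phansalkar_threshold(st$mean, st$sd, params)
  mask <- roi$valid_mask & st$n >= 2 & below_threshold(v, thr)
  new_vessel_mask(mask, "phansalkar", roi)
}

#' Sliding-window Otsu thresholding
#'
#' The map is quantized to 8 bits (`floor(v * 255 + 0.5)`); per valid
#' pixel, Otsu's between-class variance criterion over the 256-bin
#' histogram of valid window pixels yields a local cut `t`, and vessel iff
#' quantized intensity `< t`. Degenerate windows (a single distinct level,
#' or fewer than two valid pixels) yield background. Ties in the criterion
#' resolve to the smallest cut.
#'
#' @inheritParams threshold_phansalkar
#' @export
threshold_local_otsu <- function(map, roi, params = local_otsu_params()) {
  q <- quantize_8bit(map_values(map))
  thr <- cpp_local_otsu(q, roi$valid_mask, params$window)
  mask <- roi$valid_mask & q < thr
  new_vessel_mask(mask, "local_otsu", roi)
}

#' Adaptive mean thresholding
#'
#' Per valid pixel `T = m_w + (0.5 - sensitivity)` with `m_w` the valid
#' window mean; vessel iff intensity strictly below `T`. At sensitivity
#' 0.5 this is pure local-mean thresholding; the additive offset keeps the
#' sensitivity knob monotone.
#'
#' @inheritParams threshold_phansalkar
#' @export
threshold_adaptive_mean <- function(map, roi, params = adaptive_mean_params()) {
  v <- map_values(map)
  st <- window_stats(v, roi$valid_mask, params$window)
  thr <- st$mean + (0.5 - params$sensitivity)
  mask <- roi$valid_mask & st$n >= 2 & below_threshold(v, thr)
  new_vessel_mask(mask, "adaptive_mean", roi)
}

#' Global mean thresholding
#'
#' `T` is the mean intensity of all valid pixels; vessel iff intensity
#' strictly below `T` (dark-vessel convention after inversion).
#'
#' @inheritParams threshold_phansalkar
#' @export
threshold_global_mean <- function(map, roi) {
  v <- map_values(map)
  thr <- mean(v[roi$valid_mask])
  mask <- roi$valid_mask & below_threshold(v, thr)
  new_vessel_mask(mask, "global_mean", roi)
}

#' Global Otsu thresholding
#'
#' Valid pixels are quantized to 8 bits and a single Otsu cut is taken
#' over their histogram; vessel iff quantized intensity `< t`. A constant
#' valid region yields an empty mask with a warning.
#'
#' @inheritParams threshold_phansalkar
#' @export
threshold_global_otsu <- function(map, roi) {
  q <- quantize_8bit(map_values(map))
  qv <- q[roi$valid_mask]
  if (length(unique(qv)) < 2) {
    warning("all valid pixels identical: global Otsu yields an empty mask")
    return(new_vessel_mask(array(FALSE, dim(q)), "global_otsu", roi))
  }
  thr <- cpp_global_otsu(qv)
  mask <- roi$valid_mask & q < thr
  new_vessel_mask(mask, "global_otsu", roi)
}

#' Apply a named thresholding method
#'
#' @param method One of `"phansalkar"`, `"local_otsu"`, `"adaptive_mean"`,
#'   `"global_mean"`, `"global_otsu"`.
#' @param threshold_params Named list of per-method parameter objects
#'   (entries `phansalkar`, `local_otsu`, `adaptive_mean`), defaults used
#'   where missing.
#' @inheritParams threshold_phansalkar
#' @export
apply_threshold <- function(map, roi, method, threshold_params = list()) {
  method <- match.arg(method, VD_METHODS)
  switch(method,
    phansalkar = threshold_phansalkar(
      map, roi, threshold_params$phansalkar %||% phansalkar_params()),
    local_otsu = threshold_local_otsu(
      map, roi, threshold_params$local_otsu %||% local_otsu_params()),
    adaptive_mean = threshold_adaptive_mean(
      map, roi, threshold_params$adaptive_mean %||% adaptive_mean_params()),
    global_mean = threshold_global_mean(map, roi),
    global_otsu = threshold_global_otsu(map, roi))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
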