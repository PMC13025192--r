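# Fixtures are built in code; nothing binary ships with the package.

# an roi_context whose validity mask is everything (for unit tests of the
# thresholding operators, which only consult valid_mask)
full_roi <- function(nr, nc = nr, valid = matrix(TRUE, nr, nc)) {
  structure(list(center_rc = c((nr + 1) / 2, (nc + 1) / 2),
                 roi_radius_px = sqrt(nr^2 + nc^2),
                 valid_mask = valid, px_per_mm = nr / 4.5),
            class = "roi_context")
}

# horizontal bright ridge of the given width on a zero background
ridge_image <- function(n = 128, rows = 60:61, value = 1) {
  m <- matrix(0, n, n)
  m[rows, ] <- value
  m
}

# independent brute-force Otsu: exhaustive search of all 256 cuts,
# maximizing w0 * w1 * (mu0 - mu1)^2; smallest cut among ties
oracle_otsu_cut <- function(q) {
  q <- as.integer(q)
  if (length(unique(q)) < 2) return(0L)
  best <- -1; best_t <- 0L
  for (t in 1:255) {
    lo <- q[q < t]; hi <- q[q >= t]
    if (!length(lo) || !length(hi)) next
    bc <- length(lo) * length(hi) * (mean(lo) - mean(hi))^2
    if (bc > best * (1 + 1e-12)) { best <- bc; best_t <- t }
  }
  best_t
}

# naive sliding-window statistics over valid pixels (loops; oracle for
# the summed-area-table implementation)
naive_window_stats <- function(v, valid, window) {
  half <- (window - 1) / 2
  nr <- nrow(v); nc <- ncol(v)
  m <- s <- n <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ri <- max(1, i - half):min(nr, i + half)
    ci <- max(1, j - half):min(nc, j + half)
    vals <- v[ri, ci][valid[ri, ci]]
    n[i, j] <- length(vals)
    if (length(vals)) {
      m[i, j] <- mean(vals)
      if (length(vals) > 1) s[i, j] <- sqrt(mean((vals - mean(vals))^2))
    }
  }
  list(n = n, mean = m, sd = s)
}

# small phantom spec used throughout the tests to keep runtimes down
test_spec <- function(...) phantom_spec(size_px = 96, ...)
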