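#' Build the fovea-centered circular region of interest
#'
#' Centers a circular analysis region (default 3 mm diameter) on the FAZ
#' centroid and excludes the FAZ itself, yielding the validity mask used by
#' every downstream stage. "Cropping" is implemented as masking: operators
#' run on the full grid and ignore invalid pixels, which avoids coordinate
#' remapping. Pixel membership is decided at pixel centers with a `<=`
#' comparison, so boundary ties are included.
#'
#' @param image An [enface_image].
#' @param faz A [faz_mask] congruent with `image`.
#' @param roi_diameter_mm Diameter of the region of interest in mm
#'   (default 3).
#' @return An object of class `roi_context` with fields `center_rc`,
#'   `roi_radius_px`, `valid_mask`, `px_per_mm`.
#' @export
build_roi <- function(image, faz, roi_diameter_mm = 3.0) {
  if (!identical(dim(faz$mask), dim(image$pixels)))
    stop("FAZ mask shape does not match image")
  if (roi_diameter_mm > image$width_mm)
    stop(sprintf("ROI diameter %.3g mm exceeds field width %.3g mm",
                 roi_diameter_mm, image$width_mm))
  nr <- nrow(image$pixels); nc <- ncol(image$pixels)
  px_per_mm <- nc / image$width_mm
  r_px <- roi_diameter_mm / 2 * px_per_mm
  ctr <- faz$centroid_rc
  over <- max(r_px - (ctr[1] - 1), r_px - (nr - ctr[1]),
              r_px - (ctr[2] - 1), r_px - (nc - ctr[2]))
  if (over > 0)
    stop(sprintf("ROI circle extends %.2f px beyond the image bounds", over))
  d2 <- pixel_dist2(nr, nc, ctr)
  valid <- d2 <= r_px^2 & !faz$mask
  structure(list(center_rc = ctr, roi_radius_px = r_px,
                 valid_mask = valid, px_per_mm = px_per_mm),
            class = "roi_context")
}

# squared Euclidean distance of every pixel center from ctr (row, col)
pixel_dist2 <- function(nr, nc, ctr) {
  dr <- (seq_len(nr) - ctr[1])^2
  dc <- (seq_len(nc) - ctr[2])^2
  outer(dr, dc, `+`)
}

#' Convert an image to unit-interval grayscale
#'
#' Idempotent: an image already in `[0, 1]` is returned unchanged (no
#' re-stretching, so masked-out regions cannot influence the analysis of
#' an already-normalized image); out-of-range images are min-max
#' normalized, and constant images degenerate to all zeros with a
#' warning.
#'
#' @param image An [enface_image].
#' @return An [enface_image] with intensities in `[0, 1]`.
#' @export
to_grayscale_unit <- function(image) {
  p <- image$pixels
  if (min(p) < max(p) && min(p) >= 0 && max(p) <= 1)
    return(image)
  image$pixels <- normalize_unit(p)
  image
}
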