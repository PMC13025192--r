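#' Per-quadrant vessel density
#'
#' Vessel density is the percentage of analyzed pixels classified as
#' vessel: `VD = 100 * vessel pixels / quadrant pixel count`. The ring
#' value is the unweighted mean of the four quadrant values (not the
#' pooled pixel ratio; the two differ when FAZ masking leaves unequal
#' quadrant areas).
#'
#' @param mask A `binary_vessel_mask`.
#' @param quadrants A `quadrant_masks` built from the same `roi_context`.
#' @param subject_id,group_label Identifiers carried into the record.
#' @return One-row `data.frame` with columns `subject_id`, `group`,
#'   `method`, `vd_superior`, `vd_inferior`, `vd_nasal`, `vd_temporal`,
#'   `vd_ring` (percentages).
#' @export
quadrant_density <- function(mask, quadrants, subject_id = NA_character_,
                             group_label = NA_character_) {
  vd <- vapply(QUADRANTS, function(qn) {
    qmask <- quadrants[[qn]]
    n <- sum(qmask)
    if (n == 0) stop(sprintf("empty %s quadrant", qn))
    100 * sum(mask$mask & qmask) / n
  }, numeric(1))
  data.frame(subject_id = subject_id, group = group_label,
             method = mask$method,
             vd_superior = vd[["superior"]], vd_inferior = vd[["inferior"]],
             vd_nasal = vd[["nasal"]], vd_temporal = vd[["temporal"]],
             vd_ring = mean(vd), stringsAsFactors = FALSE)
}

#' Run the full per-subject pipeline
#'
#' Grayscale normalization, ROI/FAZ masking, multiscale Frangi
#' enhancement, ROI-wise rescaling, inversion, binarization with each
#' requested method, quadrant geometry, and densities. Deterministic
#' end to end.
#'
#' @param image An [enface_image].
#' @param faz A [faz_mask].
#' @param methods Character vector of thresholding methods (default all
#'   five).
#' @param config A [run_config] carrying grid/Frangi/threshold parameters.
#' @return `data.frame` with one row per method (see [quadrant_density]).
#' @export
run_subject <- function(image, faz, methods = VD_METHODS,
                        config = run_config()) {
  methods <- vapply(methods, function(m) match.arg(m, VD_METHODS), "")
  image <- to_grayscale_unit(image)
  roi <- build_roi(image, faz, config$roi_diameter_mm)
  quads <- build_quadrants(roi, config$grid, image$laterality,
                           config$od_nasal_side)
  # cropping-as-masking: FAZ and out-of-ROI intensities are excluded from
  # all analysis, so they must not leak into the Frangi convolution either
  vmap <- frangi_vesselness(image$pixels * roi$valid_mask, config$frangi)
  vmap <- rescale_vesselness(vmap, roi)
  vmap <- invert_vesselness(vmap)
  out <- lapply(methods, function(m) {
    quadrant_density(apply_threshold(vmap, roi, m, config$threshold_params),
                     quads, subject_id = image$subject_id,
                     group_label = image$group_label)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Reshape a density table to long format
#'
#' @param records Wide density `data.frame` from [run_subject] /
#'   [process_cohort].
#' @param include_ring Include the `ring` rows (default `FALSE`).
#' @return Long `data.frame` with columns `subject_id`, `group`, `method`,
#'   `quadrant`, `vd_percent`, ordered by subject, method, quadrant.
#' @export
density_long <- function(records, include_ring = FALSE) {
  quads <- c(QUADRANTS, if (include_ring) "ring")
  out <- do.call(rbind, lapply(quads, function(qn) {
    col <- paste0("vd_", qn)
    data.frame(subject_id = records$subject_id, group = records$group,
               method = records$method, quadrant = qn,
               vd_percent = records[[col]], stringsAsFactors = FALSE)
  }))
  out[order(out$subject_id, out$method, match(out$quadrant, quads)), ,
      drop = FALSE]
}
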