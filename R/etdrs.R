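#' ETDRS inner-grid specification
#'
#' The parafoveal ring of the ETDRS grid: a central circle of 1 mm
#' diameter surrounded by a ring extending to 3 mm diameter, split into
#' four quadrants at 45/135/225/315 degrees. `convention = "diameter"`
#' (default) reads the two sizes as diameters, so the ring spans radii
#' 0.5--1.5 mm; `"radius"` reads them literally as radii (ring 1--3 mm),
#' which requires a correspondingly larger region of interest.
#'
#' @param inner_mm Central-circle size in mm (default 1).
#' @param outer_mm Ring outer size in mm (default 3).
#' @param convention `"diameter"` or `"radius"`.
#' @return A list of class `grid_spec`.
#' @export
grid_spec <- function(inner_mm = 1.0, outer_mm = 3.0,
                      convention = c("diameter", "radius")) {
  convention <- match.arg(convention)
  stopifnot(inner_mm > 0, inner_mm < outer_mm)
  structure(list(inner_mm = inner_mm, outer_mm = outer_mm,
                 convention = convention),
            class = "grid_spec")
}

grid_radii_mm <- function(spec) {
  if (spec$convention == "diameter")
    c(inner = spec$inner_mm / 2, outer = spec$outer_mm / 2)
  else
    c(inner = spec$inner_mm, outer = spec$outer_mm)
}

#' Build laterality-aware parafoveal quadrant masks
#'
#' The annulus is the set of valid pixels whose center distance `d` from
#' the ROI center satisfies `inner_radius < d <= outer_radius`. Each
#' annulus pixel is assigned by its angle from the image "up" direction
#' (screen convention), half-open sectors: superior `[-45, 45)`, one
#' horizontal sector `[45, 135)`, inferior `[135, 225)`, the other
#' horizontal sector `[225, 315)`; a pixel exactly on a boundary belongs
#' to the sector counterclockwise of it. The horizontal sectors map to
#' nasal/temporal by laterality under the standard en face export
#' orientation (superior at top): for OD the nasal retina is on the image
#' left, for OS on the image right.
#'
#' @param roi An `roi_context`.
#' @param spec A [grid_spec].
#' @param laterality `"OD"` or `"OS"`.
#' @param od_nasal_side Which image side is nasal for a right eye
#'   (`"left"` default; config-exposed because export orientation is a
#'   device convention).
#' @return Object of class `quadrant_masks` with logical matrices
#'   `superior`, `inferior`, `nasal`, `temporal` and their union `ring`.
#' @export
build_quadrants <- function(roi, spec = grid_spec(), laterality = c("OD", "OS"),
                            od_nasal_side = c("left", "right")) {
  laterality <- match.arg(laterality)
  od_nasal_side <- match.arg(od_nasal_side)
  radii <- grid_radii_mm(spec) * roi$px_per_mm
  if (radii["outer"] > roi$roi_radius_px + 1e-9)
    stop(sprintf("grid outer radius %.1f px exceeds ROI radius %.1f px",
                 radii["outer"], roi$roi_radius_px))
  nr <- nrow(roi$valid_mask); nc <- ncol(roi$valid_mask)
  d2 <- pixel_dist2(nr, nc, roi$center_rc)
  ring <- roi$valid_mask & d2 > radii["inner"]^2 & d2 <= radii["outer"]^2
  if (!any(ring)) stop("parafoveal annulus is empty after masking")
  # angle from "up": dy = row - r0 grows downward, dx = col - c0 rightward
  dy <- outer(seq_len(nr) - roi$center_rc[1], rep(1, nc))
  dx <- outer(rep(1, nr), seq_len(nc) - roi$center_rc[2])
  theta <- atan2(dx, -dy) * 180 / pi          # 0 = up, 90 = image right
  theta <- (theta + 45) %% 360 - 45           # map into [-45, 315)
  superior <- ring & theta >= -45 & theta < 45
  right <- ring & theta >= 45 & theta < 135
  inferior <- ring & theta >= 135 & theta < 225
  left <- ring & theta >= 225 & theta < 315
  nasal_left <- (laterality == "OD") == (od_nasal_side == "left")
  structure(list(superior = superior, inferior = inferior,
                 nasal = if (nasal_left) left else right,
                 temporal = if (nasal_left) right else left,
                 ring = ring),
            class = "quadrant_masks")
}

QUADRANTS <- c("superior", "inferior", "nasal", "temporal")
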