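#' En face OCTA image with physical metadata
#'
#' Container for a grayscale en face angiogram together with the physical
#' field of view, eye laterality and cohort identifiers. Intensities are
#' min-max normalized to `[0, 1]` at construction.
#'
#' @param pixels Numeric matrix of intensities (any non-negative range; will
#'   be normalized).
#' @param width_mm Physical width of the field of view in mm (default 4.5,
#'   the common high-resolution macular scan).
#' @param height_mm Physical height in mm; defaults to `width_mm` (square
#'   field).
#' @param laterality `"OD"` (right eye) or `"OS"` (left eye).
#' @param subject_id Opaque subject identifier.
#' @param group_label One of `"control"`, `"noDR"`, `"NPDR"`, `"PDR"`, or
#'   `NA` when no cohort is attached.
#' @param normalize If `TRUE` (default) apply per-image min-max
#'   normalization. Normalization is idempotent.
#' @return An object of class `enface_image`.
#' @export
enface_image <- function(pixels, width_mm = 4.5, height_mm = width_mm,
                         laterality = "OD", subject_id = NA_character_,
                         group_label = NA_character_, normalize = TRUE) {
  if (!is.matrix(pixels) || nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("pixels must be a non-empty matrix")
  if (!is.numeric(width_mm) || width_mm <= 0 || height_mm <= 0)
    stop("physical dimensions must be positive")
  laterality <- match.arg(laterality, c("OD", "OS"))
  if (!is.na(group_label))
    group_label <- match_group_label(group_label)
  pixels <- pixels * 1.0
  if (normalize) pixels <- normalize_unit(pixels)
  structure(
    list(pixels = pixels, width_mm = width_mm, height_mm = height_mm,
         laterality = laterality, subject_id = subject_id,
         group_label = group_label),
    class = "enface_image")
}

#' @export
print.enface_image <- function(x, ...) {
  cat(sprintf("<enface_image> %d x %d px, %.3g x %.3g mm, %s%s\n",
              nrow(x$pixels), ncol(x$pixels), x$width_mm, x$height_mm,
              x$laterality,
              if (is.na(x$subject_id)) "" else paste0(", ", x$subject_id)))
  invisible(x)
}

# The four-level diagnostic factor used throughout the package.
GROUP_LEVELS <- c("control", "noDR", "NPDR", "PDR")

match_group_label <- function(label) {
  hit <- match(tolower(trimws(label)), tolower(GROUP_LEVELS))
  if (is.na(hit))
    stop(sprintf("unknown group label '%s' (expected one of %s)",
                 label, paste(GROUP_LEVELS, collapse = ", ")))
  GROUP_LEVELS[hit]
}

#' Min-max normalize a matrix to the unit interval
#'
#' A zero-variance input degenerates to all zeros, with a warning.
#' Applying the map twice equals applying it once.
#'
#' @param m Numeric matrix.
#' @return Matrix with values in `[0, 1]`.
#' @export
normalize_unit <- function(m) {
  lo <- min(m); hi <- max(m)
  if (hi == lo) {
    warning("zero-variance image: normalization degenerates to all zeros")
    return(array(0, dim(m)))
  }
  (m - lo) / (hi - lo)
}

read_raster <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read image '%s': no such file", path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported image format '%s' for '%s' (PNG or TIFF expected)",
                 ext, path)))
  if (length(dim(img)) == 3L) {
    # device exports are pseudo-grayscale; equal-weight channel mean avoids
    # committing to a luminance standard
    nchan <- min(dim(img)[3], 3L)
    img <- apply(img[, , seq_len(nchan), drop = FALSE], c(1, 2), mean)
  }
  img
}

#' Load an en face angiogram from PNG or TIFF
#'
#' RGB rasters collapse to the equal-weight channel mean; intensities are
#' min-max normalized to `[0, 1]`. The physical scale is supplied by the
#' caller (it is metadata, never inferred from file headers).
#'
#' @inheritParams enface_image
#' @param image_path Path to a PNG or TIFF file.
#' @return An [enface_image].
#' @export
load_enface <- function(image_path, width_mm = 4.5, laterality = "OD",
                        height_mm = width_mm, subject_id = NA_character_,
                        group_label = NA_character_) {
  enface_image(read_raster(image_path), width_mm = width_mm,
               height_mm = height_mm, laterality = laterality,
               subject_id = subject_id, group_label = group_label)
}

#' Write a normalized en face image as 16-bit TIFF
#'
#' @param image An [enface_image].
#' @param path Output path (`.tif`/`.tiff`).
#' @export
write_enface <- function(image, path) {
  tiff::writeTIFF(image$pixels, path, bits.per.sample = 16L)
  invisible(path)
}

#' Foveal avascular zone mask
#'
#' @param mask Logical matrix, `TRUE` inside the FAZ; must contain at least
#'   one `TRUE` pixel.
#' @return Object of class `faz_mask` with fields `mask` and `centroid_rc`
#'   (arithmetic mean of the TRUE-pixel row/column indices).
#' @export
faz_mask <- function(mask) {
  if (!is.matrix(mask)) stop("FAZ mask must be a matrix")
  mask <- mask != 0
  if (!any(mask)) stop("FAZ mask is empty: the FAZ must contain at least one pixel")
  idx <- which(mask, arr.ind = TRUE)
  structure(list(mask = mask,
                 centroid_rc = c(mean(idx[, 1]), mean(idx[, 2]))),
            class = "faz_mask")
}

#' Load a FAZ mask congruent with its parent image
#'
#' Any nonzero pixel counts as inside the FAZ.
#'
#' @param mask_path Path to a PNG or TIFF binary mask.
#' @param parent The parent [enface_image]; shapes must match.
#' @return A [faz_mask].
#' @export
load_faz_mask <- function(mask_path, parent) {
  raw <- read_raster(mask_path)
  if (!identical(dim(raw), dim(parent$pixels)))
    stop(sprintf("FAZ mask %dx%d does not match image %dx%d",
                 nrow(raw), ncol(raw), nrow(parent$pixels), ncol(parent$pixels)))
  faz_mask(raw > 0)
}

#' Load and validate a cohort table
#'
#' Reads a CSV with header `subject_id,group,laterality,image_path,faz_path`.
#' Group labels are matched case-insensitively after trimming; subject ids
#' must be unique; referenced files must exist (relative paths resolve
#' against the CSV's directory).
#'
#' @param table_path Path to the cohort CSV.
#' @param check_paths If `TRUE` (default) every referenced image/mask file
#'   must be resolvable at load time.
#' @return A `data.frame` with columns `subject_id`, `group` (factor with
#'   levels control, noDR, NPDR, PDR), `laterality`, `image_path`,
#'   `faz_path`.
#' @export
load_cohort <- function(table_path, check_paths = TRUE) {
  if (!file.exists(table_path)) stop(sprintf("cohort table '%s' not found", table_path))
  tab <- utils::read.csv(table_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "laterality", "image_path", "faz_path")
  if (!all(need %in% names(tab)))
    stop(sprintf("cohort table must have columns %s", paste(need, collapse = ", ")))
  tab <- tab[need]
  tab$subject_id <- trimws(as.character(tab$subject_id))
  if (anyDuplicated(tab$subject_id))
    stop(sprintf("duplicate subject_id: %s",
                 paste(unique(tab$subject_id[duplicated(tab$subject_id)]), collapse = ", ")))
  grp <- character(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    grp[i] <- tryCatch(match_group_label(tab$group[i]),
                       error = function(e) stop(sprintf("row %d: %s", i, conditionMessage(e)),
                                                call. = FALSE))
  }
  tab$group <- factor(grp, levels = GROUP_LEVELS)
  tab$laterality <- toupper(trimws(tab$laterality))
  if (!all(tab$laterality %in% c("OD", "OS")))
    stop("laterality must be OD or OS")
  base <- dirname(normalizePath(table_path))
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  tab$image_path <- resolve(tab$image_path)
  tab$faz_path <- resolve(tab$faz_path)
  if (check_paths) {
    missing <- c(tab$image_path[!file.exists(tab$image_path)],
                 tab$faz_path[!file.exists(tab$faz_path)])
    if (length(missing))
      stop(sprintf("cohort references missing files: %s",
                   paste(missing, collapse = ", ")))
  }
  tab
}
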