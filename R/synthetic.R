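#' Specification for a synthetic OCTA phantom
#'
#' Describes an OCTA-like en face angiogram: bright arteriolar trees (2-4
#' px wide random branching walks) plus a capillary mesh of short 1-2 px
#' segments on a dark background, a circular foveal avascular zone, and
#' multiplicative Gaussian speckle. `dropout_fraction` deletes a uniformly
#' chosen fraction of capillary segments while preserving the arterioles,
#' mimicking diabetic capillary nonperfusion.
#'
#' @param size_px Image side length in px (>= 64; default 320).
#' @param width_mm Physical field width in mm (default 4.5).
#' @param n_arterioles Number of large seed vessels (default 6).
#' @param branch_prob Branching probability per walk step (default 0.08).
#' @param capillary_density Target vessel fraction outside the FAZ
#'   (default 0.30, a realistic parafoveal plexus coverage).
#' @param faz_radius_mm FAZ radius in mm (default 0.3).
#' @param dropout_fraction Fraction of capillary segments deleted, in
#'   `[0, 1]` (default 0).
#' @param speckle_sigma Scale of the zero-mean multiplicative Gaussian
#'   speckle (default 0.15).
#' @param background_level Decorrelation noise floor of the avascular
#'   background, as a fraction of the vessel signal (default 0.10). OCTA
#'   background is never perfectly black; a nonzero floor lets the
#'   multiplicative speckle corrupt the background as well as the
#'   vessels, which is what makes non-adaptive global thresholds
#'   overestimate density on real angiograms.
#' @param subject_sd Between-subject standard deviation of
#'   `capillary_density` used by [make_cohort] (default 0.04); zero gives
#'   identical target densities for every subject.
#' @param seed RNG seed making the phantom fully deterministic.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(size_px = 320, width_mm = 4.5, n_arterioles = 6,
                         branch_prob = 0.08, capillary_density = 0.30,
                         faz_radius_mm = 0.3, dropout_fraction = 0,
                         speckle_sigma = 0.15, background_level = 0.10,
                         subject_sd = 0.04, seed = 1L) {
  stopifnot(size_px >= 64, width_mm > 0,
            n_arterioles >= 0, branch_prob >= 0, branch_prob <= 1,
            capillary_density >= 0, capillary_density <= 1,
            faz_radius_mm >= 0, faz_radius_mm < width_mm / 2,
            dropout_fraction >= 0, dropout_fraction <= 1,
            speckle_sigma >= 0, background_level >= 0, background_level < 1,
            subject_sd >= 0)
  structure(list(size_px = as.integer(size_px), width_mm = width_mm,
                 n_arterioles = as.integer(n_arterioles),
                 branch_prob = branch_prob,
                 capillary_density = capillary_density,
                 faz_radius_mm = faz_radius_mm,
                 dropout_fraction = dropout_fraction,
                 speckle_sigma = speckle_sigma,
                 background_level = background_level,
                 subject_sd = subject_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

# pixel offsets of a disc of radius rad around the origin
disc_offsets <- function(rad) {
  r <- ceiling(rad)
  o <- expand.grid(dr = -r:r, dc = -r:r)
  o[o$dr^2 + o$dc^2 <= rad^2, , drop = FALSE]
}

# linear pixel indices of a thick line segment, clipped to the image
thick_line_px <- function(r0, c0, r1, c1, width, n) {
  len <- sqrt((r1 - r0)^2 + (c1 - c0)^2)
  t <- seq(0, 1, length.out = max(2L, ceiling(len / 0.4) + 1L))
  pr <- round(r0 + t * (r1 - r0))
  pc <- round(c0 + t * (c1 - c0))
  off <- disc_offsets(width / 2)
  pr <- rep(pr, each = nrow(off)) + off$dr
  pc <- rep(pc, each = nrow(off)) + off$dc
  keep <- pr >= 1 & pr <= n & pc >= 1 & pc <= n
  unique((pc[keep] - 1L) * n + pr[keep])
}

# a random branching walk from the image border toward the center,
# stopping at the FAZ boundary; returns linear pixel indices
arteriole_walk <- function(center, faz_r_px, width, branch_prob, n, depth = 0L) {
  side <- sample.int(4L, 1L)
  pos <- switch(side,
                c(1, runif(1, 1, n)), c(n, runif(1, 1, n)),
                c(runif(1, 1, n), 1), c(runif(1, 1, n), n))
  dirv <- center - pos
  dirv <- dirv / sqrt(sum(dirv^2))
  walk_from(pos, dirv, center, faz_r_px, width, branch_prob, n, depth)
}

walk_from <- function(pos, dirv, center, faz_r_px, width, branch_prob, n, depth) {
  px <- integer(0)
  step_len <- 3
  for (i in seq_len(300L)) {
    to_c <- center - pos
    d_c <- sqrt(sum(to_c^2))
    if (d_c <= faz_r_px + width) break
    dirv <- 0.75 * dirv + 0.35 * to_c / d_c + stats::rnorm(2, 0, 0.3)
    dirv <- dirv / sqrt(sum(dirv^2))
    nxt <- pos + dirv * step_len
    if (any(nxt < 1) || any(nxt > n)) break
    px <- c(px, thick_line_px(pos[1], pos[2], nxt[1], nxt[2], width, n))
    if (depth < 2L && stats::runif(1) < branch_prob) {
      ang <- sample(c(-1, 1), 1) * stats::runif(1, 0.5, 1.1)
      rot <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
      px <- c(px, walk_from(pos, as.numeric(rot %*% dirv), center, faz_r_px,
                            max(2, width - 1), branch_prob, n, depth + 1L))
    }
    pos <- nxt
  }
  unique(px)
}

#' Generate a synthetic OCTA phantom
#'
#' Draws the arteriolar trees, fills the capillary mesh with short random
#' segments until the target vessel fraction outside the FAZ is reached,
#' applies segment dropout, and renders
#' `clip(blur(vessel indicator) * (1 + speckle), 0, 1)` with a small
#' Gaussian blur (sigma 0.7 px) and i.i.d. zero-mean Gaussian speckle.
#' Deterministic given `spec$seed`; the caller's RNG state is preserved.
#'
#' @param spec A [phantom_spec].
#' @param subject_id,group_label,laterality Metadata attached to the
#'   rendered [enface_image].
#' @return Object of class `phantom`: list with `image` ([enface_image]),
#'   `truth_mask` (logical matrix, no `TRUE` pixel inside the FAZ), and
#'   `faz` ([faz_mask], an exact circle).
#' @export
make_phantom <- function(spec, subject_id = NA_character_,
                         group_label = NA_character_, laterality = "OD") {
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(spec$seed)

  n <- spec$size_px
  px_per_mm <- n / spec$width_mm
  center <- c((n + 1) / 2, (n + 1) / 2)
  faz_r_px <- spec$faz_radius_mm * px_per_mm
  faz <- pixel_dist2(n, n, center) <= faz_r_px^2
  outside <- !faz
  n_out <- sum(outside)

  art <- logical(n * n)
  if (spec$n_arterioles > 0) {
    for (a in seq_len(spec$n_arterioles)) {
      w <- sample(2:4, 1L)
      art[arteriole_walk(center, faz_r_px, w, spec$branch_prob, n)] <- TRUE
    }
  }
  art[faz] <- FALSE

  # capillary mesh: short random segments until the combined vessel
  # fraction outside the FAZ reaches the target
  segments <- list()
  covered <- art
  count <- sum(covered)
  target <- spec$capillary_density * n_out
  max_attempts <- 500L + ceiling(80 * spec$capillary_density * n_out / 8)
  attempts <- 0L
  stalled <- 0L
  while (count < target) {
    attempts <- attempts + 1L
    if (attempts > max_attempts || stalled > 1500L)
      stop(sprintf("capillary density target %.3f unreachable; achieved %.3f",
                   spec$capillary_density, count / n_out))
    repeat {
      r0 <- stats::runif(1, 1, n); c0 <- stats::runif(1, 1, n)
      if (outside[round(r0) + (round(c0) - 1) * n]) break
    }
    ang <- stats::runif(1, 0, 2 * pi)
    len <- stats::runif(1, 5, 12)
    w <- sample(1:2, 1L)
    px <- thick_line_px(r0, c0, r0 + len * sin(ang), c0 + len * cos(ang), w, n)
    px <- px[outside[px]]
    # keep the mesh space-filling: a segment mostly on top of existing
    # vessels is rejected, so deleting a segment later removes its pixels
    if (!length(px) || mean(covered[px]) > 0.5) {
      stalled <- stalled + 1L
      next
    }
    stalled <- 0L
    segments[[length(segments) + 1L]] <- px
    fresh <- px[!covered[px]]
    covered[fresh] <- TRUE
    count <- count + length(fresh)
  }

  if (spec$dropout_fraction > 0 && length(segments)) {
    n_del <- round(spec$dropout_fraction * length(segments))
    if (n_del > 0)
      segments[sample.int(length(segments), n_del)] <- NULL
  }
  truth <- art
  if (length(segments)) truth[unique(unlist(segments))] <- TRUE
  truth <- matrix(truth, n, n)
  truth[faz] <- FALSE

  k <- gauss_kernels(0.7)
  rendered <- sep_filter(truth * 1, k$g, k$g)
  mx <- max(rendered)
  if (mx > 0) rendered <- rendered / mx
  # decorrelation noise floor: the background carries a fraction of the
  # vessel signal so the multiplicative speckle corrupts it too
  b <- spec$background_level
  rendered <- b + (1 - b) * rendered
  if (spec$speckle_sigma > 0)
    rendered <- rendered * (1 + matrix(stats::rnorm(n * n, 0, spec$speckle_sigma), n, n))
  rendered <- pmax(pmin(rendered, 1), 0)

  structure(list(
    image = enface_image(rendered, width_mm = spec$width_mm,
                         laterality = laterality, subject_id = subject_id,
                         group_label = group_label, normalize = FALSE),
    truth_mask = truth,
    faz = faz_mask(faz)), class = "phantom")
}

#' Generate a synthetic cohort with group-wise capillary dropout
#'
#' Derives one deterministic seed per subject from the master seed,
#' alternates laterality OD/OS, draws each subject's capillary density
#' from `Normal(base, subject_sd)` (truncated to `[0.05, 0.95]`) so the
#' cohort has realistic between-subject variability, and applies the
#' group's dropout fraction.
#'
#' @param n_per_group Subjects per group (>= 2; the ANOVA needs
#'   replication).
#' @param group_dropout Named numeric vector mapping each of `control`,
#'   `noDR`, `NPDR`, `PDR` to a dropout fraction.
#' @param base_spec A [phantom_spec] providing all other parameters.
#' @param seed Master RNG seed.
#' @return List with `cohort` (data.frame: `subject_id`, `group`,
#'   `laterality`, `image_path`, `faz_path`; paths are `NA` until
#'   [write_cohort]) and `phantoms` (named list of [make_phantom] outputs,
#'   one per row).
#' @export
make_cohort <- function(n_per_group, group_dropout, base_spec = phantom_spec(),
                        seed = 1L) {
  if (n_per_group < 2) stop("n_per_group must be >= 2 (the ANOVA needs replication)")
  if (!all(GROUP_LEVELS %in% names(group_dropout)))
    stop(sprintf("group_dropout must name all groups: %s",
                 paste(GROUP_LEVELS, collapse = ", ")))
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  n_total <- 4L * n_per_group
  subject_seeds <- sample.int(.Machine$integer.max - 1L, n_total)
  dens <- pmin(0.95, pmax(0.05, stats::rnorm(n_total, base_spec$capillary_density,
                                             base_spec$subject_sd)))
  cohort <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n_total)),
    group = factor(rep(GROUP_LEVELS, each = n_per_group), levels = GROUP_LEVELS),
    laterality = rep(c("OD", "OS"), length.out = n_total),
    image_path = NA_character_, faz_path = NA_character_,
    stringsAsFactors = FALSE)
  phantoms <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    spec_i <- base_spec
    spec_i$seed <- subject_seeds[i]
    spec_i$capillary_density <- dens[i]
    spec_i$dropout_fraction <- unname(group_dropout[[as.character(cohort$group[i])]])
    phantoms[[i]] <- make_phantom(spec_i, subject_id = cohort$subject_id[i],
                                  group_label = as.character(cohort$group[i]),
                                  laterality = cohort$laterality[i])
  }
  names(phantoms) <- cohort$subject_id
  list(cohort = cohort, phantoms = phantoms)
}

#' Write a synthetic cohort to disk
#'
#' Phantom images go out as 16-bit TIFFs, FAZ and truth masks as PNGs,
#' and the cohort table as `cohort.csv` referencing them.
#'
#' @param sim Output of [make_cohort].
#' @param dir Output directory (created if needed).
#' @return Path to the written cohort CSV.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- sim$cohort
  for (i in seq_len(nrow(cohort))) {
    id <- cohort$subject_id[i]
    ph <- sim$phantoms[[id]]
    img <- file.path(dir, paste0(id, "_angio.tiff"))
    fazp <- file.path(dir, paste0(id, "_faz.png"))
    tiff::writeTIFF(ph$image$pixels, img, bits.per.sample = 16L)
    png::writePNG(ph$faz$mask * 1, fazp)
    png::writePNG(ph$truth_mask * 1, file.path(dir, paste0(id, "_truth.png")))
    cohort$image_path[i] <- img
    cohort$faz_path[i] <- fazp
  }
  csv <- file.path(dir, "cohort.csv")
  utils::write.csv(cohort, csv, row.names = FALSE)
  csv
}

#' Truth-mask vessel fraction outside the FAZ
#'
#' @param phantom A [make_phantom] output.
#' @return Fraction of outside-FAZ pixels that are true vessels.
#' @export
truth_density <- function(phantom) {
  sum(phantom$truth_mask & !phantom$faz$mask) / sum(!phantom$faz$mask)
}
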