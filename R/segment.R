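# Morphological cleanup shared by coarse and refined segmentation:
# opening (removes specks), closing (bridges small gaps), hole filling.
clean_binary <- function(mask, open_radius_px = 2, close_radius_px = 3) {
  m <- EBImage::Image(mask * 1)
  if (open_radius_px >= 1)
    m <- EBImage::opening(m, EBImage::makeBrush(2L * open_radius_px + 1L, "disc"))
  if (close_radius_px >= 1)
    m <- EBImage::closing(m, EBImage::makeBrush(2L * close_radius_px + 1L, "disc"))
  m <- EBImage::fillHull(m)
  matrix(as.numeric(m) > 0.5, nrow(mask), ncol(mask))
}

#' Coarse whole-image pellet mask
#'
#' First-pass segmentation: the darkest of the three intensity layers of the
#' chosen channel (pellets appear dark in the red channel against the bluish
#' background), cleaned by morphological opening, closing and hole filling.
#'
#' @param image A [calibrated_image()].
#' @param channel Channel index used for thresholding (default 1, red).
#' @param open_radius_px,close_radius_px Disk structuring-element radii.
#' @return Logical matrix: `TRUE` on candidate pellet pixels.
#' @export
coarse_mask <- function(image, channel = 1L,
                        open_radius_px = 2, close_radius_px = 3) {
  stopifnot(inherits(image, "calibrated_image"))
  tl <- three_level_threshold(image$pixels[, , channel])
  clean_binary(tl$labels == 2L, open_radius_px, close_radius_px)
}

#' Gate coarse objects by area and extract candidates
#'
#' Connected components of the coarse mask strictly larger than
#' `min_area_mm2` are kept as potential pellets; each is returned with its
#' padded bounding box, the coarse mask restricted to that component, and
#' the RGB crop.
#'
#' @param mask Logical matrix from [coarse_mask()].
#' @param image The source [calibrated_image()] (supplies the pixel size).
#' @param min_area_mm2 Area gate in mm^2 (default 0.0165; objects with area
#'   exactly equal to the gate are excluded).
#' @param margin_px Bounding-box padding in pixels, clipped to the image.
#' @return List of `pellet_candidate` objects, each with fields `bbox`
#'   (`row0, col0, row1, col1`, half-open, 0-based), `coarse_mask`, `crop`,
#'   `area_mm2`, `equiv_diameter_px`, `on_border`.
#' @export
gate_and_extract <- function(mask, image, min_area_mm2 = 0.0165,
                             margin_px = 5) {
  stopifnot(inherits(image, "calibrated_image"))
  ps <- image$pixel_size
  gate_px <- min_area_mm2 * 1e6 / ps^2
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n == 0L) return(list())
  areas <- tabulate(lab[lab > 0L], nbins = n)
  keep <- which(areas > gate_px)
  nr <- nrow(mask); nc <- ncol(mask)
  out <- vector("list", length(keep))
  for (idx in seq_along(keep)) {
    k <- keep[idx]
    sel <- lab == k
    rows <- range(which(rowSums(sel) > 0))
    cols <- range(which(colSums(sel) > 0))
    on_border <- rows[1] == 1 || cols[1] == 1 || rows[2] == nr || cols[2] == nc
    r0 <- max(1, rows[1] - margin_px); r1 <- min(nr, rows[2] + margin_px)
    c0 <- max(1, cols[1] - margin_px); c1 <- min(nc, cols[2] + margin_px)
    out[[idx]] <- structure(list(
      id = idx,
      bbox = c(row0 = r0 - 1L, col0 = c0 - 1L, row1 = r1, col1 = c1),
      coarse_mask = sel[r0:r1, c0:c1, drop = FALSE],
      crop = image$pixels[r0:r1, c0:c1, , drop = FALSE],
      area_mm2 = areas[k] * ps^2 / 1e6,
      equiv_diameter_px = 2 * sqrt(areas[k] / pi),
      pixel_size = ps,
      on_border = on_border
    ), class = "pellet_candidate")
  }
  out
}

#' Refined per-candidate pellet contour
#'
#' Re-runs the three-level thresholding on the candidate crop alone; because
#' the local histogram differs from the whole image, the resulting
#' thresholds delineate the pellet contour more precisely than the coarse
#' pass. The darkest layer is cleaned and restricted to components that
#' overlap the coarse mask. Crops with fewer than 3 distinct values fall
#' back to the coarse mask with a warning.
#'
#' @param candidate A `pellet_candidate` from [gate_and_extract()].
#' @param channel Channel index (default 1, red).
#' @param open_radius_px,close_radius_px Disk structuring-element radii.
#' @return Logical matrix over the candidate bounding box.
#' @export
refine_contour <- function(candidate, channel = 1L,
                           open_radius_px = 2, close_radius_px = 3) {
  red <- candidate$crop[, , channel]
  if (length(unique(as.numeric(red))) < 3) {
    warnf("degenerate crop (< 3 distinct values); using coarse mask")
    return(candidate$coarse_mask)
  }
  tl <- three_level_threshold(red)
  m <- clean_binary(tl$labels == 2L, open_radius_px, close_radius_px)
  lab <- matrix(as.integer(EBImage::bwlabel(EBImage::Image(m * 1))),
                nrow(m), ncol(m))
  hit <- setdiff(unique(lab[candidate$coarse_mask]), 0L)
  refined <- lab %in% hit
  dim(refined) <- dim(m)
  if (!any(refined)) {
    warnf("refined mask empty; using coarse mask")
    return(candidate$coarse_mask)
  }
  refined
}

#' Inverted normalised distance surface
#'
#' Euclidean distance of every object pixel to the nearest background pixel,
#' inverted and rescaled per connected component so that the object boundary
#' sits at the per-component maximum and the morphological centre at 0.
#'
#' @param mask Logical matrix (nonempty).
#' @return Numeric matrix in `[0, 1]`; pixels outside the mask are 1.
#' @export
inverted_normalized_distance <- function(mask) {
  if (!any(mask)) stopf("empty mask")
  D <- matrix(as.numeric(EBImage::distmap(EBImage::Image(mask * 1))),
              nrow(mask), ncol(mask))
  lab <- matrix(as.integer(EBImage::bwlabel(EBImage::Image(mask * 1))),
                nrow(mask), ncol(mask))
  out <- matrix(1, nrow(mask), ncol(mask))
  for (k in seq_len(max(lab))) {
    sel <- lab == k
    mx <- max(D[sel])
    out[sel] <- if (mx > 0) 1 - D[sel] / mx else 0
  }
  out
}

#' Detect dark pellet core regions
#'
#' Otsu's threshold on the in-mask values of the smoothed, normalised
#' grayscale raster; the below-threshold region is the high-hyphal-density
#' core. Core components smaller than `min_core_px` are discarded as noise.
#'
#' @param norm_gray Normalised grayscale matrix (from
#'   [smooth_and_normalize()]), aligned to `mask`.
#' @param mask Logical pellet mask.
#' @param min_core_px Minimum core component area in pixels.
#' @return Logical core mask. Constant in-mask intensities yield an empty
#'   core set with a warning.
#' @export
detect_cores <- function(norm_gray, mask, min_core_px = 9) {
  vals <- norm_gray[mask]
  if (length(unique(vals)) < 2) {
    warnf("constant in-mask intensities; no cores detected")
    return(matrix(FALSE, nrow(mask), ncol(mask)))
  }
  th <- otsu_threshold(vals)
  cores <- mask & (norm_gray <= th)
  lab <- matrix(as.integer(EBImage::bwlabel(EBImage::Image(cores * 1))),
                nrow(mask), ncol(mask))
  if (max(lab) > 0L) {
    areas <- tabulate(lab[lab > 0L], nbins = max(lab))
    drop <- which(areas < min_core_px)
    cores[lab %in% drop] <- FALSE
  }
  cores
}

#' Separate touching pellets by a combined-surface watershed
#'
#' Builds the flooding surface as the sum of the normalised grayscale raster
#' and the inverted normalised distance surface, so that both the bright
#' hyphal edge between adjacent pellets and the geometric neck contribute to
#' the ridge line. Core regions act as imposed minima: a marker-controlled
#' watershed floods the surface from the cores, restricted to the mask,
#' yielding exactly one instance per core component. Mask components without
#' any core become single instances. Boundary pixels join the instance whose
#' flood reaches them first (deeper minimum wins; ties resolve to the lower
#' label id), so the union of instances equals the mask.
#'
#' @param refined_mask Logical pellet mask.
#' @param norm_gray Normalised grayscale matrix aligned to the mask.
#' @param cores Logical core mask (subset of `refined_mask`).
#' @return Integer matrix: 0 background, `1..K` pellet instances, labelled
#'   in core order then maskwise for coreless components.
#' @export
split_touching <- function(refined_mask, norm_gray, cores) {
  nr <- nrow(refined_mask); nc <- ncol(refined_mask)
  if (!any(refined_mask)) return(matrix(0L, nr, nc))
  surface <- norm_gray + inverted_normalized_distance(refined_mask)
  markers <- matrix(as.integer(EBImage::bwlabel(
    EBImage::Image((cores & refined_mask) * 1))), nr, nc)
  n_core <- max(markers)
  # components with no core become their own (whole-component) markers
  comp <- matrix(as.integer(EBImage::bwlabel(EBImage::Image(refined_mask * 1))),
                 nr, nc)
  has_core <- sort(unique(comp[markers > 0L]))
  coreless <- setdiff(seq_len(max(comp)), has_core)
  if (length(coreless)) {
    extra <- match(comp, coreless)
    sel <- !is.na(extra) & refined_mask
    markers[sel] <- n_core + extra[sel]
  }
  .flood_from_markers(surface, markers, refined_mask)
}
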