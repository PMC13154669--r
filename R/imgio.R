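#' Calibrated microscope image
#'
#' Container for an 8-bit RGB raster together with its spatial calibration.
#' Pixels are stored as a `height x width x 3` numeric array with values in
#' `[0, 255]`, row/column indexed with the origin at the top-left corner.
#'
#' @param pixels Numeric array `height x width x 3`, values in `[0, 255]`.
#' @param pixel_size_um Edge length of one pixel in micrometres (`> 0`).
#' @param source_id Free-text identifier carried through to result tables.
#' @return An object of class `calibrated_image`.
#' @export
calibrated_image <- function(pixels, pixel_size_um, source_id = "image") {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stopf("`pixels` must be a height x width x 3 array (got %s channels)",
          if (length(dim(pixels)) == 3L) dim(pixels)[3] else "a non-3D array of")
  if (min(pixels) < 0 || max(pixels) > 255)
    stopf("pixel values must lie in [0, 255]")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      is.na(pixel_size_um) || pixel_size_um <= 0)
    stopf("`pixel_size_um` must be a single positive number")
  storage.mode(pixels) <- "double"
  structure(
    list(pixels = pixels, pixel_size = pixel_size_um, source_id = source_id),
    class = "calibrated_image"
  )
}

#' @export
print.calibrated_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<calibrated_image '%s': %d x %d px, %.3g um/px>\n",
              x$source_id, d[1], d[2], x$pixel_size))
  invisible(x)
}

#' @export
dim.calibrated_image <- function(x) dim(x$pixels)[1:2]

#' Read an 8-bit RGB image with a pixel-size calibration
#'
#' Reads TIFF or PNG via EBImage and attaches the micrometre-per-pixel
#' calibration. The calibration is supplied by the caller because stereo
#' images are typically acquired at varying magnifications and the files
#' carry no reliable scale metadata.
#'
#' @param path File path (8-bit RGB TIFF or PNG).
#' @param pixel_size_um Micrometres per pixel.
#' @return A [calibrated_image()].
#' @export
load_image <- function(path, pixel_size_um) {
  if (!file.exists(path)) stopf("file does not exist: %s", path)
  img <- EBImage::readImage(path)
  d <- dim(img)
  if (length(d) != 3L || d[3] != 3L)
    stopf("image is not RGB: expected 3 channels, found %d (%s)",
          if (length(d) == 3L) d[3] else 1L, path)
  vals <- EBImage::imageData(img) * 255
  if (max(abs(vals - round(vals))) > 1e-6)
    stopf("image is not 8-bit: sample values are not multiples of 1/255 (%s)",
          path)
  # EBImage stores (x, y, channel); transpose to row/column convention
  px <- array(0, dim = c(d[2], d[1], 3L))
  for (ch in 1:3) px[, , ch] <- t(round(vals[, , ch]))
  calibrated_image(px, pixel_size_um, source_id = basename(path))
}

#' Write a calibrated image to TIFF or PNG (8-bit)
#'
#' @param image A [calibrated_image()].
#' @param path Output path; format chosen from the file extension.
#' @return `path`, invisibly.
#' @export
save_image <- function(image, path) {
  stopifnot(inherits(image, "calibrated_image"))
  d <- dim(image$pixels)
  arr <- array(0, dim = c(d[2], d[1], 3L))
  for (ch in 1:3) arr[, , ch] <- t(image$pixels[, , ch]) / 255
  img <- EBImage::Image(arr, colormode = "Color")
  EBImage::writeImage(img, path, bits.per.sample = 8L)
  invisible(path)
}

#' Write a per-pellet feature table as CSV
#'
#' One row per pellet, ordered by image then label id; column headers carry
#' units. Writing the same records twice yields byte-identical files.
#'
#' @param records Tibble of pellet records as produced by [analyze()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pellet_table <- function(records, path) {
  cols <- c(
    image = "image", label = "label", class = "class",
    area_mm2 = "area_mm2", equiv_diameter_um = "equiv_diameter_um",
    perimeter_um = "perimeter_um", circularity = "circularity",
    solidity = "solidity", aspect_ratio = "aspect_ratio",
    core_count = "core_count", core_area_fraction = "core_area_fraction",
    mean_gray = "mean_gray", border_contact = "border_contact"
  )
  keep <- intersect(cols, names(records))
  out <- as.data.frame(records[, keep, drop = FALSE])
  if (nrow(out) > 0)
    out <- out[order(out$image, out$label), , drop = FALSE]
  num <- vapply(out, is.numeric, logical(1)) &
    !(names(out) %in% c("core_count", "label"))
  out[num] <- lapply(out[num], function(v) sprintf("%.6g", v))
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.csv(out, con, row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Annotation set for accuracy evaluation
#'
#' Ground-truth annotations in one of two dialects: a 16-bit instance label
#' mask plus a class table, or a table of centroids with classes.
#'
#' @param classes Tibble/data frame with columns `label` (instance id) and
#'   `class` (one of `AN_pellet`, `SC_pellet`, `SC_aggregate`); for centroid
#'   annotations additionally `row` and `col` (0-based pixel coordinates).
#' @param label_mask Optional integer matrix (0 = background) aligned to the
#'   annotated image.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(classes, label_mask = NULL) {
  classes <- tibble::as_tibble(classes)
  if (!all(c("label", "class") %in% names(classes)))
    stopf("`classes` needs columns `label` and `class`")
  bad <- setdiff(unique(classes$class), PELLET_CLASSES)
  if (length(bad))
    stopf("unknown class label(s): %s", paste(bad, collapse = ", "))
  if (is.null(label_mask) && !all(c("row", "col") %in% names(classes)))
    stopf("centroid annotations need `row` and `col` columns")
  if (!is.null(label_mask)) {
    present <- setdiff(unique(as.integer(label_mask)), 0L)
    if (!all(present %in% classes$label))
      stopf("label mask contains instances missing from the class table")
  }
  structure(list(classes = classes, label_mask = label_mask),
            class = "annotation_set")
}

#' Export an instance labeling as a 16-bit label TIFF
#' @param label_mask Integer matrix of instance labels (0 = background).
#' @param path Output path (use a `.tif` extension; TIFF is the format
#'   that preserves 16-bit label depth).
#' @return `path`, invisibly.
#' @export
write_label_mask <- function(label_mask, path) {
  if (max(label_mask) > 65535) stopf("more than 65535 instances")
  EBImage::writeImage(t(label_mask) / 65535, path, type = "tiff",
                      bits.per.sample = 16L)
  invisible(path)
}

#' Read a 16-bit label TIFF written by [write_label_mask()]
#' @param path Label TIFF path.
#' @return Integer matrix of instance labels.
#' @export
read_label_mask <- function(path) {
  img <- EBImage::readImage(path)
  round(t(EBImage::imageData(img)) * 65535)
}

#' Render a class-coloured overlay
#'
#' Tints segmented instances on top of the source image: fungal pellets in
#' red, single bacterial pellets in dark blue, bacterial aggregates in cyan.
#' Pixels outside labelled regions are returned unchanged.
#'
#' @param image A [calibrated_image()].
#' @param label_mask Integer instance labeling aligned to `image`.
#' @param classes Character vector (or tibble with `label`, `class`) giving
#'   the class of each instance `1..max(label_mask)`.
#' @param alpha Blend weight of the tint in `[0, 1]`.
#' @return A [calibrated_image()] with tinted instances.
#' @export
render_overlay <- function(image, label_mask, classes, alpha = 0.5) {
  stopifnot(inherits(image, "calibrated_image"))
  if (!identical(dim(label_mask), dim(image$pixels)[1:2]))
    stopf("label mask is not aligned to the image")
  if (is.data.frame(classes)) {
    cl <- classes$class[order(classes$label)]
  } else cl <- classes
  bad <- setdiff(unique(cl), PELLET_CLASSES)
  if (length(bad))
    stopf("unknown class label(s): %s", paste(bad, collapse = ", "))
  px <- image$pixels
  for (k in seq_along(cl)) {
    sel <- label_mask == k
    if (!any(sel)) next
    col <- CLASS_COLORS[[cl[k]]]
    for (ch in 1:3) {
      plane <- px[, , ch]
      plane[sel] <- (1 - alpha) * plane[sel] + alpha * col[ch]
      px[, , ch] <- plane
    }
  }
  calibrated_image(px, image$pixel_size,
                   source_id = paste0(image$source_id, "_overlay"))
}
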