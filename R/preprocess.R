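#' Three-class multi-level Otsu thresholding
#'
#' Splits a single-channel raster into three intensity layers by choosing two
#' thresholds `t1 < t2` that maximise the between-class variance, the
#' multi-level generalisation of Otsu's criterion. In transmitted-light
#' stereo images of pellet suspensions the three layers correspond to the
#' mid-intensity background, the bright one-sided lateral shadows, and the
#' dark pellets; the darkest layer receives label 2.
#'
#' Thresholds are placed at the midpoint between the two observed gray
#' values that separate adjacent classes, so they fall strictly inside the
#' empty intensity gap. Ties in the criterion are broken toward the
#' lexicographically smallest threshold pair.
#'
#' @param channel_raster Numeric matrix with at least 3 distinct values.
#' @return A list of class `three_class_map` with elements `thresholds`
#'   (`c(t1, t2)`), and `labels` (integer matrix: 0 = background layer,
#'   1 = bright shadow layer, 2 = dark pellet layer).
#' @export
three_level_threshold <- function(channel_raster) {
  v <- sort(unique(as.numeric(channel_raster)))
  k <- length(v)
  if (k < 3)
    stopf("degenerate input: need >= 3 distinct gray values, found %d", k)
  cnt <- tabulate(match(as.numeric(channel_raster), v), nbins = k)
  w <- cnt / sum(cnt)
  W <- cumsum(w)
  S <- cumsum(w * v)
  Stot <- S[k]
  # maximise sum_c S_c^2 / W_c over boundary index pairs i < j (both < k)
  best <- c(-Inf, NA, NA)
  for (i in 1:(k - 2)) {
    j <- (i + 1):(k - 1)
    wA <- W[i]; sA <- S[i]
    wB <- W[j] - wA; sB <- S[j] - sA
    wC <- 1 - W[j]; sC <- Stot - S[j]
    crit <- sA^2 / wA + sB^2 / wB + sC^2 / wC
    jm <- which.max(crit)
    if (crit[jm] > best[1] + 1e-12) best <- c(crit[jm], i, j[jm])
  }
  i <- best[2]; j <- best[3]
  t1 <- (v[i] + v[i + 1]) / 2
  t2 <- (v[j] + v[j + 1]) / 2
  x <- channel_raster
  labels <- matrix(0L, nrow(x), ncol(x))
  labels[x <= t1] <- 2L          # darkest layer: pellets
  labels[x > t2] <- 1L           # brightest layer: lateral shadows
  structure(list(thresholds = c(t1, t2), labels = labels),
            class = "three_class_map")
}

# Plain two-class Otsu on a value vector, same midpoint convention as
# three_level_threshold(); used for core detection inside a pellet mask.
otsu_threshold <- function(values) {
  v <- sort(unique(as.numeric(values)))
  k <- length(v)
  if (k < 2) return(NA_real_)
  cnt <- tabulate(match(as.numeric(values), v), nbins = k)
  w <- cnt / sum(cnt)
  W <- cumsum(w)
  S <- cumsum(w * v)
  i <- 1:(k - 1)
  crit <- S[i]^2 / W[i] + (S[k] - S[i])^2 / (1 - W[i])
  b <- which.max(crit)
  (v[b] + v[b + 1]) / 2
}

#' RGB to grayscale conversion (ITU-R BT.601 luma)
#'
#' @param rgb A [calibrated_image()] or a `H x W x 3` array.
#' @return Numeric matrix of luma values on the input scale.
#' @export
to_grayscale <- function(rgb) {
  px <- if (inherits(rgb, "calibrated_image")) rgb$pixels else rgb
  if (length(dim(px)) != 3L || dim(px)[3] != 3L)
    stopf("`rgb` must have 3 channels")
  g <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  matrix(g, dim(px)[1], dim(px)[2])
}

#' Retrospective correction of location-dependent brightness
#'
#' Estimates a multiplicative shading surface from a collection of grayscale
#' rasters of common shape and divides it out, preserving each raster's mean
#' intensity. The default estimator takes a robust per-pixel quantile across
#' the collection and smooths it with a low-order 2-D polynomial; it assumes
#' the shading varies slowly across the field of view, the usual situation
#' for vignetting and lateral illumination gradients. An alternative
#' estimator (a function taking the list of rasters and returning a shading
#' matrix) can be plugged in.
#'
#' @param gray_rasters A matrix or list of matrices of identical shape.
#' @param estimator Optional replacement shading estimator.
#' @param quantile_prob Per-pixel quantile used by the default estimator.
#' @param degree Polynomial degree of the smoothing fit.
#' @return A list of corrected rasters (a single matrix if a single matrix
#'   was supplied) with an attribute `shading` carrying the estimated
#'   surface (normalised to mean 1).
#' @export
correct_illumination <- function(gray_rasters, estimator = NULL,
                                 quantile_prob = 0.5, degree = 2) {
  single <- is.matrix(gray_rasters)
  if (single) gray_rasters <- list(gray_rasters)
  if (!length(gray_rasters)) stopf("empty raster collection")
  dims <- vapply(gray_rasters, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stopf("rasters have mixed shapes")
  shading <- if (is.null(estimator)) {
    shading_quantile_poly(gray_rasters, quantile_prob, degree)
  } else {
    estimator(gray_rasters)
  }
  shading <- pmax(shading, 1e-6)
  shading <- shading / mean(shading)
  corrected <- lapply(gray_rasters, function(x) {
    y <- x / shading
    m <- mean(y)
    if (m > 0) y * (mean(x) / m) else y
  })
  attr(corrected, "shading") <- shading
  if (single) {
    out <- corrected[[1]]
    attr(out, "shading") <- shading
    return(out)
  }
  corrected
}

# Default shading estimator: per-pixel quantile across the collection,
# smoothed by a polynomial surface in (row, col). The fit is done on a
# subgrid for speed; shading varies slowly so nothing is lost.
shading_quantile_poly <- function(rasters, prob, degree) {
  nr <- nrow(rasters[[1]]); nc <- ncol(rasters[[1]])
  ri <- unique(round(seq(1, nr, length.out = min(nr, 64))))
  ci <- unique(round(seq(1, nc, length.out = min(nc, 64))))
  grid <- expand.grid(row = ri, col = ci)
  pick <- cbind(grid$row, grid$col)
  if (length(rasters) == 1L) {
    grid$z <- rasters[[1]][pick]
  } else {
    vals <- vapply(rasters, function(x) x[pick], numeric(nrow(pick)))
    grid$z <- apply(vals, 1, quantile, probs = prob, names = FALSE)
  }
  grid$r <- (grid$row - 1) / max(nr - 1, 1)
  grid$c <- (grid$col - 1) / max(nc - 1, 1)
  fit <- lm(z ~ poly(r, degree, raw = TRUE) + poly(c, degree, raw = TRUE) +
              I(r * c), data = grid)
  full <- expand.grid(r = ((1:nr) - 1) / max(nr - 1, 1),
                      c = ((1:nc) - 1) / max(nc - 1, 1))
  matrix(predict(fit, newdata = full), nr, nc)
}

#' Disk median smoothing followed by unit-interval normalisation
#'
#' Applies a median filter over a disk-shaped neighbourhood whose radius is
#' one-twentieth of the object diameter (rounded to the nearest integer,
#' floored at 1 px), then rescales the result to span `[0, 1]`. The
#' diameter is that of the coarse candidate, the only diameter available at
#' this stage of the pipeline.
#'
#' @param gray Numeric matrix.
#' @param object_diameter_px Equivalent diameter of the object in pixels.
#' @return Numeric matrix in `[0, 1]` with attribute `filter_radius_px`. If
#'   the filtered raster is constant the result is all zeros with a warning
#'   (min-max normalisation is undefined).
#' @export
smooth_and_normalize <- function(gray, object_diameter_px) {
  if (!is.numeric(object_diameter_px) || object_diameter_px <= 0)
    stopf("`object_diameter_px` must be positive")
  radius <- max(1L, as.integer(round(object_diameter_px / 20)))
  sm <- .disk_median(gray, radius)
  rng <- range(sm)
  if (diff(rng) <= .Machine$double.eps) {
    warnf("raster is constant after filtering; returning all zeros")
    out <- matrix(0, nrow(gray), ncol(gray))
  } else {
    out <- (sm - rng[1]) / diff(rng)
  }
  attr(out, "filter_radius_px") <- radius
  out
}
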