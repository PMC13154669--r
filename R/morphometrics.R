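#' Morphometric features of one pellet instance
#'
#' Canonical shape and intensity descriptors per segmented instance. Lengths
#' are reported in micrometres and areas in mm^2 via the pixel calibration.
#' The perimeter is a corrected chain-code contour length (axial steps
#' weighted 0.948, diagonal steps 1.340, the standard bias correction for
#' digitised outlines); circularity (`4*pi*area/perimeter^2`) inherits
#' that estimator and may slightly exceed 1 for small rasterised disks.
#' Solidity uses the convex hull of the pixel outlines (pixel corners), so
#' it is always `<= 1`.
#'
#' @param instance Logical matrix: the instance mask (nonempty).
#' @param norm_gray Normalised grayscale matrix aligned to the mask.
#' @param cores Logical core mask.
#' @param pixel_size_um Micrometres per pixel.
#' @param on_border Whether the parent candidate touched the image border.
#' @return One-row tibble with columns `area_mm2`, `equiv_diameter_um`,
#'   `perimeter_um`, `circularity`, `solidity`, `aspect_ratio`,
#'   `core_count`, `core_area_fraction`, `mean_gray`, `border_contact`.
#' @export
compute_features <- function(instance, norm_gray, cores, pixel_size_um,
                             on_border = FALSE) {
  if (!any(instance)) stopf("empty instance mask")
  area_px <- sum(instance)
  area_um2 <- area_px * pixel_size_um^2

  img <- EBImage::Image(instance * 1)
  mo <- EBImage::computeFeatures.moment(img)
  perim_px <- chain_perimeter(img)
  perim_um <- perim_px * pixel_size_um
  circularity <- if (perim_px > 0) 4 * pi * area_px / perim_px^2 else NA_real_

  solidity <- area_px / convex_hull_area(instance)

  major <- mo[1, "m.majoraxis"]
  ecc <- mo[1, "m.eccentricity"]
  minor <- major * sqrt(max(0, 1 - ecc^2))
  aspect_ratio <- if (is.finite(minor) && minor > 0) major / minor else 1

  core_in <- cores & instance
  ncore <- max(EBImage::bwlabel(EBImage::Image(core_in * 1)))

  tibble::tibble(
    area_mm2 = area_um2 / 1e6,
    equiv_diameter_um = 2 * sqrt(area_um2 / pi),
    perimeter_um = perim_um,
    circularity = circularity,
    solidity = solidity,
    aspect_ratio = aspect_ratio,
    core_count = as.integer(ncore),
    core_area_fraction = sum(core_in) / area_px,
    mean_gray = mean(norm_gray[instance]),
    border_contact = on_border
  )
}

# Corrected chain-code perimeter: follow the 8-connected outer contour
# and weight axial/diagonal steps by the standard digitisation-bias
# coefficients (Kulpa), which are near-exact for smooth convex outlines.
chain_perimeter <- function(img) {
  oc <- EBImage::ocontour(img)
  total <- 0
  for (ct in oc) {
    n <- nrow(ct)
    if (n < 2) { total <- total + 3.14; next }  # single pixel
    dif <- ct - ct[c(2:n, 1), , drop = FALSE]
    step2 <- rowSums(dif^2)
    total <- total + 0.948 * sum(step2 == 1) + 1.340 * sum(step2 == 2)
  }
  total
}

# Convex hull area of a pixel mask, computed over the 4 corners of every
# mask pixel so the hull always contains the full rasterised area.
convex_hull_area <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  pts <- rbind(
    cbind(idx[, 1] - 0.5, idx[, 2] - 0.5),
    cbind(idx[, 1] - 0.5, idx[, 2] + 0.5),
    cbind(idx[, 1] + 0.5, idx[, 2] - 0.5),
    cbind(idx[, 1] + 0.5, idx[, 2] + 0.5)
  )
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  n <- nrow(hp)
  if (n < 3) return(sum(mask))
  x <- hp[, 1]; y <- hp[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Classification rule set
#'
#' Thresholds for the three-class decision between single fungal pellets,
#' single bacterial pellets, and bacterial aggregates. Defaults reflect the
#' qualitative morphology of the two species under typical shake-flask
#' conditions: the fungus forms large (above ~400 um) spherical pellets
#' with a single dark core, a small core-area fraction and a bright hyphal
#' body, while the bacterium stays around 250 um and may fuse into
#' irregular multi-core aggregates.
#'
#' @param d_large_um Diameter at and above which a single-core particle is a
#'   fungal pellet.
#' @param d_sc_max_um Diameter at and below which a non-aggregate particle is
#'   a bacterial pellet (must not exceed `d_large_um`).
#' @param core_frac_an_max,mean_gray_an_min Core-area fraction and mean-gray
#'   cutoffs deciding the ambiguous diameter band.
#' @param agg_min_cores Minimum core count that marks an aggregate.
#' @param agg_solidity_max Solidity below which a small particle is an
#'   aggregate.
#' @return An object of class `class_rules`.
#' @export
class_rules <- function(d_large_um = 400, d_sc_max_um = 350,
                        core_frac_an_max = 0.3, mean_gray_an_min = 0.6,
                        agg_min_cores = 2L, agg_solidity_max = 0.85) {
  vals <- c(d_large_um, d_sc_max_um, core_frac_an_max, mean_gray_an_min,
            agg_min_cores, agg_solidity_max)
  if (any(vals <= 0)) stopf("all rule thresholds must be positive")
  if (d_sc_max_um > d_large_um)
    stopf("d_sc_max_um must not exceed d_large_um")
  structure(list(
    d_large_um = d_large_um, d_sc_max_um = d_sc_max_um,
    core_frac_an_max = core_frac_an_max, mean_gray_an_min = mean_gray_an_min,
    agg_min_cores = as.integer(agg_min_cores),
    agg_solidity_max = agg_solidity_max
  ), class = "class_rules")
}

#' Read / write a rule set as YAML
#' @param path YAML file path.
#' @return [class_rules()] for `read_class_rules`; `path` invisibly for
#'   `write_class_rules`.
#' @export
read_class_rules <- function(path) do.call(class_rules, yaml::read_yaml(path))

#' @rdname read_class_rules
#' @param rules A [class_rules()] object.
#' @export
write_class_rules <- function(rules, path) {
  yaml::write_yaml(unclass(rules), path)
  invisible(path)
}

#' Classify pellets from morphometric features
#'
#' Deterministic rule-table classification into `AN_pellet` (single fungal
#' pellet), `SC_pellet` (single bacterial pellet) or `SC_aggregate`
#' (bacterial aggregate). The decision sequence: (1) multi-core particles,
#' and small low-solidity particles, are aggregates; (2) otherwise large
#' particles with at most one core are fungal pellets; (3) otherwise
#' particles within the bacterial size range are bacterial pellets;
#' (4) the remaining ambiguous diameter band is decided by core-area
#' fraction and mean gray intensity (fungal pellets have a smaller core
#' fraction and a brighter body). Every feature record receives exactly one
#' class.
#'
#' @param features Data frame with columns `equiv_diameter_um`,
#'   `core_count`, `solidity`, `core_area_fraction`, `mean_gray` (one row
#'   per pellet).
#' @param rules A [class_rules()] object.
#' @return `features` with a `class` column appended (tibble).
#' @export
classify_pellets <- function(features, rules = class_rules()) {
  stopifnot(inherits(rules, "class_rules"))
  f <- tibble::as_tibble(features)
  d <- f$equiv_diameter_um
  is_agg <- f$core_count >= rules$agg_min_cores |
    (f$solidity < rules$agg_solidity_max & d <= rules$d_large_um)
  is_an <- !is_agg & d >= rules$d_large_um & f$core_count <= 1L
  is_sc <- !is_agg & !is_an & d <= rules$d_sc_max_um
  band_an <- !is_agg & !is_an & !is_sc &
    f$core_area_fraction <= rules$core_frac_an_max &
    f$mean_gray >= rules$mean_gray_an_min
  cls <- rep("SC_pellet", nrow(f))
  cls[is_agg] <- "SC_aggregate"
  cls[is_an | band_an] <- "AN_pellet"
  cls[is_sc] <- "SC_pellet"
  f$class <- cls
  f
}

#' Classify a single feature record
#' @param features One-row data frame or named list of features.
#' @param rules A [class_rules()] object.
#' @return Class label (character scalar).
#' @export
classify_pellet <- function(features, rules = class_rules()) {
  classify_pellets(tibble::as_tibble(as.list(features)), rules)$class
}

#' Compare predictions to annotations
#'
#' Matches predicted instances to ground truth one-to-one, greedily by
#' descending IoU (intersection over union), accepting matches with IoU at
#' least `iou_min`. Centroid annotations use containment instead: a truth
#' centroid matches the predicted instance it falls inside. The confusion
#' matrix is computed over matched pairs; unmatched truths count against
#' detection recall. Because the reference protocol for the headline
#' accuracy is ambiguous, both accuracy over matched pairs
#' (`overall_accuracy`) and accuracy over all annotated objects
#' (`accuracy_all_truths`, unmatched truths counted as errors) are
#' reported.
#'
#' @param pred_labels Integer instance labeling (prediction).
#' @param pred_classes Character vector: class of predicted instance
#'   `1..max(pred_labels)`.
#' @param truth An [annotation_set()].
#' @param iou_min Minimum IoU for a valid match.
#' @return An object of class `pellet_evaluation`: list with `confusion`
#'   (3x3, truth x predicted), `overall_accuracy`, `accuracy_all_truths`,
#'   `detection_recall`, `per_class` tibble, `n_matched`, `n_truth`,
#'   `n_pred`.
#' @export
evaluate_detections <- function(pred_labels, pred_classes, truth,
                                iou_min = 0.5) {
  stopifnot(inherits(truth, "annotation_set"))
  n_pred <- max(0L, max(pred_labels))
  truth_tbl <- truth$classes
  n_truth <- nrow(truth_tbl)

  matches <- if (!is.null(truth$label_mask)) {
    match_by_iou(pred_labels, truth$label_mask, truth_tbl$label, iou_min)
  } else {
    match_by_centroid(pred_labels, truth_tbl)
  }

  conf <- matrix(0L, 3, 3, dimnames = list(truth = PELLET_CLASSES,
                                           predicted = PELLET_CLASSES))
  if (nrow(matches)) {
    tc <- truth_tbl$class[match(matches$truth, truth_tbl$label)]
    pc <- pred_classes[matches$pred]
    for (i in seq_along(tc)) conf[tc[i], pc[i]] <- conf[tc[i], pc[i]] + 1L
  }
  n_matched <- sum(conf)
  acc <- if (n_matched > 0) sum(diag(conf)) / n_matched else NA_real_
  acc_all <- if (n_truth > 0) sum(diag(conf)) / n_truth else NA_real_
  per_class <- tibble::tibble(
    class = PELLET_CLASSES,
    precision = vapply(1:3, function(j)
      if (sum(conf[, j]) > 0) conf[j, j] / sum(conf[, j]) else NA_real_,
      numeric(1)),
    recall = vapply(1:3, function(i)
      if (sum(conf[i, ]) > 0) conf[i, i] / sum(conf[i, ]) else NA_real_,
      numeric(1))
  )
  structure(list(
    confusion = conf,
    overall_accuracy = acc,
    accuracy_all_truths = acc_all,
    detection_recall = if (n_truth > 0) n_matched / n_truth else NA_real_,
    per_class = per_class,
    n_matched = n_matched, n_truth = n_truth, n_pred = n_pred
  ), class = "pellet_evaluation")
}

match_by_iou <- function(pred_labels, truth_labels, truth_ids, iou_min) {
  # pair areas via a cross-tabulation of overlapping labels
  sel <- pred_labels > 0L | truth_labels > 0L
  p <- pred_labels[sel]; t <- truth_labels[sel]
  pa <- tabulate(p[p > 0L], nbins = max(1L, max(pred_labels)))
  ta_all <- tabulate(t[t > 0L], nbins = max(1L, max(truth_labels)))
  both <- p > 0L & t > 0L
  if (!any(both)) return(data.frame(pred = integer(), truth = integer()))
  key <- paste(p[both], t[both])
  ov <- table(key)
  parts <- do.call(rbind, strsplit(names(ov), " "))
  cand <- data.frame(pred = as.integer(parts[, 1]),
                     truth = as.integer(parts[, 2]),
                     inter = as.integer(ov))
  cand$iou <- cand$inter /
    (pa[cand$pred] + ta_all[cand$truth] - cand$inter)
  cand <- cand[cand$iou >= iou_min & cand$truth %in% truth_ids, , drop = FALSE]
  cand <- cand[order(-cand$iou, cand$pred, cand$truth), , drop = FALSE]
  used_p <- integer(); used_t <- integer()
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!(cand$pred[i] %in% used_p) && !(cand$truth[i] %in% used_t)) {
      keep[i] <- TRUE
      used_p <- c(used_p, cand$pred[i])
      used_t <- c(used_t, cand$truth[i])
    }
  }
  cand[keep, c("pred", "truth"), drop = FALSE]
}

match_by_centroid <- function(pred_labels, truth_tbl) {
  nr <- nrow(pred_labels); nc <- ncol(pred_labels)
  res <- data.frame(pred = integer(), truth = integer(), d2 = numeric())
  for (i in seq_len(nrow(truth_tbl))) {
    r <- truth_tbl$row[i] + 1L; c <- truth_tbl$col[i] + 1L
    if (r < 1 || r > nr || c < 1 || c > nc) next
    lab <- pred_labels[r, c]
    if (lab > 0L) {
      idx <- which(pred_labels == lab, arr.ind = TRUE)
      d2 <- (mean(idx[, 1]) - r)^2 + (mean(idx[, 2]) - c)^2
      res <- rbind(res, data.frame(pred = lab, truth = truth_tbl$label[i],
                                   d2 = d2))
    }
  }
  res <- res[order(res$d2), , drop = FALSE]
  used_p <- integer(); used_t <- integer(); keep <- logical(nrow(res))
  for (i in seq_len(nrow(res))) {
    if (!(res$pred[i] %in% used_p) && !(res$truth[i] %in% used_t)) {
      keep[i] <- TRUE
      used_p <- c(used_p, res$pred[i]); used_t <- c(used_t, res$truth[i])
    }
  }
  res[keep, c("pred", "truth"), drop = FALSE]
}

#' @export
print.pellet_evaluation <- function(x, ...) {
  cat(sprintf(
    "<pellet_evaluation: %d/%d truths matched, accuracy %.3f (matched), %.3f (all truths)>\n",
    x$n_matched, x$n_truth, x$overall_accuracy, x$accuracy_all_truths))
  print(x$confusion)
  invisible(x)
}

#' Tidy a pellet evaluation into per-class rows
#' @param x A `pellet_evaluation`.
#' @param ... Unused.
#' @return Tibble with one row per class (precision, recall, support).
#' @method tidy pellet_evaluation
#' @export
tidy.pellet_evaluation <- function(x, ...) {
  dplyr::mutate(x$per_class, support = rowSums(x$confusion))
}

#' One-row summary of a pellet evaluation
#' @param x A `pellet_evaluation`.
#' @param ... Unused.
#' @return One-row tibble with overall accuracy (matched and all-truths
#'   modes), detection recall, and counts.
#' @method glance pellet_evaluation
#' @export
glance.pellet_evaluation <- function(x, ...) {
  tibble::tibble(
    overall_accuracy = x$overall_accuracy,
    accuracy_all_truths = x$accuracy_all_truths,
    detection_recall = x$detection_recall,
    n_matched = x$n_matched, n_truth = x$n_truth, n_pred = x$n_pred
  )
}

#' Write an evaluation report (JSON + CSV confusion matrix)
#' @param x A `pellet_evaluation`.
#' @param json_path,csv_path Output paths (either may be `NULL`).
#' @return `x`, invisibly.
#' @export
write_evaluation <- function(x, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      overall_accuracy = x$overall_accuracy,
      accuracy_all_truths = x$accuracy_all_truths,
      detection_recall = x$detection_recall,
      n_matched = x$n_matched, n_truth = x$n_truth, n_pred = x$n_pred,
      confusion = as.data.frame(as.table(x$confusion))
    ), json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) write.csv(x$confusion, csv_path)
  invisible(x)
}
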