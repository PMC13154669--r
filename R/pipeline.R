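#' Pipeline run configuration
#'
#' All tunable parameters of the image-to-population pipeline, serialised
#' alongside every output for provenance.
#'
#' @param channel Channel index for segmentation (1 = red).
#' @param min_area_mm2 Coarse-object area gate in mm^2.
#' @param margin_px Candidate bounding-box padding.
#' @param open_radius_px,close_radius_px Morphology structuring radii.
#' @param min_core_px Minimum core-component area (px).
#' @param rules A [class_rules()] object.
#' @param bin_widths_um Per-class histogram bin widths (um).
#' @param iou_min Evaluation IoU threshold.
#' @param illumination One of `"batch"` (estimate one shading surface from
#'   all whole-image grayscales, the per-collection mode), `"crop"`
#'   (correct each candidate crop individually), `"none"`.
#' @param exclude_border Drop border-contact pellets from population
#'   statistics.
#' @param sample_volume_mL,dilution_factor Optional concentration inputs.
#' @return A `run_config` list.
#' @export
run_config <- function(channel = 1L, min_area_mm2 = 0.0165, margin_px = 5,
                       open_radius_px = 2, close_radius_px = 3,
                       min_core_px = 9, rules = class_rules(),
                       bin_widths_um = c(AN_pellet = 100, SC_pellet = 25,
                                         SC_aggregate = 25),
                       iou_min = 0.5,
                       illumination = c("batch", "crop", "none"),
                       exclude_border = TRUE,
                       sample_volume_mL = NULL, dilution_factor = 10) {
  illumination <- match.arg(illumination)
  stopifnot(inherits(rules, "class_rules"))
  structure(as.list(environment())[
    c("channel", "min_area_mm2", "margin_px", "open_radius_px",
      "close_radius_px", "min_core_px", "rules", "bin_widths_um",
      "iou_min", "illumination", "exclude_border", "sample_volume_mL",
      "dilution_factor")],
    class = "run_config")
}

#' Segment, split and classify the pellets of one image
#'
#' Runs the full single-image pipeline: coarse three-level segmentation of
#' the chosen channel, area gating, per-candidate contour refinement,
#' grayscale smoothing and normalisation, dark-core detection,
#' combined-surface marker-controlled watershed, feature computation and
#' rule-table classification. Deterministic for fixed input and config.
#'
#' @param image A [calibrated_image()].
#' @param config A [run_config()].
#' @param gray Optional pre-corrected whole-image grayscale matrix (used by
#'   [analyze()] for batch illumination correction).
#' @return List with `pellets` (tibble: one row per instance with features
#'   and class), `labels` (whole-image integer instance raster), and
#'   `stage_counts`.
#' @export
analyze_image <- function(image, config = run_config(), gray = NULL) {
  stopifnot(inherits(image, "calibrated_image"))
  if (is.null(gray)) {
    gray <- to_grayscale(image)
    if (config$illumination == "batch")
      gray <- correct_illumination(gray)
  }
  cmask <- coarse_mask(image, channel = config$channel,
                       open_radius_px = config$open_radius_px,
                       close_radius_px = config$close_radius_px)
  cands <- gate_and_extract(cmask, image,
                            min_area_mm2 = config$min_area_mm2,
                            margin_px = config$margin_px)
  labels_full <- matrix(0L, nrow(cmask), ncol(cmask))
  rows <- list()
  next_label <- 0L
  n_instances <- 0L
  for (cand in cands) {
    refined <- refine_contour(cand, channel = config$channel,
                              open_radius_px = config$open_radius_px,
                              close_radius_px = config$close_radius_px)
    bb <- cand$bbox
    gcrop <- gray[(bb["row0"] + 1):bb["row1"],
                  (bb["col0"] + 1):bb["col1"], drop = FALSE]
    if (config$illumination == "crop")
      gcrop <- correct_illumination(gcrop)
    ngray <- suppressWarnings(
      smooth_and_normalize(gcrop, cand$equiv_diameter_px))
    cores <- suppressWarnings(detect_cores(ngray, refined,
                                           min_core_px = config$min_core_px))
    inst <- split_touching(refined, ngray, cores)
    for (k in seq_len(max(inst))) {
      sel <- inst == k
      if (!any(sel)) next
      n_instances <- n_instances + 1L
      next_label <- next_label + 1L
      feats <- compute_features(sel, ngray, cores, image$pixel_size,
                                on_border = cand$on_border)
      feats$image <- image$source_id
      feats$label <- next_label
      feats$candidate <- cand$id
      rows[[length(rows) + 1L]] <- feats
      win <- labels_full[(bb["row0"] + 1):bb["row1"],
                         (bb["col0"] + 1):bb["col1"], drop = FALSE]
      win[sel] <- next_label
      labels_full[(bb["row0"] + 1):bb["row1"],
                  (bb["col0"] + 1):bb["col1"]] <- win
    }
  }
  pellets <- if (length(rows)) {
    classify_pellets(dplyr::bind_rows(rows), config$rules)
  } else {
    tibble::tibble()
  }
  list(
    pellets = pellets,
    labels = labels_full,
    stage_counts = c(candidates = length(cands),
                     instances = n_instances,
                     classified = if (nrow(pellets)) nrow(pellets) else 0L)
  )
}

#' Analyse a batch of images into a pellet table and population summaries
#'
#' Applies [analyze_image()] to every image (sharing one batch-estimated
#' illumination surface when configured), pools the per-pellet records,
#' and summarises each class's size distribution. Per-image failures are
#' collected and skipped; the call errors only if every image fails.
#'
#' @param images List of [calibrated_image()] objects.
#' @param config A [run_config()].
#' @return An object of class `pellet_analysis`: list with `pellets`
#'   (pooled tibble), `summary` (a [summarize_population()] result, or
#'   `NULL` with a `no_objects` flag if nothing was detected), `labels`
#'   (per-image instance rasters), `stage_counts`, `errors`, `config`.
#' @export
analyze <- function(images, config = run_config()) {
  if (inherits(images, "calibrated_image")) images <- list(images)
  if (!length(images)) stopf("need >= 1 image")
  grays <- NULL
  if (config$illumination == "batch") {
    g <- lapply(images, to_grayscale)
    dims <- vapply(g, dim, integer(2))
    if (all(dims[1, ] == dims[1, 1]) && all(dims[2, ] == dims[2, 1])) {
      grays <- correct_illumination(g)
    } else {
      grays <- lapply(g, correct_illumination)
    }
  }
  results <- list(); labels <- list(); errors <- character()
  counts <- c(candidates = 0L, instances = 0L, classified = 0L)
  for (i in seq_along(images)) {
    res <- tryCatch(
      analyze_image(images[[i]], config,
                    gray = if (is.null(grays)) NULL else grays[[i]]),
      error = function(e) e)
    if (inherits(res, "error")) {
      errors <- c(errors, sprintf("%s: %s", images[[i]]$source_id,
                                  conditionMessage(res)))
      next
    }
    results[[length(results) + 1L]] <- res$pellets
    labels[[images[[i]]$source_id]] <- res$labels
    counts <- counts + res$stage_counts
  }
  if (!length(labels) && length(errors))
    stopf("all images failed:\n%s", paste(errors, collapse = "\n"))
  pellets <- dplyr::bind_rows(results)
  summary <- NULL
  no_objects <- nrow(pellets) == 0
  if (!no_objects)
    summary <- summarize_population(
      pellets, bin_widths_um = config$bin_widths_um,
      sample_volume_mL = config$sample_volume_mL,
      dilution_factor = config$dilution_factor,
      exclude_border = config$exclude_border)
  structure(list(pellets = pellets, summary = summary,
                 no_objects = no_objects, labels = labels,
                 stage_counts = counts, errors = errors, config = config),
            class = "pellet_analysis")
}

#' @export
print.pellet_analysis <- function(x, ...) {
  cat(sprintf("<pellet_analysis: %d image(s), %d pellet(s)%s>\n",
              length(x$labels), nrow(x$pellets),
              if (x$no_objects) ", no objects" else ""))
  if (!is.null(x$summary)) print(x$summary$summary)
  invisible(x)
}

#' Evaluate a pipeline run against ground truth
#'
#' Runs the pipeline on each image and pools the confusion matrix over the
#' batch using one-to-one IoU matching per image.
#'
#' @param images List of [calibrated_image()] objects.
#' @param truths List of [annotation_set()] objects, paired with `images`.
#' @param config A [run_config()].
#' @return A pooled `pellet_evaluation` (see [evaluate_detections()]).
#' @export
evaluate_run <- function(images, truths, config = run_config()) {
  if (inherits(images, "calibrated_image")) images <- list(images)
  if (inherits(truths, "annotation_set")) truths <- list(truths)
  if (length(images) != length(truths))
    stopf("images and truths are not paired (%d vs %d)",
          length(images), length(truths))
  conf <- matrix(0L, 3, 3, dimnames = list(truth = PELLET_CLASSES,
                                           predicted = PELLET_CLASSES))
  n_truth <- 0L; n_pred <- 0L
  for (i in seq_along(images)) {
    res <- analyze_image(images[[i]], config)
    classes <- if (nrow(res$pellets))
      res$pellets$class[order(res$pellets$label)] else character()
    ev <- evaluate_detections(res$labels, classes, truths[[i]],
                              iou_min = config$iou_min)
    conf <- conf + ev$confusion
    n_truth <- n_truth + ev$n_truth
    n_pred <- n_pred + ev$n_pred
  }
  n_matched <- sum(conf)
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
    overall_accuracy = if (n_matched > 0) sum(diag(conf)) / n_matched
                       else NA_real_,
    accuracy_all_truths = if (n_truth > 0) sum(diag(conf)) / n_truth
                          else NA_real_,
    detection_recall = if (n_truth > 0) n_matched / n_truth else NA_real_,
    per_class = per_class,
    n_matched = n_matched, n_truth = n_truth, n_pred = n_pred
  ), class = "pellet_evaluation")
}

# Ground truth of a synthetic field as an annotation set.
#' Convert synthetic ground truth to an [annotation_set()]
#' @param truth The `truth` element of a [generate_field()] result.
#' @return An [annotation_set()] with the instance label mask attached.
#' @export
truth_as_annotations <- function(truth) {
  annotation_set(
    tibble::tibble(label = truth$info$instance, class = truth$info$class,
                   row = round(truth$info$row), col = round(truth$info$col)),
    label_mask = truth$labels)
}
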