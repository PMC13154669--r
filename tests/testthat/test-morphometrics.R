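test_that("disk features match geometry within discretisation tolerance", {
  m <- disk_mask(120, 120, 60, 60, 50)
  g <- matrix(0.5, 120, 120)
  f <- compute_features(m, g, matrix(FALSE, 120, 120), pixel_size_um = 10)
  expect_equal(f$equiv_diameter_um, 1000, tolerance = 0.02)
  expect_gte(f$circularity, 0.95)
  expect_lte(f$circularity, 1.2)
  expect_lte(f$solidity, 1)
  expect_gte(f$solidity, 0.95)
  expect_equal(f$aspect_ratio, 1, tolerance = 0.05)
  expect_equal(f$core_count, 0L)
  expect_equal(f$mean_gray, 0.5)
})

test_that("core count and area fraction are measured from the core mask", {
  m <- disk_mask(120, 120, 60, 60, 50)
  core <- disk_mask(120, 120, 60, 60, 50 * sqrt(0.1))  # 10% of the area
  f <- compute_features(m, matrix(0.5, 120, 120), core, 10)
  expect_equal(f$core_count, 1L)
  expect_equal(f$core_area_fraction, 0.1, tolerance = 0.02)
  expect_error(compute_features(matrix(FALSE, 5, 5), matrix(0, 5, 5),
                                matrix(FALSE, 5, 5), 10), "empty")
})

test_that("rule table reproduces the reference decisions", {
  feats <- function(d, cores, frac, gray, sol)
    tibble::tibble(equiv_diameter_um = d, core_count = cores,
                   core_area_fraction = frac, mean_gray = gray,
                   solidity = sol)
  expect_equal(classify_pellet(feats(1000, 1L, 0.1, 0.7, 0.95)), "AN_pellet")
  expect_equal(classify_pellet(feats(250, 1L, 0.4, 0.3, 0.95)), "SC_pellet")
  expect_equal(classify_pellet(feats(300, 3L, 0.5, 0.2, 0.7)),
               "SC_aggregate")
  # ambiguous band decided by core fraction and mean gray
  expect_equal(classify_pellet(feats(375, 1L, 0.1, 0.7, 0.95)), "AN_pellet")
  expect_equal(classify_pellet(feats(375, 1L, 0.5, 0.3, 0.95)), "SC_pellet")
})

test_that("classification is total and monotone in diameter", {
  set.seed(7)
  grid <- tibble::tibble(
    equiv_diameter_um = runif(300, 50, 2000),
    core_count = sample(0:4, 300, replace = TRUE),
    core_area_fraction = runif(300),
    mean_gray = runif(300),
    solidity = runif(300, 0.5, 1)
  )
  out <- classify_pellets(grid)
  expect_true(all(out$class %in% c("AN_pellet", "SC_pellet",
                                   "SC_aggregate")))
  expect_equal(nrow(out), 300)
  # growing a fungal pellet never turns it into a bacterial pellet
  for (i in 1:50) {
    base <- grid[sample(300, 1), ]
    cls <- classify_pellets(base)$class
    if (cls != "AN_pellet") next
    bigger <- base
    bigger$equiv_diameter_um <- base$equiv_diameter_um * runif(1, 1, 3)
    expect_false(classify_pellets(bigger)$class == "SC_pellet")
  }
})

test_that("rule sets validate and round-trip through YAML", {
  expect_error(class_rules(d_large_um = 300, d_sc_max_um = 400), "exceed")
  expect_error(class_rules(d_large_um = -1), "positive")
  r <- class_rules(d_large_um = 500, agg_min_cores = 3)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_class_rules(r, path)
  expect_equal(read_class_rules(path), r)
})

test_that("evaluation scores perfect, inverted, and partial matchings", {
  lab <- matrix(0L, 60, 90)
  lab[disk_mask(60, 90, 20, 20, 8)] <- 1L
  lab[disk_mask(60, 90, 20, 60, 8)] <- 2L
  lab[disk_mask(60, 90, 45, 40, 8)] <- 3L
  cls <- c("AN_pellet", "SC_pellet", "SC_aggregate")
  truth <- annotation_set(
    tibble::tibble(label = 1:3, class = cls,
                   row = c(20, 20, 45), col = c(20, 60, 40)),
    label_mask = lab)
  ev <- evaluate_detections(lab, cls, truth)
  expect_equal(ev$overall_accuracy, 1)
  expect_equal(ev$detection_recall, 1)

  ev2 <- evaluate_detections(lab, c("SC_pellet", "AN_pellet", "SC_pellet"),
                             truth)
  expect_equal(ev2$overall_accuracy, 0)
  expect_equal(ev2$detection_recall, 1)

  # 10 matched (9 correct) + 1 unmatched truth
  big <- matrix(0L, 60, 300)
  for (k in 1:11) big[disk_mask(60, 300, 30, 13 + 26 * (k - 1), 8)] <- k
  pred <- big; pred[pred == 11L] <- 0L
  classes <- rep("SC_pellet", 10)
  classes[1] <- "AN_pellet"  # truth says SC everywhere
  truth2 <- annotation_set(
    tibble::tibble(label = 1:11, class = "SC_pellet",
                   row = 30, col = 13 + 26 * (0:10)),
    label_mask = big)
  ev3 <- evaluate_detections(pred, classes, truth2)
  expect_equal(ev3$overall_accuracy, 0.9)
  expect_equal(ev3$detection_recall, 10 / 11)
  expect_equal(ev3$accuracy_all_truths, 9 / 11)
})

test_that("centroid annotations match by containment", {
  lab <- matrix(0L, 40, 40)
  lab[disk_mask(40, 40, 20, 20, 9)] <- 1L
  truth <- annotation_set(tibble::tibble(label = 5L, class = "SC_pellet",
                                         row = 19, col = 21))
  ev <- evaluate_detections(lab, "SC_pellet", truth)
  expect_equal(ev$n_matched, 1L)
  expect_equal(ev$overall_accuracy, 1)
})

test_that("tidy and glance summarise evaluations", {
  lab <- matrix(0L, 30, 30)
  lab[disk_mask(30, 30, 15, 15, 6)] <- 1L
  truth <- annotation_set(tibble::tibble(label = 1L, class = "AN_pellet",
                                         row = 15, col = 15),
                          label_mask = lab)
  ev <- evaluate_detections(lab, "AN_pellet", truth)
  td <- tidy(ev)
  expect_equal(nrow(td), 3)
  expect_true(all(c("precision", "recall", "support") %in% names(td)))
  gl <- glance(ev)
  expect_equal(gl$overall_accuracy, 1)
  expect_equal(gl$n_truth, 1L)
})
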