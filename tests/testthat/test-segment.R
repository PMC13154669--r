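test_that("coarse mask fills holes and drops specks", {
  img <- phantom_image(disks = data.frame(cr = 100, cc = 100, r = 40))
  px <- img$pixels
  # punch a small interior hole and add an isolated dark speck
  px[100:102, 100:102, 1] <- 150
  px[20, 20, 1] <- 60
  img <- calibrated_image(px, img$pixel_size)
  m <- coarse_mask(img)
  expect_true(all(m[100:102, 100:102]))   # hole filled
  expect_false(m[20, 20])                 # speck opened away
  expect_gt(mask_iou(m, disk_mask(200, 200, 100, 100, 40)), 0.9)
})

test_that("a pellet-free background yields an empty mask", {
  img <- phantom_image(disks = NULL)
  expect_equal(sum(coarse_mask(img)), 0)
})

test_that("area gate converts mm^2 using the pixel size and is strict", {
  # at 10 um/px the 0.0165 mm^2 gate is exactly 165 px^2
  mask <- matrix(FALSE, 80, 80)
  mask[2:17, 2:11] <- TRUE    # 160 px
  mask[40:56, 40:49] <- TRUE  # 170 px
  img <- phantom_image(h = 80, w = 80, pixel_size = 10)
  cands <- gate_and_extract(mask, img)
  expect_length(cands, 1)
  expect_equal(cands[[1]]$area_mm2, 170 * 100 / 1e6)
  # exactly-at-gate components are excluded
  mask2 <- matrix(FALSE, 80, 80)
  mask2[2:16, 2:12] <- TRUE   # 165 px
  expect_length(gate_and_extract(mask2, img), 0)
  expect_length(gate_and_extract(matrix(FALSE, 80, 80), img), 0)
})

test_that("candidates carry bbox, crop and border flag", {
  img <- phantom_image(disks = data.frame(cr = 45, cc = 100, r = 28))
  cands <- gate_and_extract(coarse_mask(img), img)
  expect_length(cands, 1)
  b <- cands[[1]]$bbox
  expect_equal(dim(cands[[1]]$crop)[1:2], unname(c(b["row1"] - b["row0"],
                                                   b["col1"] - b["col0"])))
  expect_false(cands[[1]]$on_border)
  img2 <- phantom_image(disks = data.frame(cr = 10, cc = 100, r = 20))
  cands2 <- gate_and_extract(coarse_mask(img2), img2)
  expect_true(cands2[[1]]$on_border)
})

test_that("refined contour recovers a uniform disk and falls back safely", {
  img <- phantom_image(h = 150, w = 150,
                       disks = data.frame(cr = 75, cc = 75, r = 40))
  cands <- gate_and_extract(coarse_mask(img), img)
  refined <- refine_contour(cands[[1]])
  b <- cands[[1]]$bbox
  truth <- disk_mask(150, 150, 75, 75, 40)[(b["row0"] + 1):b["row1"],
                                           (b["col0"] + 1):b["col1"]]
  expect_gt(mask_iou(refined, truth), 0.95)

  cand2 <- cands[[1]]
  nc2 <- dim(cand2$crop)
  cand2$crop[, , 1] <- matrix(rep_len(c(0, 255), nc2[1] * nc2[2]),
                              nc2[1], nc2[2])
  expect_warning(out <- refine_contour(cand2), "degenerate")
  expect_identical(out, cand2$coarse_mask)
})

test_that("inverted normalised distance is 0 at centre, max at boundary", {
  m <- disk_mask(41, 41, 21, 21, 15)
  s <- inverted_normalized_distance(m)
  expect_equal(s[21, 21], 0)
  boundary <- m & !EBImage::erode(EBImage::Image(m * 1),
                                  EBImage::makeBrush(3, "box")) > 0.5
  expect_equal(max(s[m]), max(s[boundary]))
  # degenerate single-pixel object
  m1 <- matrix(FALSE, 5, 5); m1[3, 3] <- TRUE
  expect_equal(inverted_normalized_distance(m1)[3, 3], 0)
  expect_error(inverted_normalized_distance(matrix(FALSE, 4, 4)), "empty")
})

test_that("core detection separates dark cores and respects min size", {
  m <- disk_mask(60, 60, 30, 30, 25)
  g <- matrix(0.8, 60, 60)
  core_truth <- disk_mask(60, 60, 30, 30, 10)
  g[core_truth] <- 0.2
  cores <- detect_cores(g, m)
  expect_gt(mask_iou(cores, core_truth), 0.9)

  expect_warning(out <- detect_cores(matrix(0.5, 60, 60), m), "constant")
  expect_equal(sum(out), 0)

  g2 <- matrix(0.8, 60, 60)
  g2[disk_mask(60, 60, 20, 20, 6)] <- 0.2
  g2[disk_mask(60, 60, 42, 42, 6)] <- 0.2
  m2 <- disk_mask(60, 60, 30, 30, 29)
  cores2 <- detect_cores(g2, m2)
  expect_equal(max(EBImage::bwlabel(EBImage::Image(cores2 * 1))), 2)
})

test_that("watershed splits two touching disks near the geometric chord", {
  h <- 80; w <- 140
  d1 <- disk_mask(h, w, 40, 50, 26)
  d2 <- disk_mask(h, w, 40, 90, 26)
  mask <- d1 | d2
  g <- matrix(0.8, h, w)
  g[disk_mask(h, w, 40, 50, 8)] <- 0.2
  g[disk_mask(h, w, 40, 90, 8)] <- 0.2
  cores <- detect_cores(g, mask)
  inst <- split_touching(mask, g, cores)
  expect_equal(max(inst), 2)
  expect_true(all((inst > 0) == mask))   # no pixel loss
  # split line close to the geometric chord at col 70
  lab_left <- inst[40, 50]
  boundary_cols <- range(which(colSums(inst == lab_left) > 0))
  expect_lt(abs(boundary_cols[2] - 70), 4)
})

test_that("single-core component stays whole; coreless components survive", {
  m <- disk_mask(50, 50, 25, 25, 18)
  g <- matrix(0.7, 50, 50); g[disk_mask(50, 50, 25, 25, 6)] <- 0.2
  inst <- split_touching(m, g, detect_cores(g, m))
  expect_equal(max(inst), 1)
  expect_true(all((inst == 1) == m))
  # no cores at all: whole component = one instance
  inst2 <- split_touching(m, matrix(0.7, 50, 50),
                          matrix(FALSE, 50, 50))
  expect_equal(max(inst2), 1)
  expect_true(all((inst2 == 1) == m))
})

test_that("a small pellet attached to a large one is recovered intact", {
  # 1000 um and 250 um pellets at 5 um/px: radii 100 and 25 px
  h <- 320; w <- 320
  big <- disk_mask(h, w, 160, 140, 100)
  small <- disk_mask(h, w, 160, 262, 25)
  mask <- big | small
  g <- matrix(0.8, h, w)
  g[disk_mask(h, w, 160, 140, 30)] <- 0.2
  g[disk_mask(h, w, 160, 262, 12)] <- 0.2
  cores <- detect_cores(g, mask)
  inst <- split_touching(mask, g, cores)
  expect_equal(max(inst), 2)
  lab_big <- inst[160, 140]; lab_small <- inst[160, 262]
  expect_false(lab_big == lab_small)
  # the large pellet is not fragmented: its instance covers almost all of it
  expect_gt(sum(inst == lab_big & big) / sum(big), 0.95)
  expect_gt(sum(inst == lab_small & small) / sum(small), 0.85)
})

test_that("instance count equals core-component count on random phantoms", {
  set.seed(21)
  for (rep in 1:8) {
    h <- 90; w <- 90
    n <- sample(1:3, 1)
    centres <- cbind(runif(n, 25, 65), runif(n, 25, 65))
    mask <- matrix(FALSE, h, w)
    g <- matrix(0.8, h, w)
    for (i in seq_len(n)) {
      mask <- mask | disk_mask(h, w, centres[i, 1], centres[i, 2], 16)
      g[disk_mask(h, w, centres[i, 1], centres[i, 2], 5)] <- 0.2
    }
    cores <- detect_cores(g, mask)
    ncore <- max(EBImage::bwlabel(EBImage::Image(cores * 1)))
    inst <- split_touching(mask, g, cores)
    expect_equal(max(inst), ncore)
    expect_true(all((inst > 0) == mask))
  }
})
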