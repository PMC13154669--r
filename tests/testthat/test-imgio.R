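test_that("calibrated images validate their invariants", {
  px <- array(128, c(10, 12, 3))
  img <- calibrated_image(px, 10, "x")
  expect_equal(dim(img), c(10L, 12L))
  expect_error(calibrated_image(array(0, c(5, 5, 2)), 10), "3")
  expect_error(calibrated_image(px, -1), "positive")
  expect_error(calibrated_image(array(300, c(5, 5, 3)), 10), "255")
})

test_that("save/load round-trips are pixel-identical for PNG and TIFF", {
  set.seed(4)
  px <- array(sample(0:255, 40 * 40 * 3, replace = TRUE), c(40, 40, 3))
  img <- calibrated_image(px, 10, "rt")
  for (ext in c("png", "tif")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    save_image(img, path)
    back <- load_image(path, 10)
    expect_identical(back$pixels, img$pixels)
    expect_equal(back$pixel_size, 10)
  }
})

test_that("non-RGB input is rejected with a format error", {
  path <- withr::local_tempfile(fileext = ".png")
  EBImage::writeImage(EBImage::Image(matrix(runif(100), 10, 10)), path,
                      bits.per.sample = 8L)
  expect_error(load_image(path, 10), "not RGB")
  expect_error(load_image("/nonexistent/file.png", 10), "exist")
})

test_that("pellet tables are deterministic with units in the header", {
  recs <- tibble::tibble(
    image = c("b", "a", "a"), label = c(1L, 2L, 1L),
    class = c("AN_pellet", "SC_pellet", "SC_pellet"),
    area_mm2 = c(0.5, 0.01, 0.02),
    equiv_diameter_um = c(800, 110, 160),
    perimeter_um = c(2500, 350, 500), circularity = c(1, 0.9, 0.95),
    solidity = c(0.99, 0.97, 0.96), aspect_ratio = c(1, 1.1, 1.2),
    core_count = c(1L, 1L, 1L), core_area_fraction = c(0.1, 0.4, 0.5),
    mean_gray = c(0.4, 0.2, 0.25), border_contact = c(FALSE, FALSE, TRUE)
  )
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_pellet_table(recs, p1)
  write_pellet_table(recs, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  lines <- readLines(p1)
  expect_length(lines, 4)  # header + 3 rows
  expect_match(lines[1], "equiv_diameter_um")
  # deterministic order: image then label
  expect_match(lines[2], "^\"a\",1")
  p3 <- withr::local_tempfile(fileext = ".csv")
  write_pellet_table(recs[0, ], p3)
  expect_length(readLines(p3), 1)
})

test_that("overlays tint instances by class and leave the rest unchanged", {
  img <- phantom_image(h = 60, w = 60)
  lab <- matrix(0L, 60, 60)
  lab[disk_mask(60, 60, 30, 30, 10)] <- 1L
  ov <- render_overlay(img, lab, "AN_pellet")
  sel <- lab == 1L
  expect_identical(ov$pixels[, , 1][!sel], img$pixels[, , 1][!sel])
  # red tint raises the red channel over the dark pellet region
  expect_true(all(ov$pixels[, , 1][sel] > img$pixels[, , 1][sel]))

  ov0 <- render_overlay(img, matrix(0L, 60, 60), character())
  expect_identical(ov0$pixels, img$pixels)

  lab3 <- matrix(0L, 60, 60)
  lab3[disk_mask(60, 60, 15, 15, 6)] <- 1L
  lab3[disk_mask(60, 60, 15, 45, 6)] <- 2L
  lab3[disk_mask(60, 60, 45, 30, 6)] <- 3L
  ov3 <- render_overlay(img, lab3,
                        c("AN_pellet", "SC_pellet", "SC_aggregate"),
                        alpha = 1)
  tints <- unique(vapply(1:3, function(k) {
    i <- which(lab3 == k, arr.ind = TRUE)[1, ]
    paste(ov3$pixels[i[1], i[2], ], collapse = ",")
  }, character(1)))
  expect_length(tints, 3)
  expect_error(render_overlay(img, lab, "fungus"), "unknown class")
  expect_error(render_overlay(img, matrix(0L, 10, 10), character()),
               "aligned")
})

test_that("16-bit label masks round-trip", {
  lab <- matrix(0L, 30, 30)
  lab[5:10, 5:10] <- 1L
  lab[20:25, 20:28] <- 350L
  path <- withr::local_tempfile(fileext = ".tif")
  write_label_mask(lab, path)
  expect_identical(read_label_mask(path), lab + 0)
})

test_that("annotation sets validate labels and geometry dialects", {
  tbl <- tibble::tibble(label = 1:2, class = c("AN_pellet", "SC_pellet"),
                        row = c(5, 10), col = c(5, 10))
  a <- annotation_set(tbl)
  expect_s3_class(a, "annotation_set")
  expect_error(annotation_set(tibble::tibble(label = 1, class = "x",
                                             row = 1, col = 1)),
               "unknown class")
  lab <- matrix(0L, 20, 20); lab[3:6, 3:6] <- 1L
  expect_error(annotation_set(tibble::tibble(label = 2, class = "SC_pellet"),
                              label_mask = lab), "missing")
})
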