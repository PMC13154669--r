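# Small, fast generator configurations for testing (coarser pixels, small
# fields); the study-scale defaults are exercised in the acceptance suite.
fast_cfg <- function(...) {
  synth_config(width_px = 500, height_px = 500, pixel_size_um = 10,
               an_diameter_um = c(300, 600), ...)
}

test_that("identical configurations render bit-identical fields", {
  f1 <- generate_field(fast_cfg(seed = 5, n_an = 2, n_sc = 5, n_agg = 1))
  f2 <- generate_field(fast_cfg(seed = 5, n_an = 2, n_sc = 5, n_agg = 1))
  expect_identical(f1$image$pixels, f2$image$pixels)
  expect_identical(f1$truth$labels, f2$truth$labels)
  expect_identical(f1$truth$info, f2$truth$info)
  f3 <- generate_field(fast_cfg(seed = 6, n_an = 2, n_sc = 5, n_agg = 1))
  expect_false(identical(f1$image$pixels, f3$image$pixels))
})

test_that("ground truth bookkeeping matches the configured counts", {
  f <- generate_field(fast_cfg(seed = 2, n_an = 3, n_sc = 8, n_agg = 2))
  info <- f$truth$info
  expect_equal(nrow(info), 13)
  expect_equal(sum(info$class == "AN_pellet"), 3)
  expect_equal(sum(info$class == "SC_pellet"), 8)
  expect_equal(sum(info$class == "SC_aggregate"), 2)
  expect_setequal(setdiff(unique(as.integer(f$truth$labels)), 0L),
                  info$instance)
  # cores lie inside their instances
  expect_true(all(f$truth$labels[f$truth$cores] > 0))
})

test_that("aggregate truth diameters equal their rasterised areas", {
  f <- generate_field(fast_cfg(seed = 9, n_an = 0, n_sc = 0, n_agg = 3))
  info <- f$truth$info
  ps <- f$image$pixel_size
  for (i in info$instance) {
    area_px <- sum(f$truth$labels == i)
    expect_equal(info$diameter_um[info$instance == i],
                 2 * sqrt(area_px * ps^2 / pi), tolerance = 1e-9)
  }
})

test_that("sampled diameters respect the configured ranges", {
  rng <- c(300, 600)
  ds <- unlist(lapply(1:40, function(s) {
    f <- generate_field(fast_cfg(seed = s, n_an = 5, n_sc = 0, n_agg = 0))
    f$truth$info$diameter_um
  }))
  expect_length(ds, 200)
  expect_true(all(ds >= rng[1] & ds <= rng[2]))
  # empirical mean within 3 standard errors of the uniform midpoint
  se <- diff(rng) / sqrt(12) / sqrt(length(ds))
  expect_lt(abs(mean(ds) - mean(rng)), 3 * se)
})

test_that("bacterial sizes follow the configured uniform distribution", {
  ds <- unlist(lapply(1:9, function(s) {
    f <- generate_field(synth_config(width_px = 1100, height_px = 1100,
                                     pixel_size_um = 5, seed = 100 + s,
                                     n_an = 0, n_sc = 60, n_agg = 0))
    f$truth$info$diameter_um
  }))
  expect_gte(length(ds), 500)
  rng <- synth_config()$sc_diameter_um
  ks <- suppressWarnings(ks.test(ds, "punif", rng[1], rng[2]))
  expect_gt(ks$p.value, 0.01)
})

test_that("a diameter schedule scales the generated sizes", {
  series <- generate_series(fast_cfg(seed = 3, n_an = 4, n_sc = 0,
                                     n_agg = 0),
                            schedule = c(1, 1.5))
  m1 <- mean(series[[1]]$truth$info$diameter_um)
  m2 <- mean(series[[2]]$truth$info$diameter_um)
  expect_equal(m2 / m1, 1.5, tolerance = 0.05)  # paired population, scaled

  single <- generate_series(fast_cfg(seed = 3, n_an = 4, n_sc = 0,
                                     n_agg = 0), schedule = 1)
  direct <- generate_field(fast_cfg(seed = 3, n_an = 4, n_sc = 0,
                                    n_agg = 0))
  expect_identical(single[[1]]$image$pixels, direct$image$pixels)

  again <- generate_series(fast_cfg(seed = 3, n_an = 4, n_sc = 0,
                                    n_agg = 0), schedule = c(1, 1.5))
  expect_identical(again[[2]]$image$pixels, series[[2]]$image$pixels)
  expect_error(generate_series(fast_cfg(), schedule = c(2, 1)),
               "non-decreasing")
})

test_that("impossible packings raise a placement error", {
  expect_error(
    generate_field(synth_config(width_px = 300, height_px = 300,
                                pixel_size_um = 5, n_an = 10, n_sc = 0,
                                n_agg = 0, seed = 1)),
    "placement")
})

test_that("fields round-trip to disk", {
  f <- generate_field(fast_cfg(seed = 4, n_an = 1, n_sc = 3, n_agg = 0))
  img <- withr::local_tempfile(fileext = ".png")
  lab <- withr::local_tempfile(fileext = ".tif")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_field(f, img, lab, csv)
  expect_identical(load_image(img, 10)$pixels, f$image$pixels)
  expect_identical(read_label_mask(lab), f$truth$labels + 0)
  expect_equal(nrow(read.csv(csv)), nrow(f$truth$info))
})
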