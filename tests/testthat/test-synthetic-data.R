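test_that("bead phantoms are seeded, two-valued without noise, and match their spec", {
  cfg <- tiny_phantom_config(64, noise_sigma = 0)
  p1 <- make_bead_phantom(cfg, seed = 12)
  p2 <- make_bead_phantom(cfg, seed = 12)
  expect_identical(p1$image, p2$image)
  expect_identical(as.data.frame(p1$spec), as.data.frame(p2$spec))
  # objects 25, field-of-view background 1, outside the scanner circle 0
  expect_setequal(unique(as.numeric(p1$image)), c(0, 1, 25))
  # the returned spec rasterized at its densities reproduces the support
  re <- rasterize_shapes(p1$spec, 64, density_mode = "fixed")
  expect_identical(re == 25, p1$image == 25)
  expect_identical(re[re == 25], p1$image[p1$image == 25])

  noisy <- make_bead_phantom(tiny_phantom_config(64, noise_sigma = 0.5),
                             seed = 12)
  expect_gt(length(unique(as.numeric(noisy$image))), 2)
  expect_true(all(noisy$image >= 0))
})

test_that("impossible packings fail with a diagnostic", {
  cfg <- phantom_config(image_size = 32, n_circles_range = c(8, 8),
                        radius_range = c(10, 12), margin = 1)
  expect_error(make_bead_phantom(cfg, seed = 1), "non-overlapping circles")
})

test_that("defects subtract exactly their pixel count and stay inside objects", {
  cfg <- tiny_phantom_config(64, noise_sigma = 0, defect = "holes",
                             defect_radius_range = c(1.5, 2.5),
                             defects_per_object_range = c(1, 2))
  ph <- make_bead_phantom(cfg, seed = 33)
  def <- add_defects(ph$image, ph$spec, cfg, seed = 34)
  changed <- which(def$image != ph$image, arr.ind = TRUE)
  expect_gt(nrow(changed), 0)
  expect_equal(sum(ph$image) - sum(def$image), 24 * nrow(changed))
  # geometric containment: every changed pixel lies inside a parent circle
  x <- changed[, 2] - 1; y <- changed[, 1] - 1
  inside_parent <- rep(FALSE, nrow(changed))
  for (i in seq_len(nrow(ph$spec)))
    inside_parent <- inside_parent |
      ((x - ph$spec$cx[i])^2 + (y - ph$spec$cy[i])^2 <= ph$spec$r[i]^2)
  expect_true(all(inside_parent))
  # hole locations are reported but never added to the object spec
  expect_gt(nrow(def$holes), 0)
  expect_equal(nrow(ph$spec), nrow(make_bead_phantom(cfg, seed = 33)$spec))

  cfg0 <- tiny_phantom_config(64, noise_sigma = 0, defect = "holes",
                              defects_per_object_range = c(0, 0),
                              defect_radius_range = c(1, 1.5))
  def0 <- add_defects(ph$image, ph$spec, cfg0, seed = 1)
  expect_identical(def0$image, ph$image)

  cfg_big <- tiny_phantom_config(64, defect = "holes",
                                 defect_radius_range = c(50, 60))
  expect_error(add_defects(ph$image, ph$spec, cfg_big, seed = 1),
               "not smaller")
})

test_that("datasets are reproducible and internally consistent", {
  g <- scan_geometry(32, 32)
  d1 <- build_dataset(10, g, missing_fractions = 0.5,
                      config = tiny_phantom_config(32), seed = 77)
  d2 <- build_dataset(10, g, missing_fractions = 0.5,
                      config = tiny_phantom_config(32), seed = 77)
  expect_identical(serialize(d1$records, NULL), serialize(d2$records, NULL))
  expect_equal(length(d1$records), 10)
  expect_equal(d1$split$train, 1:9)
  expect_equal(d1$split$test, 10L)
  for (rec in d1$records) {
    expect_equal(rec$mask$n_missing, 16)
    m <- mask_matrix(rec$mask, 32)
    expect_identical(unclass(rec$masked), unclass(rec$sinogram) * (1 - m))
    expect_equal(rowSums(abs(unclass(rec$masked)[!rec$mask$observed, ])),
                 rep(0, 16))
    # prior blindness: the prior spec carries no densities
    expect_true(all(is.na(rec$prior_spec$density)))
  }
})

test_that("the known-density no-defect prior reproduces the target sinogram", {
  g <- scan_geometry(32, 32)
  cfg <- tiny_phantom_config(32, noise_sigma = 0)
  ph <- make_bead_phantom(cfg, seed = 55)
  target <- forward_project(ph$image, g)
  # prior in the known-density limit, with the field-of-view background
  re_img <- rasterize_shapes(ph$spec, 32, density_mode = "fixed")
  re_img[re_img == 0 & disc_image(32, 31 / 2) > 0] <- 1
  re <- forward_project(re_img, g)
  expect_gt(psnr(unclass(re), unclass(target)), 40)
  # without the background shell the prior is close but imperfect
  prior <- encode_prior(ph$spec, g, image_size = 32, density_mode = "fixed")
  expect_gt(psnr(unclass(prior), unclass(target)), 15)
})

test_that("datasets round-trip through disk with a manifest", {
  ds <- tiny_dataset()
  path <- withr::local_tempfile(fileext = ".rds")
  save_dataset(ds, path)
  expect_true(file.exists(paste0(path, ".manifest.json")))
  man <- jsonlite::read_json(paste0(path, ".manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$n_slices, 12)
  expect_equal(man$test, ds$split$test)
  back <- load_dataset(path)
  expect_identical(serialize(back$records, NULL), serialize(ds$records, NULL))
})

test_that("withheld circles drop out of the prior but stay in the phantom", {
  g <- scan_geometry(32, 32)
  cfg <- tiny_phantom_config(32, withhold_fraction = 0.5)
  ds <- build_dataset(4, g, missing_fractions = 0.3, config = cfg, seed = 91)
  for (rec in ds$records) {
    expect_lt(nrow(rec$prior_spec), nrow(rec$spec) + 1)
    if (nrow(rec$spec) >= 2)
      expect_lt(nrow(rec$prior_spec), nrow(rec$spec))
  }
})
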