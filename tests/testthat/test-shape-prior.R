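test_that("rasterization fills circles with the requested densities", {
  expect_equal(rasterize_shapes(shape_spec(), 16), matrix(0, 16, 16))

  spec <- shape_spec(cx = 20, cy = 20, r = 10, density = 2)
  img <- rasterize_shapes(spec, 41)
  n_px <- sum(img > 0)
  expect_equal(sum(img), 2 * n_px)  # oracle: rasterized pixel count
  # pixel count within the +-1 px boundary band of the analytic area
  expect_gt(n_px, pi * 9^2)
  expect_lt(n_px, pi * 11^2)

  expect_error(rasterize_shapes(shape_spec(cx = 100, cy = 100, r = 3), 16),
               "outside the image")
})

test_that("random densities are seeded and reproducible", {
  spec <- shape_spec(cx = c(10, 25), cy = c(12, 20), r = c(5, 6))
  a <- rasterize_shapes(spec, 40, density_mode = "random", seed = 3)
  b <- rasterize_shapes(spec, 40, density_mode = "random", seed = 3)
  c <- rasterize_shapes(spec, 40, density_mode = "random", seed = 4)
  expect_identical(a, b)
  expect_false(identical(a, c))
  expect_error(rasterize_shapes(spec, 40, density_mode = "fixed"),
               "NA densities")
})

test_that("shape specs round-trip through JSON", {
  spec <- shape_spec(cx = c(10.5, 25), cy = c(12, 20.25), r = c(5, 6.5),
                     density = c(25, NA))
  path <- withr::local_tempfile(fileext = ".json")
  write_shape_spec(spec, path)
  back <- read_shape_spec(path)
  expect_equal(as.data.frame(back), as.data.frame(spec))
})

test_that("circle detection recovers non-overlapping discs within 2 px", {
  spec <- shape_spec(cx = c(60, 160, 200, 90, 180),
                     cy = c(70, 60, 180, 190, 120),
                     r = c(20, 14, 17, 10, 8), density = rep(25, 5))
  img <- rasterize_shapes(spec, 256, background = 1)
  det <- find_circles(img, radius_range = c(6, 24))
  expect_equal(nrow(det), 5)
  for (i in seq_len(5)) {
    j <- which.min((det$cx - spec$cx[i])^2 + (det$cy - spec$cy[i])^2)
    expect_lt(abs(det$cx[j] - spec$cx[i]), 2)
    expect_lt(abs(det$cy[j] - spec$cy[i]), 2)
    expect_lt(abs(det$r[j] - spec$r[i]), 2)
  }
})

test_that("a border-touching disc may drop but interior discs survive", {
  img <- matrix(1, 128, 128)
  xs <- matrix(rep(0:127, each = 128), 128, 128)
  ys <- matrix(rep(0:127, times = 128), 128, 128)
  img[(xs - 1)^2 + (ys - 64)^2 <= 100] <- 25    # half outside
  img[(xs - 64)^2 + (ys - 64)^2 <= 400] <- 25   # interior, r = 20
  det <- find_circles(img, radius_range = c(6, 24))
  d_int <- sqrt((det$cx - 64)^2 + (det$cy - 64)^2)
  expect_true(any(d_int < 2 & abs(det$r - 20) < 2))
})

test_that("blank images give an empty detection", {
  expect_equal(nrow(find_circles(matrix(0, 64, 64), c(4, 10))), 0)
})

test_that("detection round-trips rasterization for discs >= 5 px", {
  set.seed(88)
  spec <- shape_spec(cx = c(25, 70, 100, 45), cy = c(30, 40, 100, 90),
                     r = c(9, 12, 15, 6), density = rep(25, 4))
  img <- rasterize_shapes(spec, 128, background = 1)
  det <- find_circles(img, radius_range = c(4, 18))
  expect_equal(nrow(det), nrow(spec))
  for (i in seq_len(nrow(spec))) {
    j <- which.min((det$cx - spec$cx[i])^2 + (det$cy - spec$cy[i])^2)
    expect_lt(max(abs(c(det$cx[j] - spec$cx[i], det$cy[j] - spec$cy[i],
                        det$r[j] - spec$r[i]))), 2)
  }
})

test_that("prior encoding projects the rasterized spec", {
  g <- scan_geometry(32, 32)
  expect_true(all(unclass(encode_prior(shape_spec(), g)) == 0))

  spec <- shape_spec(cx = 15.5, cy = 15.5, r = 9, density = 25)
  img <- rasterize_shapes(spec, 32)
  prior <- encode_prior(spec, g, density_mode = "fixed")
  expect_equal(vals(prior), vals(forward_project(img, g)),
               tolerance = 1e-12)
  expect_false(isTRUE(attr(prior, "scaled")))

  spec_na <- shape_spec(cx = 15.5, cy = 15.5, r = 9)
  p1 <- encode_prior(spec_na, g, seed = 5)
  p2 <- encode_prior(spec_na, g, seed = 5)
  expect_identical(unclass(p1), unclass(p2))
})

test_that("prior rows rescale to the observed total attenuation", {
  g <- scan_geometry(32, 32)
  img <- disc_image(32, 9, 25)
  sino <- forward_project(img, g)
  mask <- angular_mask(32, 0.5, 0)
  masked <- apply_mask(sino, mask)
  prior <- forward_project(disc_image(32, 9, 13), g)  # wrong density
  scaled <- scale_prior_columns(prior, masked, mask)
  t_ref <- attr(scaled, "t_ref")
  expect_equal(t_ref, mean(total_attenuation_profile(sino)[mask$observed]))
  expect_true(isTRUE(attr(scaled, "scaled")))
  expect_equal(total_attenuation_profile(scaled), rep(t_ref, 32),
               tolerance = 1e-12)
  # a row with sum 50 scaled to t_ref 100 doubles
  g3 <- scan_geometry(2, 2)
  pr <- as_sinogram(matrix(c(20, 50, 30, 0), 2, 2), g3)  # row sums 50, 50
  ms <- as_sinogram(matrix(c(60, 70, 40, 30), 2, 2), g3) # row sums 100 each
  m_all <- suppressWarnings(angular_mask(2, 0, 0))
  doubled <- scale_prior_columns(pr, ms, m_all)
  expect_equal(vals(doubled), 2 * vals(pr))
})

test_that("prior scaling handles degenerate rows and inputs", {
  g <- scan_geometry(16, 16)
  img <- disc_image(16, 4, 10)
  sino <- forward_project(img, g)
  mask <- suppressWarnings(angular_mask(16, 0, 0))
  # identical prior under full observation is a fixed point up to the
  # quadrature variation of the per-angle totals
  same <- scale_prior_columns(sino, sino, mask)
  expect_equal(vals(same), vals(sino), tolerance = 0.01)
  # an all-zero prior row stays zero without division errors
  pr <- unclass(sino); pr[3, ] <- 0
  scaled <- scale_prior_columns(as_sinogram(pr, g), sino, mask)
  expect_true(all(unclass(scaled)[3, ] == 0))
  # no observed angles / zero observed sums are rejected
  m_none <- suppressWarnings(angular_mask(16, 0.99, 0))
  m_none$observed[] <- FALSE
  m_none$n_missing <- 16L
  expect_error(scale_prior_columns(sino, sino, m_none), "no observed")
  zero <- as_sinogram(matrix(0, 16, 16), g)
  expect_error(scale_prior_columns(sino, zero, mask), "zero total")
})
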