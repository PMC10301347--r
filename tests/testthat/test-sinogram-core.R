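test_that("forward projection of the zero image is the zero sinogram", {
  g <- scan_geometry(256, 256)
  s <- forward_project(matrix(0, 256, 256), g)
  expect_equal(dim(s), c(256, 256))
  expect_true(all(unclass(s) == 0))
})

test_that("projection of a centred disc conserves mass at every angle", {
  g <- scan_geometry(256, 256)
  img <- disc_image(256, radius = 32, value = 25)
  s <- forward_project(img, g)
  prof <- total_attenuation_profile(s)
  # oracle: the pixel sum of the rasterized disc
  expect_true(all(abs(prof - sum(img)) / sum(img) < 0.01))
  # and the analytic disc mass to within rasterization error
  expect_true(all(abs(prof - 25 * pi * 32^2) / (25 * pi * 32^2) < 0.015))
  expect_lt(max(prof) / min(prof), 1.01)
})

test_that("a centred disc projects identically at every angle", {
  g <- scan_geometry(64, 64)
  s <- unclass(forward_project(disc_image(64, radius = 16, value = 25), g))
  dev <- sweep(s, 2, colMeans(s))
  expect_lt(max(abs(dev)), 0.05 * max(s))
})

test_that("the projector is linear", {
  g <- scan_geometry(20, 24)
  set.seed(31)
  f1 <- matrix(runif(24^2), 24, 24)
  f2 <- matrix(runif(24^2), 24, 24)
  lhs <- unclass(forward_project(2.5 * f1 - 1.25 * f2, g))
  rhs <- 2.5 * unclass(forward_project(f1, g)) -
    1.25 * unclass(forward_project(f2, g))
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("back_project is the exact adjoint of forward_project", {
  set.seed(17)
  for (sz in c(16, 31)) {
    g <- scan_geometry(sz - 2, sz + 3)
    f <- matrix(runif(sz^2), sz, sz)
    y <- matrix(runif(g$n_angles * g$n_detectors), g$n_angles, g$n_detectors)
    lhs <- sum(unclass(forward_project(f, g)) * y)
    rhs <- sum(f * back_project(as_sinogram(y, g), sz))
    expect_lt(abs(lhs - rhs) / abs(lhs), 1e-6)
  }
})

test_that("invalid images are rejected", {
  g <- scan_geometry(8, 8)
  expect_error(forward_project(matrix(0, 8, 9), g), "square")
  expect_error(forward_project(matrix(NA_real_, 8, 8), g), "finite")
})

test_that("angular masks are one contiguous block of the right length", {
  m <- angular_mask(256, 0.5, start_index = 0)
  expect_identical(which(!m$observed), 1:128)
  expect_identical(which(m$observed), 129:256)

  m2 <- suppressWarnings(angular_mask(360, 1 / 6, start_index = 0))
  expect_equal(m2$n_missing, 60)
  runs <- rle(m2$observed)
  expect_equal(sum(!m2$observed), 60)
  expect_equal(sum(!runs$values), 1)  # exactly one missing run

  expect_warning(m3 <- angular_mask(256, 0, start_index = 0), "operating range")
  expect_true(all(m3$observed))

  expect_error(angular_mask(256, 1), "\\[0, 1\\)")
  expect_error(angular_mask(256, -0.1), "\\[0, 1\\)")
})

test_that("random mask starts are seeded and reproducible", {
  m1 <- angular_mask(128, 0.25, seed = 7)
  m2 <- angular_mask(128, 0.25, seed = 7)
  m3 <- angular_mask(128, 0.25, seed = 8)
  expect_identical(m1$start_index, m2$start_index)
  expect_false(m1$start_index == m3$start_index &&
                 identical(m1$observed, m3$observed))
})

test_that("mask_from_degrees maps wedges on the half turn to angle counts", {
  expect_equal(mask_from_degrees(256, 30)$n_missing, round(256 * 30 / 180))
  expect_equal(mask_from_degrees(256, 90)$n_missing, 128)
})

test_that("apply_mask zeroes missing rows exactly and leaves the rest alone", {
  g <- scan_geometry(32, 16)
  set.seed(5)
  s <- as_sinogram(matrix(runif(32 * 16), 32, 16), g)
  m0 <- suppressWarnings(angular_mask(32, 0, 0))
  expect_identical(unclass(apply_mask(s, m0)), unclass(s))

  m <- angular_mask(32, 0.5, 3)
  sm <- apply_mask(s, m)
  expect_equal(sum(rowSums(abs(unclass(sm))) == 0), 16)
  expect_identical(unclass(sm)[m$observed, ], unclass(s)[m$observed, ])
  expect_identical(unclass(apply_mask(sm, m)), unclass(sm))  # idempotent

  g2 <- scan_geometry(16, 16)
  s2 <- as_sinogram(matrix(0, 16, 16), g2)
  expect_error(apply_mask(s2, m), "does not match")
})

test_that("per-angle totals behave as row sums", {
  g <- scan_geometry(4, 3)
  expect_equal(total_attenuation_profile(as_sinogram(matrix(0, 4, 3), g)),
               rep(0, 4))
  expect_equal(total_attenuation_profile(matrix(c(1, 2, 3), 1, 3)), 6)
})

test_that("support outside the field of view is flagged", {
  img <- matrix(0, 32, 32)
  img[1, 1] <- 5  # corner, outside the inscribed circle
  expect_warning(validate_support(img), "inscribed circle")
  expect_silent(validate_support(disc_image(32, 10, 1)))
})
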