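# Shared fixtures, built in code and cached for the test run.

.fixtures <- new.env()

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures, inherits = FALSE)
}

# sinogram values stripped of class/geometry attributes, for comparisons
vals <- function(s) {
  v <- unclass(s)
  array(as.numeric(v), dim(v))
}

# desk-scale phantom settings for a given slice size
tiny_phantom_config <- function(size, ...) {
  phantom_config(image_size = size, n_circles_range = c(2, 4),
                 radius_range = c(max(2, size / 16), max(3, size / 8)),
                 margin = 1, ...)
}

# 12-slice 32x32 dataset used across module tests
tiny_dataset <- function() {
  fixture("tiny_dataset", function() {
    build_dataset(12, scan_geometry(32, 32), missing_fractions = 0.3,
                  config = tiny_phantom_config(32), seed = 400)
  })
}

# like tiny_dataset but with an air background, the condition under which
# the shape prior accounts for (nearly) all attenuating mass
air_dataset <- function() {
  fixture("air_dataset", function() {
    build_dataset(12, scan_geometry(32, 32), missing_fractions = 0.3,
                  config = tiny_phantom_config(32,
                                               background_attenuation = 0),
                  seed = 410)
  })
}

# brute-force oracle for periodic linear interpolation: build the explicit
# 360-degree flipped extension, interpolate every bin, fold back
linear_inpaint_oracle <- function(v, mask) {
  na <- nrow(v); nd <- ncol(v)
  E <- rbind(v, v[, nd:1, drop = FALSE])
  s0 <- mask$start_index
  len <- mask$n_missing
  li <- (s0 - 1) %% (2 * na)
  ri <- (s0 + len) %% (2 * na)
  out <- v
  for (k in seq_len(len)) {
    e <- s0 + k - 1
    w <- k / (len + 1)
    val <- (1 - w) * E[li + 1, ] + w * E[ri + 1, ]
    if (e >= na) out[e - na + 1, ] <- rev(val) else out[e + 1, ] <- val
  }
  out
}

# dense projector matrix for small geometries (column = projection of a
# pixel basis image), the oracle for adjoint/SIRT checks
dense_projector <- function(geometry, image_size) {
  A <- matrix(0, geometry$n_angles * geometry$n_detectors,
              image_size * image_size)
  for (i in seq_len(image_size * image_size)) {
    e <- matrix(0, image_size, image_size)
    e[i] <- 1
    A[, i] <- as.numeric(unclass(forward_project(e, geometry)))
  }
  A
}
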