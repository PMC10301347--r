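#' Forward project an image into a sinogram
#'
#' Discretizes the parallel-beam Radon transform
#' \deqn{R(\theta, r) = \int\int f(x, y)\,\delta(x\cos\theta + y\sin\theta - r)\,dx\,dy}
#' by ray-driven sampling: for each (angle, detector) pair the ray is walked
#' with unit step and the image is sampled with bilinear interpolation. The
#' operator is linear in the image and has an exact adjoint
#' ([back_project()]), which iterative reconstruction relies on.
#'
#' @param image Square numeric matrix of non-negative attenuation values.
#' @param geometry A [scan_geometry()].
#' @return A [as_sinogram()] object, `n_angles x n_detectors`.
#' @examples
#' g <- scan_geometry(64, 64)
#' img <- disc_image(64, radius = 16, value = 25)
#' s <- forward_project(img, g)
#' @export
forward_project <- function(image, geometry) {
  check_image(image)
  stopifnot(is_scan_geometry(geometry))
  v <- cpp_radon_forward(image, geometry$angles, geometry$n_detectors)
  as_sinogram(v, geometry)
}

#' Adjoint of the forward projector (unfiltered backprojection)
#'
#' Scatters sinogram values back along the sampling rays with the same
#' bilinear weights used by [forward_project()], so that
#' `sum(forward_project(f) * y) == sum(f * back_project(y))` up to float
#' rounding. This is the smearing operator `A^T`, not a reconstruction;
#' see [fbp_reconstruct()] and [sirt_reconstruct()] for those.
#'
#' @param sino A sinogram.
#' @param image_size Side length of the output image (defaults to
#'   `n_detectors`).
#' @return Square numeric matrix `image_size x image_size`.
#' @export
back_project <- function(sino, image_size = NULL) {
  g <- sino_geometry(sino)
  if (is.null(image_size)) image_size <- g$n_detectors
  cpp_radon_adjoint(unclass(sino), g$angles, image_size, image_size)
}

#' Per-angle total attenuation
#'
#' Sums each sinogram row over detector bins. For an object fully inside
#' the field of view this profile is constant in angle (conservation of
#' total attenuation), which is what [scale_prior_columns()] exploits.
#'
#' @param sino A sinogram (or plain matrix with angles in rows).
#' @return Numeric vector of length `n_angles`.
#' @export
total_attenuation_profile <- function(sino) {
  rowSums(unclass(sino))
}

#' Uniform disc test image
#'
#' Convenience constructor for a centred (or offset) disc phantom, used
#' throughout the examples and tests.
#'
#' @param size Image side length in pixels.
#' @param radius Disc radius in pixels.
#' @param value Attenuation inside the disc.
#' @param center Optional `c(cx, cy)` in 0-based pixel coordinates
#'   (defaults to the image centre).
#' @param background Attenuation outside the disc.
#' @return `size x size` numeric matrix.
#' @export
disc_image <- function(size, radius, value = 1, center = NULL, background = 0) {
  if (is.null(center)) center <- c((size - 1) / 2, (size - 1) / 2)
  xs <- matrix(rep(0:(size - 1), each = size), size, size)  # column index
  ys <- matrix(rep(0:(size - 1), times = size), size, size) # row index
  img <- matrix(background, size, size)
  img[(xs - center[1])^2 + (ys - center[2])^2 <= radius^2] <- value
  img
}
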