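#' Encode a shape prior in the sinogram domain
#'
#' Rasterizes the circle specification (assigning random densities to
#' circles whose attenuation is unknown) and forward-projects it, producing
#' the prior channel that conditions the inpainting methods. The result is
#' unscaled; see [scale_prior_columns()] for the per-angle total-attenuation
#' rescaling.
#'
#' @param spec A [shape_spec()].
#' @param geometry A [scan_geometry()].
#' @param image_size Side length used for rasterization (defaults to
#'   `n_detectors`).
#' @param density_mode,density_range,seed Passed to [rasterize_shapes()].
#' @return A sinogram with attribute `scaled = FALSE`.
#' @export
encode_prior <- function(spec, geometry, image_size = NULL,
                         density_mode = "random",
                         density_range = c(12.5, 37.5), seed = NULL) {
  stopifnot(is_scan_geometry(geometry))
  if (is.null(image_size)) image_size <- geometry$n_detectors
  img <- rasterize_shapes(spec, image_size, density_mode = density_mode,
                          density_range = density_range, seed = seed)
  out <- forward_project(img, geometry)
  attr(out, "scaled") <- FALSE
  out
}

#' Rescale prior rows to the measured total attenuation
#'
#' For a fully-visible object the per-angle total attenuation
#' `sum_r R(theta, r)` is a constant `T_ref`. The prior sinogram generally
#' has the wrong total (its densities are guessed), so each of its rows is
#' multiplied by `T_ref / rowsum`, where `T_ref` is the mean per-angle sum
#' of the measured sinogram over the *observed* angles. Rows whose prior
#' sum is zero are left at zero.
#'
#' @param prior Prior sinogram (from [encode_prior()]).
#' @param measured Measured (possibly masked) sinogram.
#' @param mask An [angular_mask()] marking which angles of `measured` are
#'   observed.
#' @return A sinogram with attribute `scaled = TRUE`; every nonzero row
#'   sums exactly to `T_ref`.
#' @export
scale_prior_columns <- function(prior, measured, mask) {
  g <- sino_geometry(prior)
  gm <- sino_geometry(measured)
  stopifnot(inherits(mask, "angular_mask"))
  if (g$n_angles != gm$n_angles || g$n_detectors != gm$n_detectors)
    stop("prior and measured sinogram shapes differ")
  if (length(mask$observed) != g$n_angles)
    stop("mask length does not match n_angles")
  if (!any(mask$observed))
    stop("cannot scale prior: no observed angles")
  obs_sums <- total_attenuation_profile(measured)[mask$observed]
  if (all(obs_sums == 0))
    stop("cannot scale prior: all observed angles have zero total attenuation")
  t_ref <- mean(obs_sums)
  row_sums <- total_attenuation_profile(prior)
  scale <- ifelse(row_sums == 0, 0, t_ref / row_sums)
  out <- unclass(prior) * scale
  # enforce the exact row-sum contract (guards against accumulated rounding)
  nz <- row_sums != 0
  rs <- rowSums(out[nz, , drop = FALSE])
  out[nz, ] <- out[nz, , drop = FALSE] * (t_ref / rs)
  out <- as_sinogram(out, g)
  attr(out, "scaled") <- TRUE
  attr(out, "t_ref") <- t_ref
  out
}
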