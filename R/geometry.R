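#' Parallel-beam scan geometry
#'
#' Describes a half-turn parallel-beam acquisition: `n_angles` equally
#' spaced projection angles `theta_i = i * pi / n_angles` in `[0, pi)` and
#' `n_detectors` detector bins with unit spacing, offsets centred on 0.
#'
#' @param n_angles Positive integer, number of projection angles.
#' @param n_detectors Positive integer, number of detector bins.
#' @return An object of class `scan_geometry` with elements `n_angles`,
#'   `n_detectors`, `angles` (radians) and `detector_offsets` (pixels).
#' @examples
#' g <- scan_geometry(256, 256)
#' range(g$angles)
#' @export
scan_geometry <- function(n_angles, n_detectors) {
  stopifnot(length(n_angles) == 1, length(n_detectors) == 1,
            n_angles >= 1, n_detectors >= 1,
            n_angles == round(n_angles), n_detectors == round(n_detectors))
  structure(
    list(
      n_angles = as.integer(n_angles),
      n_detectors = as.integer(n_detectors),
      angles = (seq_len(n_angles) - 1) * pi / n_angles,
      detector_offsets = seq_len(n_detectors) - 1 - (n_detectors - 1) / 2
    ),
    class = "scan_geometry"
  )
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf("<scan_geometry> %d angles over [0, pi), %d detector bins\n",
              x$n_angles, x$n_detectors))
  invisible(x)
}

is_scan_geometry <- function(x) inherits(x, "scan_geometry")

check_image <- function(image) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("`image` must be a numeric matrix")
  if (nrow(image) != ncol(image))
    stop("`image` must be square (", nrow(image), " x ", ncol(image), ")")
  if (!all(is.finite(image)))
    stop("`image` contains non-finite values")
  invisible(image)
}

#' Construct a sinogram object
#'
#' A sinogram is an `n_angles x n_detectors` matrix of line integrals tied
#' to a [scan_geometry()]. Rows index projection angles, columns detector
#' bins.
#'
#' @param values Numeric matrix, `n_angles x n_detectors`.
#' @param geometry A [scan_geometry()].
#' @return A `sinogram` object (matrix with a `geometry` attribute).
#' @export
as_sinogram <- function(values, geometry) {
  stopifnot(is_scan_geometry(geometry))
  if (!is.matrix(values) || nrow(values) != geometry$n_angles ||
      ncol(values) != geometry$n_detectors)
    stop("sinogram shape does not match geometry (want ",
         geometry$n_angles, " x ", geometry$n_detectors, ")")
  if (!all(is.finite(values))) stop("sinogram contains non-finite values")
  structure(values, geometry = geometry, class = c("sinogram", "matrix"))
}

#' @export
print.sinogram <- function(x, ...) {
  g <- attr(x, "geometry")
  cat(sprintf("<sinogram> %d angles x %d detectors, range [%.3g, %.3g]\n",
              g$n_angles, g$n_detectors, min(x), max(x)))
  invisible(x)
}

sino_geometry <- function(sino) {
  g <- attr(sino, "geometry")
  if (is.null(g)) stop("not a sinogram: missing geometry attribute")
  g
}

#' Warn when phantom support approaches the image border
#'
#' Total attenuation per angle is only angle-independent when the whole
#' object stays inside the scanner field of view (the circle inscribed in
#' the detector span). This helper warns when pixels above a threshold lie
#' outside that circle, in which case per-angle sums will vary.
#'
#' @param image Square numeric matrix.
#' @param threshold Pixels strictly above this value count as support
#'   (default 0).
#' @return `TRUE` (invisibly) when the support is fully contained, `FALSE`
#'   with a warning otherwise.
#' @export
validate_support <- function(image, threshold = 0) {
  check_image(image)
  H <- nrow(image)
  ctr <- (H - 1) / 2
  idx <- which(image > threshold, arr.ind = TRUE)
  if (nrow(idx) == 0) return(invisible(TRUE))
  d2 <- (idx[, 1] - 1 - ctr)^2 + (idx[, 2] - 1 - ctr)^2
  ok <- all(d2 <= ((H - 1) / 2)^2)
  if (!ok)
    warning("phantom support extends outside the inscribed circle; ",
            "total attenuation will vary with angle")
  invisible(ok)
}
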