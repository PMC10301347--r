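#' Contiguous limited-angle mask
#'
#' Marks one contiguous block of `round(missing_fraction * n_angles)`
#' consecutive projection angles as missing, emulating an acquisition that
#' cannot cover part of the half turn. The block wraps around the angle
#' index if it runs past the end.
#'
#' @param n_angles Number of projection angles.
#' @param missing_fraction Fraction of angles missing. The usual operating
#'   range is `[0.05, 0.95]`; values outside it (but in `[0, 1)`) are
#'   allowed with a warning.
#' @param start_index 0-based index of the first missing angle. When `NULL`
#'   it is drawn uniformly (use `seed` for reproducibility).
#' @param seed Optional integer seed used only when `start_index` is `NULL`.
#' @return An `angular_mask`: list with `observed` (logical, length
#'   `n_angles`), `missing_fraction`, `start_index`, `n_missing`.
#' @examples
#' m <- angular_mask(256, 0.5, start_index = 0)
#' sum(!m$observed)  # 128
#' @export
angular_mask <- function(n_angles, missing_fraction, start_index = NULL,
                         seed = NULL) {
  stopifnot(n_angles >= 1)
  if (missing_fraction < 0 || missing_fraction >= 1)
    stop("`missing_fraction` must be in [0, 1)")
  if (missing_fraction < 0.05 || missing_fraction > 0.95)
    warning("missing_fraction ", missing_fraction,
            " is outside the usual [0.05, 0.95] operating range")
  n_missing <- round(missing_fraction * n_angles)
  if (is.null(start_index))
    start_index <- with_seed(seed, sample.int(n_angles, 1) - 1L)
  start_index <- as.integer(start_index) %% n_angles
  observed <- rep(TRUE, n_angles)
  if (n_missing > 0) {
    idx <- (start_index + seq_len(n_missing) - 1L) %% n_angles
    observed[idx + 1L] <- FALSE
  }
  structure(
    list(observed = observed, missing_fraction = missing_fraction,
         start_index = start_index, n_missing = as.integer(n_missing)),
    class = "angular_mask"
  )
}

#' @export
print.angular_mask <- function(x, ...) {
  cat(sprintf("<angular_mask> %d/%d angles missing from index %d\n",
              x$n_missing, length(x$observed), x$start_index))
  invisible(x)
}

#' Mask from a missing wedge in degrees
#'
#' Maps a missing wedge of `degrees` on the 180-degree arc to
#' `round(n_angles * degrees / 180)` consecutive missing angles.
#'
#' @param n_angles Number of projection angles.
#' @param degrees Missing wedge in degrees (e.g. 30, 60, 90).
#' @param start_index,seed Passed to [angular_mask()].
#' @return An `angular_mask`.
#' @export
mask_from_degrees <- function(n_angles, degrees, start_index = 0L,
                              seed = NULL) {
  suppressWarnings(
    angular_mask(n_angles, degrees / 180, start_index = start_index,
                 seed = seed)
  )
}

#' Zero out the missing angular block of a sinogram
#'
#' Missing rows are set exactly to 0; observed rows are returned untouched.
#'
#' @param sino A sinogram.
#' @param mask An [angular_mask()] whose length matches the sinogram.
#' @return A sinogram of the same shape.
#' @export
apply_mask <- function(sino, mask) {
  g <- sino_geometry(sino)
  stopifnot(inherits(mask, "angular_mask"))
  if (length(mask$observed) != g$n_angles)
    stop("mask length ", length(mask$observed),
         " does not match n_angles ", g$n_angles)
  out <- unclass(sino)
  out[!mask$observed, ] <- 0
  as_sinogram(out, g)
}

# mask as a 0/1 "missing" indicator matrix matching a sinogram shape
mask_matrix <- function(mask, n_detectors) {
  matrix(as.numeric(!mask$observed), nrow = length(mask$observed),
         ncol = n_detectors)
}
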