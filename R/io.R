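#' Read and write images as TIFF
#'
#' Attenuation maps are stored as 32-bit TIFF. The TIFF payload holds the
#' image affinely scaled to [0, 1]; the original range is recorded in a
#' sidecar file `<path>.range.json` which `read_image_tiff` uses to
#' restore physical attenuation values (e.g. 25 for the bead material).
#' Without the sidecar the raw [0, 1] payload is returned. Requires the
#' `tiff` package.
#'
#' @param image Numeric matrix.
#' @param path File path.
#' @return `write_image_tiff` returns `path` invisibly; `read_image_tiff`
#'   a numeric matrix.
#' @export
write_image_tiff <- function(image, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the `tiff` package is required for TIFF input/output")
  check_image(image)
  lo <- min(image)
  hi <- max(image)
  scaled <- if (hi > lo) (image - lo) / (hi - lo) else image * 0
  tiff::writeTIFF(scaled, path, bits.per.sample = 32, reduce = FALSE)
  jsonlite::write_json(list(min = lo, max = hi),
                       paste0(path, ".range.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the `tiff` package is required for TIFF input/output")
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img <- as.matrix(img)
  side <- paste0(path, ".range.json")
  if (file.exists(side)) {
    rg <- jsonlite::read_json(side)
    img <- img * (rg$max - rg$min) + rg$min
  }
  img
}
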