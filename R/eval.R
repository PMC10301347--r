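#' Peak signal-to-noise ratio
#'
#' `10 * log10(peak^2 / MSE)` in decibels. With `peak_mode =
#' "target_range"` (the default) the peak is `max(target) - min(target)`;
#' with `"fixed"` it is `peak_value`, in which case the measure is
#' symmetric in its arguments. Identical inputs give `Inf`.
#'
#' @param estimate,target Numeric arrays of identical shape.
#' @param peak_mode `"target_range"` or `"fixed"`.
#' @param peak_value Peak used when `peak_mode = "fixed"`.
#' @return PSNR in dB (possibly `Inf`).
#' @export
psnr <- function(estimate, target, peak_mode = c("target_range", "fixed"),
                 peak_value = NULL) {
  peak_mode <- match.arg(peak_mode)
  if (length(estimate) != length(target) ||
      !isTRUE(all.equal(dim(estimate), dim(target))))
    stop("`estimate` and `target` shapes differ")
  peak <- if (peak_mode == "fixed") {
    if (is.null(peak_value)) stop("`peak_value` required for fixed peak")
    peak_value
  } else {
    max(target) - min(target)
  }
  mse <- mean((as.numeric(estimate) - as.numeric(target))^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

#' Benchmark inpainting methods over a grid of missing wedges
#'
#' For each registered method and each missing wedge, the test slices are
#' masked at a fixed start angle (index 0), the shape prior is rescaled
#' against the masked measurement, the method inpaints, and two PSNRs are
#' recorded: sinogram PSNR against the target sinogram, and (optionally)
#' image PSNR of the SIRT (or FBP) reconstruction against the
#' reconstruction computed from the *full* sinogram — the reference is the
#' full-data reconstruction, not the phantom, so the score isolates the
#' inpainting error from the reconstruction error.
#'
#' @param dataset A [build_dataset()] result.
#' @param methods Character vector of registered inpainter names (see
#'   [list_inpainters()]), or a named list of inpainter functions.
#' @param missing_degrees Missing wedges in degrees on the 180-degree arc
#'   (a wedge of d degrees masks `round(n_angles * d / 180)` consecutive
#'   angles).
#' @param slices Slice indices to evaluate (default: the test split).
#' @param recon `"sirt"`, `"fbp"` or `"none"` (skip image-domain scores).
#' @param n_iters SIRT iterations.
#' @param start_index First missing angle (default 0, fixed for
#'   reproducibility).
#' @return A data frame with columns `method`, `missing_deg`, `slice_id`,
#'   `sinogram_psnr_db`, `image_psnr_db`.
#' @export
run_benchmark <- function(dataset, methods, missing_degrees = c(30, 60, 90),
                          slices = NULL, recon = c("sirt", "fbp", "none"),
                          n_iters = 100, start_index = 0L) {
  recon <- match.arg(recon)
  stopifnot(inherits(dataset, "sino_dataset"))
  if (length(methods) == 0) stop("`methods` must name at least one method")
  if (is.character(methods)) {
    fns <- lapply(methods, get_inpainter)
    names(fns) <- methods
  } else {
    fns <- methods
    if (is.null(names(fns)) || any(names(fns) == ""))
      stop("a list of methods must be named")
  }
  g <- dataset$geometry
  if (is.null(slices)) slices <- dataset$split$test
  stopifnot(length(slices) >= 1)
  rows <- list()
  for (deg in missing_degrees) {
    mask <- mask_from_degrees(g$n_angles, deg, start_index = start_index)
    for (sl in slices) {
      rec <- dataset$records[[sl]]
      masked <- apply_mask(rec$sinogram, mask)
      prior_scaled <- scale_prior_columns(rec$prior_raw, masked, mask)
      ref_img <- switch(recon,
        sirt = sirt_reconstruct(rec$sinogram, n_iters = n_iters),
        fbp = fbp_reconstruct(rec$sinogram),
        none = NULL)
      for (nm in names(fns)) {
        est <- fns[[nm]](masked, rec$prior_raw, prior_scaled, mask)
        sp <- psnr(unclass(est), unclass(rec$sinogram))
        ip <- NA_real_
        if (recon != "none") {
          est_img <- switch(recon,
            sirt = sirt_reconstruct(est, n_iters = n_iters),
            fbp = fbp_reconstruct(est))
          ip <- psnr(est_img, ref_img)
        }
        rows[[length(rows) + 1]] <- data.frame(
          method = nm, missing_deg = deg, slice_id = sl,
          sinogram_psnr_db = sp, image_psnr_db = ip)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sino_benchmark", "data.frame")
  out
}

#' Summarize a benchmark as a methods-by-wedge table
#'
#' Means per (method, wedge) cell, excluding infinite per-slice PSNRs with
#' a warning (an infinite PSNR means the method reproduced a slice
#' exactly).
#'
#' @param results A [run_benchmark()] data frame.
#' @param metric `"sinogram_psnr_db"` or `"image_psnr_db"`.
#' @return A data frame, methods in rows and one column per wedge.
#' @export
summarize_benchmark <- function(results,
                                metric = c("sinogram_psnr_db",
                                           "image_psnr_db")) {
  metric <- match.arg(metric)
  v <- results[[metric]]
  if (any(is.infinite(v))) {
    warning("excluding ", sum(is.infinite(v)),
            " infinite PSNR value(s) from the means")
    results <- results[!is.infinite(v), ]
  }
  methods <- unique(results$method)
  degs <- sort(unique(results$missing_deg))
  out <- data.frame(method = methods)
  for (d in degs) {
    out[[paste0("deg_", d)]] <- vapply(methods, function(m) {
      mean(results[[metric]][results$method == m & results$missing_deg == d])
    }, 0)
  }
  out
}
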