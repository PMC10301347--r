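#' Replace missing projections with the shape-prior sinogram
#'
#' The simplest use of CAD information: observed rows are kept untouched
#' and each missing row is copied from the prior sinogram, optionally after
#' the per-angle total-attenuation rescaling ([scale_prior_columns()]).
#'
#' @param masked Masked sinogram (missing rows zero).
#' @param prior Prior sinogram.
#' @param mask The [angular_mask()] used to mask `masked`.
#' @param use_scaling Apply [scale_prior_columns()] first?
#' @return Inpainted sinogram; observed rows are bit-identical to `masked`.
#' @export
inpaint_cad <- function(masked, prior, mask, use_scaling = FALSE) {
  g <- sino_geometry(masked)
  gp <- sino_geometry(prior)
  if (g$n_angles != gp$n_angles || g$n_detectors != gp$n_detectors)
    stop("masked and prior sinogram shapes differ")
  if (use_scaling) prior <- scale_prior_columns(prior, masked, mask)
  out <- unclass(masked)
  out[!mask$observed, ] <- unclass(prior)[!mask$observed, ]
  as_sinogram(out, g)
}

#' Linear interpolation across the missing angular block
#'
#' For each detector bin independently, values inside the gap are linearly
#' interpolated along the angle axis between the nearest observed angles.
#' With `periodic = TRUE` (the default) the angle axis wraps across the
#' half-turn boundary using the parallel-beam symmetry
#' `R(theta + pi, r) = R(theta, -r)`, i.e. the anchor row on the far side is
#' taken with its detector axis flipped — the physically correct
#' continuation for a 180-degree arc. With `periodic = FALSE` a gap touching
#' the boundary is extended as a constant from its single anchor.
#'
#' @param masked Masked sinogram.
#' @param mask The [angular_mask()].
#' @param periodic Wrap the angle axis with the detector flip?
#' @return Inpainted sinogram; observed rows are bit-identical to `masked`.
#' @export
inpaint_linear <- function(masked, mask, periodic = TRUE) {
  g <- sino_geometry(masked)
  if (length(mask$observed) != g$n_angles)
    stop("mask length does not match n_angles")
  if (!any(mask$observed))
    stop("gap covers all angles; nothing to interpolate from")
  if (all(mask$observed)) return(masked)
  na <- g$n_angles
  nd <- g$n_detectors
  v <- unclass(masked)
  out <- v
  s0 <- mask$start_index        # 0-based first missing angle
  len <- mask$n_missing
  if (periodic) {
    # work on the 360-degree extension E[i] = R(theta_i) for i < na and
    # E[i] = R(theta_{i-na}) with detectors flipped for na <= i < 2na;
    # the gap is the contiguous ext-index block s0 .. s0+len-1
    E <- rbind(v, v[, nd:1, drop = FALSE])
    li <- (s0 - 1L) %% (2L * na)
    ri <- (s0 + len) %% (2L * na)
    vl <- E[li + 1L, ]
    vr <- E[ri + 1L, ]
    for (k in seq_len(len)) {
      e <- s0 + k - 1L
      w <- k / (len + 1)
      val <- (1 - w) * vl + w * vr
      if (e >= na) out[e - na + 1L, ] <- rev(val) else out[e + 1L, ] <- val
    }
  } else {
    # plain per-bin interpolation along the angle index, constant
    # extrapolation where the gap touches the axis ends
    obs <- which(mask$observed)
    for (j in seq_len(nd)) {
      fill <- stats::approx(x = obs, y = v[obs, j],
                            xout = which(!mask$observed), rule = 2)$y
      out[!mask$observed, j] <- fill
    }
  }
  as_sinogram(out, g)
}

# ---- inpainter registry ----------------------------------------------------

.inpainters <- new.env(parent = emptyenv())

#' Register / look up inpainting methods by name
#'
#' The benchmark harness and command line address methods through this
#' registry. An inpainter is `function(masked, prior_raw, prior_scaled,
#' mask)` returning a sinogram. `"cad"`, `"cad_scaled"`, `"linear"` and
#' `"identity"` are pre-registered; learned models join via
#' [as_inpainter()].
#'
#' @param name Method name.
#' @param fn Inpainter function.
#' @return `register_inpainter` the function invisibly; `get_inpainter` the
#'   function; `list_inpainters` a character vector of names.
#' @export
register_inpainter <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1, is.function(fn))
  assign(name, fn, envir = .inpainters)
  invisible(fn)
}

#' @rdname register_inpainter
#' @export
get_inpainter <- function(name) {
  if (!exists(name, envir = .inpainters))
    stop("unknown inpainter \"", name, "\"; available: ",
         paste(sort(ls(.inpainters)), collapse = ", "))
  get(name, envir = .inpainters)
}

#' @rdname register_inpainter
#' @export
list_inpainters <- function() sort(ls(.inpainters))

register_builtin_inpainters <- function() {
  register_inpainter("identity", function(masked, prior_raw, prior_scaled,
                                          mask) masked)
  register_inpainter("cad", function(masked, prior_raw, prior_scaled, mask)
    inpaint_cad(masked, prior_raw, mask, use_scaling = FALSE))
  register_inpainter("cad_scaled", function(masked, prior_raw, prior_scaled,
                                            mask)
    inpaint_cad(masked, prior_scaled, mask, use_scaling = FALSE))
  register_inpainter("linear", function(masked, prior_raw, prior_scaled, mask)
    inpaint_linear(masked, mask, periodic = TRUE))
}

.onLoad <- function(libname, pkgname) {
  register_builtin_inpainters()
}
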