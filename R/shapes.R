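#' Circle-based shape specification
#'
#' The stand-in for CAD data: a list of circles, each with a 0-based pixel
#' centre `(cx, cy)`, a radius in pixels and an optional attenuation
#' density. Unknown densities (`NA`) are assigned at rasterization time.
#'
#' @param cx,cy Numeric vectors, circle centres (0-based pixel coordinates).
#' @param r Numeric vector of radii (> 0), pixels.
#' @param density Numeric vector of attenuations, or `NA` where unknown.
#' @return A `shape_spec`: data frame with columns `cx`, `cy`, `r`,
#'   `density`.
#' @examples
#' shape_spec(cx = c(20, 40), cy = c(30, 30), r = c(8, 6))
#' @export
shape_spec <- function(cx = numeric(), cy = numeric(), r = numeric(),
                       density = NA_real_) {
  n <- length(cx)
  stopifnot(length(cy) == n, length(r) == n)
  if (n > 0 && any(r <= 0)) stop("circle radii must be positive")
  density <- rep_len(as.numeric(density), n)
  structure(data.frame(cx = as.numeric(cx), cy = as.numeric(cy),
                       r = as.numeric(r), density = density),
            class = c("shape_spec", "data.frame"))
}

#' @export
print.shape_spec <- function(x, ...) {
  cat(sprintf("<shape_spec> %d circle(s)\n", nrow(x)))
  if (nrow(x) > 0) print.data.frame(x, ...)
  invisible(x)
}

#' Rasterize a shape specification into an image
#'
#' Fills each circle (boundary and interior: pixels whose centre lies
#' within the radius) with its density. With `density_mode = "random"`,
#' circles with unknown (`NA`) density receive a value drawn uniformly
#' from `density_range` — this is how an attenuation-less CAD drawing is
#' turned into a usable prior image. Overlaps resolve last-drawn-wins.
#'
#' @param spec A [shape_spec()].
#' @param size Output image side length in pixels.
#' @param density_mode `"fixed"` (NA densities error) or `"random"`.
#' @param density_range Length-2 range for random densities.
#' @param seed Optional seed for the random densities.
#' @param background Background value (default 0).
#' @return `size x size` numeric matrix.
#' @export
rasterize_shapes <- function(spec, size, density_mode = c("fixed", "random"),
                             density_range = c(12.5, 37.5), seed = NULL,
                             background = 0) {
  density_mode <- match.arg(density_mode)
  stopifnot(inherits(spec, "shape_spec"))
  img <- matrix(background, size, size)
  if (nrow(spec) == 0) return(img)
  out_of_image <- spec$cx + spec$r < 0 | spec$cx - spec$r > size - 1 |
    spec$cy + spec$r < 0 | spec$cy - spec$r > size - 1
  if (any(out_of_image))
    stop("circle(s) ", paste(which(out_of_image), collapse = ", "),
         " lie fully outside the image")
  dens <- spec$density
  if (anyNA(dens)) {
    if (density_mode == "fixed")
      stop("spec has NA densities; use density_mode = \"random\" ",
           "or set them explicitly")
    dens[is.na(dens)] <- with_seed(seed,
      runif(sum(is.na(dens)), density_range[1], density_range[2]))
  }
  xs <- matrix(rep(0:(size - 1), each = size), size, size)
  ys <- matrix(rep(0:(size - 1), times = size), size, size)
  for (i in seq_len(nrow(spec))) {
    inside <- (xs - spec$cx[i])^2 + (ys - spec$cy[i])^2 <= spec$r[i]^2
    img[inside] <- dens[i]
  }
  img
}

#' Write / read a shape specification as JSON
#'
#' Serialized as `{"circles": [{"cx":..,"cy":..,"r":..,"density":..|null}]}`.
#'
#' @param spec A [shape_spec()].
#' @param path File path.
#' @return `write_shape_spec` returns `path` invisibly; `read_shape_spec`
#'   returns a `shape_spec`.
#' @export
write_shape_spec <- function(spec, path) {
  stopifnot(inherits(spec, "shape_spec"))
  circles <- lapply(seq_len(nrow(spec)), function(i) {
    list(cx = spec$cx[i], cy = spec$cy[i], r = spec$r[i],
         density = if (is.na(spec$density[i])) NULL else spec$density[i])
  })
  jsonlite::write_json(list(circles = circles), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_shape_spec
#' @export
read_shape_spec <- function(path) {
  obj <- jsonlite::read_json(path)
  circles <- obj$circles
  get_num <- function(c, f, default = NA_real_) {
    v <- c[[f]]
    if (is.null(v)) default else as.numeric(v)
  }
  shape_spec(
    cx = vapply(circles, get_num, 0, f = "cx"),
    cy = vapply(circles, get_num, 0, f = "cy"),
    r = vapply(circles, get_num, 0, f = "r"),
    density = vapply(circles, get_num, 0, f = "density")
  )
}

#' Detect circles in an image (circular Hough transform)
#'
#' Edge detection (Gaussian smoothing, Sobel gradients, thresholding on
#' gradient magnitude) followed by gradient-direction Hough voting over a
#' radius range, iterative peak picking with non-maximum suppression and
#' centroid-based sub-pixel refinement. Intended for reconstructions of
#' circular phantoms; densities in the result are left unset.
#'
#' @param image Square numeric matrix.
#' @param radius_range Length-2 integer range of candidate radii (pixels).
#' @param sensitivity In (0, 1]: a candidate circle is kept while its Hough
#'   peak collects at least `sensitivity * 2 * pi * r` votes-per-perimeter
#'   equivalents (lower = more circles). Default 0.5.
#' @param max_circles Safety cap on the number of detections.
#' @return A [shape_spec()] with `NA` densities (possibly 0 rows).
#' @export
find_circles <- function(image, radius_range, sensitivity = 0.5,
                         max_circles = 64) {
  check_image(image)
  H <- nrow(image)
  radii <- seq(floor(radius_range[1]), ceiling(radius_range[2]))
  stopifnot(length(radii) >= 1, radii[1] >= 1)

  # 3x3 Gaussian smoothing then Sobel gradients
  sm <- convolve3x3(image, matrix(c(1, 2, 1, 2, 4, 2, 1, 2, 1) / 16, 3, 3))
  gx <- convolve3x3(sm, matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3,
                               byrow = TRUE))
  gy <- convolve3x3(sm, matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3,
                               byrow = TRUE))
  mag <- sqrt(gx^2 + gy^2)
  thr <- max(mag) * 0.2
  if (max(mag) == 0) return(shape_spec())
  edge <- which(mag > thr, arr.ind = TRUE)
  if (nrow(edge) == 0) return(shape_spec())
  ex <- edge[, 2] - 1  # x = column, 0-based
  ey <- edge[, 1] - 1
  ux <- gx[edge] / mag[edge]
  uy <- gy[edge] / mag[edge]

  # gradient-direction voting, both polarities, one accumulator per radius;
  # slices are 3x3-box smoothed (votes land within ~1 px of the centre) and
  # normalized by the perimeter so peaks of different radii are comparable
  nr <- length(radii)
  acc <- array(0, dim = c(H, H, nr))
  box <- matrix(1, 3, 3)
  for (k in seq_len(nr)) {
    r <- radii[k]
    slice <- numeric(H * H)
    for (sgn in c(-1, 1)) {
      cx <- round(ex + sgn * r * ux)
      cy <- round(ey + sgn * r * uy)
      ok <- cx >= 0 & cx < H & cy >= 0 & cy < H
      if (!any(ok)) next
      slice <- slice + tabulate((cy[ok] + 1) + cx[ok] * H, nbins = H * H)
    }
    acc[, , k] <- convolve3x3(matrix(slice, H, H), box) / (2 * pi * r)
  }

  found <- shape_spec()
  ys <- matrix(rep(0:(H - 1), times = H), H, H)
  xs <- matrix(rep(0:(H - 1), each = H), H, H)
  while (nrow(found) < max_circles) {
    peak <- which.max(acc)
    if (acc[peak] < sensitivity) break
    idx <- arrayInd(peak, dim(acc))
    # sub-pixel centre: score-weighted centroid over a 3x3 neighbourhood
    ri <- max(1, idx[1] - 1):min(H, idx[1] + 1)
    ci <- max(1, idx[2] - 1):min(H, idx[2] + 1)
    slab <- acc[ri, ci, idx[3], drop = FALSE]
    w <- slab / sum(slab)
    cy0 <- sum(outer(ri - 1, rep(1, length(ci))) * w[, , 1])
    cx0 <- sum(outer(rep(1, length(ri)), ci - 1) * w[, , 1])
    # radius refinement: score-weighted mean over neighbouring radii
    rk <- max(1, idx[3] - 1):min(nr, idx[3] + 1)
    rv <- acc[idx[1], idx[2], rk]
    r0 <- sum(radii[rk] * rv) / sum(rv)
    found <- rbind(found, shape_spec(cx = cx0, cy = cy0, r = r0))
    class(found) <- c("shape_spec", "data.frame")
    # suppress all accumulator mass near this centre
    # non-overlapping circles have centres >= r1 + r2 apart
    near <- (xs - cx0)^2 + (ys - cy0)^2 <= (r0 + radii[1])^2
    for (k in seq_len(nr)) {
      a <- acc[, , k]
      a[near] <- 0
      acc[, , k] <- a
    }
  }
  found
}

# Same-size 3x3 convolution with zero padding (small, test-oracle friendly)
convolve3x3 <- function(img, kern) {
  H <- nrow(img); W <- ncol(img)
  pad <- matrix(0, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- img
  out <- matrix(0, H, W)
  for (di in 0:2) for (dj in 0:2)
    out <- out + kern[di + 1, dj + 1] * pad[(1 + di):(H + di), (1 + dj):(W + dj)]
  out
}
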