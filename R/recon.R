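#' SIRT iterative reconstruction
#'
#' Simultaneous iterative reconstruction technique: the preconditioned
#' Landweber iteration
#' \deqn{x \leftarrow x + C A^T R (y - A x)}
#' with `R` and `C` the inverse row and column sums of the projector `A`
#' (zero rows/columns get inverse 0), starting from `x = 0`, with an
#' optional non-negativity clamp after each iteration. The row-weighted
#' residual norm `||y - A x||_R` is tracked and returned; it is
#' non-increasing for this iteration, and the reconstruction aborts if the
#' residual ever grows past 10x its initial value.
#'
#' @param sino Sinogram to invert.
#' @param image_size Output side length (defaults to `n_detectors`).
#' @param n_iters Number of iterations (>= 1).
#' @param nonneg Clamp negative pixels to 0 after each update?
#' @param relax Relaxation factor in (0, 2).
#' @return Reconstructed image matrix with attribute `residuals` (the
#'   weighted residual norm per iteration, including the initial one).
#' @export
sirt_reconstruct <- function(sino, image_size = NULL, n_iters = 100,
                             nonneg = TRUE, relax = 1) {
  g <- sino_geometry(sino)
  stopifnot(n_iters >= 1, relax > 0, relax < 2)
  if (is.null(image_size)) image_size <- g$n_detectors
  y <- unclass(sino)
  ones_img <- matrix(1, image_size, image_size)
  row_sums <- cpp_radon_forward(ones_img, g$angles, g$n_detectors)
  ones_sino <- matrix(1, g$n_angles, g$n_detectors)
  col_sums <- cpp_radon_adjoint(ones_sino, g$angles, image_size, image_size)
  Rinv <- ifelse(row_sums > 0, 1 / row_sums, 0)
  Cinv <- ifelse(col_sums > 0, 1 / col_sums, 0)
  x <- matrix(0, image_size, image_size)
  res_norm <- function(r) sqrt(sum(Rinv * r^2))
  r0 <- y
  residuals <- res_norm(r0)
  for (it in seq_len(n_iters)) {
    r <- y - cpp_radon_forward(x, g$angles, g$n_detectors)
    x <- x + relax * Cinv *
      cpp_radon_adjoint(Rinv * r, g$angles, image_size, image_size)
    if (nonneg) x[x < 0] <- 0
    rn <- res_norm(y - cpp_radon_forward(x, g$angles, g$n_detectors))
    residuals <- c(residuals, rn)
    if (rn > 10 * residuals[1])
      stop("SIRT diverged: residual grew 10x over its initial value at ",
           "iteration ", it)
  }
  attr(x, "residuals") <- residuals
  x
}

#' Filtered back-projection reconstruction
#'
#' Each sinogram row is ramp-filtered in the detector frequency domain
#' (optionally apodized with a Hann window), backprojected with the
#' adjoint projector, and scaled by `pi / (2 * n_angles)`.
#'
#' @param sino Sinogram to invert.
#' @param image_size Output side length (defaults to `n_detectors`).
#' @param filter `"ramp"` or `"hann"`.
#' @return Reconstructed image matrix.
#' @export
fbp_reconstruct <- function(sino, image_size = NULL,
                            filter = c("ramp", "hann")) {
  filter <- match.arg(filter)
  g <- sino_geometry(sino)
  if (is.null(image_size)) image_size <- g$n_detectors
  nd <- g$n_detectors
  # zero-pad to the next power of two >= 2*nd to suppress wrap-around
  npad <- 2^ceiling(log2(2 * nd))
  freq <- c(seq(0, npad / 2), seq(-npad / 2 + 1, -1)) / npad
  f <- 2 * abs(freq)
  if (filter == "hann")
    f <- f * (0.5 + 0.5 * cos(pi * freq / max(abs(freq))))
  v <- unclass(sino)
  filtered <- matrix(0, g$n_angles, nd)
  for (i in seq_len(g$n_angles)) {
    row <- c(v[i, ], rep(0, npad - nd))
    fr <- Re(fft(fft(row) * f, inverse = TRUE)) / npad
    filtered[i, ] <- fr[seq_len(nd)]
  }
  bp <- cpp_radon_adjoint(filtered, g$angles, image_size, image_size)
  bp * pi / (2 * g$n_angles)
}
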