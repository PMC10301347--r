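# Training loops for the adversarial inpainter and its U-net-only
# baselines, plus inference (sinogram inpainting with a trained model).

# Stack per-slice sinograms of the chosen split into training tensors.
# Channels are normalized to [0, 1] by the shared scale `norm_scale`
# (maximum of the split's target sinograms) and mapped to [-1, 1] at the
# network boundary.
assemble_tensors <- function(dataset, ids, use_prior = TRUE,
                             norm_scale = NULL) {
  g <- dataset$geometry
  S <- g$n_angles
  N <- length(ids)
  x <- array(0, c(S, S, N)); xt <- x; y <- x; m <- x
  for (k in seq_len(N)) {
    rec <- dataset$records[[ids[k]]]
    x[, , k] <- unclass(rec$sinogram)
    xt[, , k] <- unclass(rec$masked)
    if (use_prior) y[, , k] <- unclass(rec$prior)
    m[, , k] <- mask_matrix(rec$mask, g$n_detectors)
  }
  if (is.null(norm_scale)) norm_scale <- max(x)
  list(x01 = x / norm_scale, xt01 = xt / norm_scale, y01 = y / norm_scale,
       m = m, norm_scale = norm_scale, S = S, N = N)
}

# generator input stack [S,S,3,nb] on the [-1, 1] scale
gen_input <- function(tens, idx) {
  S <- tens$S; nb <- length(idx)
  gin <- array(0, c(S, S, 3, nb))
  gin[, , 1, ] <- 2 * tens$xt01[, , idx] - 1
  gin[, , 2, ] <- 2 * tens$y01[, , idx] - 1
  gin[, , 3, ] <- 2 * tens$m[, , idx] - 1
  gin
}

# discriminator input stack [S,S,2,nb] from a sinogram slab in [0,1]
disc_input <- function(sino01, y01slab, sigma) {
  S <- dim(sino01)[1]; nb <- dim(sino01)[3]
  din <- array(0, c(S, S, 2, nb))
  din[, , 1, ] <- 2 * sino01 - 1
  din[, , 2, ] <- 2 * y01slab - 1
  if (sigma > 0) din <- din + rnorm(length(din), 0, sigma)
  din
}

clip_prob <- function(p) pmin(pmax(p, 1e-7), 1 - 1e-7)

batch_indices <- function(n, batch_size) {
  ord <- sample.int(n)
  out <- split(ord, ceiling(seq_along(ord) / batch_size))
  Filter(function(b) length(b) >= 2, out)  # batch-norm needs >= 2 samples
}

check_trainable <- function(dataset) {
  stopifnot(inherits(dataset, "sino_dataset"))
  g <- dataset$geometry
  if (g$n_angles != g$n_detectors)
    stop("training requires square sinograms (n_angles == n_detectors)")
  if (length(dataset$split$train) < 2)
    stop("dataset has fewer than 2 training slices")
  g$n_angles
}

#' Train the conditional adversarial inpainter
#'
#' Alternates discriminator and generator Adam updates over the training
#' split. Real labels are smoothed to `1 - label_smoothing`; Gaussian
#' instance noise (s.d. decaying linearly to 0 over the epochs) is added to
#' every discriminator input; the generator objective
#' `-log D(G) + lambda_l1 * L1` is averaged over only the `topk_keep`
#' samples per batch that the discriminator scores as most realistic.
#' Fully seeded: the same `config$seed` on a single thread reproduces the
#' run bit-for-bit.
#'
#' @param dataset A [build_dataset()] result with square sinograms.
#' @param config A [gan_config()].
#' @param verbose Print per-epoch losses?
#' @return A `sino_inpainter_model` with elements `generator`,
#'   `discriminator`, `history` (per-epoch `d_loss`, `g_adv`, `g_l1`),
#'   `norm_scale`, `config`.
#' @export
train_gan <- function(dataset, config = gan_config(), verbose = FALSE) {
  S <- check_trainable(dataset)
  set.seed(config$seed)
  tens <- assemble_tensors(dataset, dataset$split$train, use_prior = TRUE)
  gen <- build_generator(generator_spec(S, width = config$width,
                                        dropout_rate = config$dropout_rate))
  disc <- build_discriminator(discriminator_spec(width = config$width))
  glayers <- generator_layers(gen)
  dlayers <- disc$layers
  eps_s <- config$label_smoothing
  hist <- data.frame(epoch = seq_len(config$epochs), d_loss = NA_real_,
                     g_adv = NA_real_, g_l1 = NA_real_)
  t_d <- 0; t_g <- 0
  for (epoch in seq_len(config$epochs)) {
    sigma_t <- config$instance_noise_sigma *
      (1 - (epoch - 1) / config$epochs)
    ep <- c(d_loss = 0, g_adv = 0, g_l1 = 0)
    batches <- batch_indices(tens$N, config$batch_size)
    for (idx in batches) {
      nb <- length(idx)
      gin <- gen_input(tens, idx)
      raw <- generator_forward(gen, gin, training = TRUE)
      out01 <- (raw[, , 1, , drop = TRUE] + 1) / 2
      dim(out01) <- c(S, S, nb)
      comp01 <- tens$xt01[, , idx, drop = FALSE] +
        tens$m[, , idx, drop = FALSE] * out01
      dim(comp01) <- c(S, S, nb)
      yslab <- tens$y01[, , idx, drop = FALSE]
      dim(yslab) <- c(S, S, nb)

      # ---- discriminator update (generator detached) ----
      zero_grads(dlayers)
      p_real <- discriminator_forward(
        disc, disc_input(tens$x01[, , idx, drop = FALSE], yslab, sigma_t),
        training = TRUE)
      P <- nrow(p_real)
      pr <- clip_prob(p_real)
      dreal <- -((1 - eps_s) / pr - eps_s / (1 - pr)) / length(pr)
      discriminator_backward(disc, dreal, S, nb)
      p_fake <- discriminator_forward(
        disc, disc_input(comp01, yslab, sigma_t), training = TRUE)
      pf <- clip_prob(p_fake)
      dfake <- (1 / (1 - pf)) / length(pf)
      discriminator_backward(disc, dfake, S, nb)
      t_d <- t_d + 1
      adam_step(dlayers, config$learning_rate, config$adam_beta1,
                config$adam_beta2, t_d)
      d_loss <- -mean((1 - eps_s) * log(pr) + eps_s * log(1 - pr)) -
        mean(log(1 - pf))

      # ---- generator update (through the updated discriminator) ----
      p_fake2 <- discriminator_forward(
        disc, disc_input(comp01, yslab, sigma_t), training = TRUE)
      pf2 <- clip_prob(p_fake2)
      scores <- colMeans(pf2)
      keep <- topk_filter(scores, min(config$topk_keep, nb))
      sel <- rep(0, nb); sel[keep] <- 1
      k <- length(keep)
      # adversarial gradient at the discriminator probabilities
      dprob <- -sweep(1 / pf2, 2, sel, `*`) / (k * P)
      zero_grads(dlayers)  # scratch; D itself is not stepped here
      dinp <- discriminator_backward(disc, dprob, S, nb)
      dcomp <- 2 * dinp[, , 1, , drop = TRUE]  # d(2*comp01-1)/dcomp01 = 2
      dim(dcomp) <- c(S, S, nb)
      # L1 gradient, selected samples only
      resid <- comp01 - tens$x01[, , idx, drop = FALSE]
      dim(resid) <- c(S, S, nb)
      dl1 <- config$lambda_l1 * sign(resid) / (k * S * S)
      dl1 <- sweep(dl1, 3, sel, `*`)
      dcomp <- dcomp + dl1
      dout01 <- tens$m[, , idx, drop = FALSE] * dcomp
      draw <- array(dout01 / 2, c(S, S, 1, nb))
      zero_grads(glayers)
      generator_backward(gen, draw)
      t_g <- t_g + 1
      adam_step(glayers, config$learning_rate, config$adam_beta1,
                config$adam_beta2, t_g)

      g_adv <- -mean(log(pf2))
      g_l1 <- mean(abs(resid))
      if (!all(is.finite(c(d_loss, g_adv, g_l1))))
        stop("training diverged (non-finite loss) at epoch ", epoch)
      ep <- ep + c(d_loss, g_adv, g_l1)
    }
    hist[epoch, 2:4] <- ep / length(batches)
    if (verbose)
      message(sprintf("epoch %3d  d=%.4f  adv=%.4f  l1=%.5f", epoch,
                      hist$d_loss[epoch], hist$g_adv[epoch],
                      hist$g_l1[epoch]))
  }
  structure(list(kind = "pix2pix", generator = gen, discriminator = disc,
                 config = config, norm_scale = tens$norm_scale,
                 input_size = S, geometry = dataset$geometry,
                 use_prior = TRUE, history = hist),
            class = "sino_inpainter_model")
}

#' Train the U-net-only baselines
#'
#' Same generator architecture and data pipeline as [train_gan()] but
#' trained with the plain L1 reconstruction loss (no discriminator, no
#' top-k). With `use_prior = FALSE` the prior channel is fed as zeros,
#' giving the shape-blind baseline.
#'
#' @inheritParams train_gan
#' @param use_prior Feed the shape-prior channel?
#' @return A `sino_inpainter_model` (kind `"unet_prior"` or `"unet"`).
#' @export
train_unet_baseline <- function(dataset, config = gan_config(),
                                use_prior = TRUE, verbose = FALSE) {
  S <- check_trainable(dataset)
  set.seed(config$seed)
  tens <- assemble_tensors(dataset, dataset$split$train,
                           use_prior = use_prior)
  gen <- build_generator(generator_spec(S, width = config$width,
                                        dropout_rate = config$dropout_rate))
  glayers <- generator_layers(gen)
  hist <- data.frame(epoch = seq_len(config$epochs), g_l1 = NA_real_)
  t_g <- 0
  for (epoch in seq_len(config$epochs)) {
    ep <- 0
    batches <- batch_indices(tens$N, config$batch_size)
    for (idx in batches) {
      nb <- length(idx)
      gin <- gen_input(tens, idx)
      raw <- generator_forward(gen, gin, training = TRUE)
      out01 <- (raw[, , 1, , drop = TRUE] + 1) / 2
      dim(out01) <- c(S, S, nb)
      comp01 <- tens$xt01[, , idx, drop = FALSE] +
        tens$m[, , idx, drop = FALSE] * out01
      dim(comp01) <- c(S, S, nb)
      resid <- comp01 - tens$x01[, , idx, drop = FALSE]
      dim(resid) <- c(S, S, nb)
      g_l1 <- mean(abs(resid))
      if (!is.finite(g_l1))
        stop("training diverged (non-finite loss) at epoch ", epoch)
      dcomp <- sign(resid) / length(resid)
      dout01 <- tens$m[, , idx, drop = FALSE] * dcomp
      draw <- array(dout01 / 2, c(S, S, 1, nb))
      zero_grads(glayers)
      generator_backward(gen, draw)
      t_g <- t_g + 1
      adam_step(glayers, config$learning_rate, config$adam_beta1,
                config$adam_beta2, t_g)
      ep <- ep + g_l1
    }
    hist$g_l1[epoch] <- ep / length(batches)
    if (verbose)
      message(sprintf("epoch %3d  l1=%.5f", epoch, hist$g_l1[epoch]))
  }
  structure(list(kind = if (use_prior) "unet_prior" else "unet",
                 generator = gen, discriminator = NULL, config = config,
                 norm_scale = tens$norm_scale, input_size = S,
                 geometry = dataset$geometry, use_prior = use_prior,
                 history = hist),
            class = "sino_inpainter_model")
}

#' @export
print.sino_inpainter_model <- function(x, ...) {
  cat(sprintf("<sino_inpainter_model> %s, %d x %d sinograms, width %d, %d epochs\n",
              x$kind, x$input_size, x$input_size, x$config$width,
              x$config$epochs))
  invisible(x)
}

#' Inpaint a sinogram with a trained model
#'
#' Runs the generator in evaluation mode (running batch statistics,
#' dropout off) and composes the result through the mask: observed rows
#' are returned bit-identical to `masked`, missing rows come from the
#' denormalized network output.
#'
#' @param model A `sino_inpainter_model`.
#' @param masked Masked sinogram.
#' @param prior Scaled prior sinogram (ignored for a `use_prior = FALSE`
#'   model).
#' @param mask The [angular_mask()].
#' @return Inpainted sinogram.
#' @export
inpaint_gan <- function(model, masked, prior, mask) {
  stopifnot(inherits(model, "sino_inpainter_model"))
  g <- sino_geometry(masked)
  if (g$n_angles != model$input_size || g$n_detectors != model$input_size)
    stop("sinogram geometry (", g$n_angles, " x ", g$n_detectors,
         ") does not match the model input size ", model$input_size)
  s <- model$norm_scale
  S <- model$input_size
  gin <- array(0, c(S, S, 3, 1))
  gin[, , 1, 1] <- 2 * (unclass(masked) / s) - 1
  if (model$use_prior) gin[, , 2, 1] <- 2 * (unclass(prior) / s) - 1
  else gin[, , 2, 1] <- -1
  gin[, , 3, 1] <- 2 * mask_matrix(mask, S) - 1
  raw <- generator_forward(model$generator, gin, training = FALSE)
  fill <- s * (raw[, , 1, 1] + 1) / 2
  out <- unclass(masked)
  out[!mask$observed, ] <- fill[!mask$observed, ]
  as_sinogram(out, g)
}

#' Wrap a trained model as a registrable inpainter
#'
#' @param model A `sino_inpainter_model`.
#' @return `function(masked, prior_raw, prior_scaled, mask)` suitable for
#'   [register_inpainter()] / [run_benchmark()].
#' @export
as_inpainter <- function(model) {
  force(model)
  function(masked, prior_raw, prior_scaled, mask)
    inpaint_gan(model, masked, prior_scaled, mask)
}

#' Save / load a trained inpainter model
#'
#' Checkpoints embed the architecture, configuration (including the seed)
#' and normalization constants, so a reloaded model reproduces inference
#' exactly.
#'
#' @param model A `sino_inpainter_model`.
#' @param path File path (RDS).
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "sino_inpainter_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "sino_inpainter_model"))
  model
}
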