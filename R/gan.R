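# Conditional adversarial sinogram inpainting: a U-net generator mapping
# {masked sinogram, shape-prior sinogram, mask} to the full sinogram, and a
# 16x16-patch discriminator conditioned on the prior channel.

#' Generator architecture specification
#'
#' An 8-stage encoder/decoder U-net with 4x4 stride-2 convolutions for
#' 256x256 inputs; for smaller power-of-2 inputs the stack depth adapts to
#' `log2(input_size)`. Encoder channels are `width * min(2^(i-1), 8)`
#' (64-128-256-512-512-512-512-512 at `width = 64`); decoder output
#' channels mirror the encoder doubled by the skip concatenation
#' (512-1024-1024-1024-1024-512-256-128 at full depth), with 50% dropout on
#' the first three decoder stages. A final stride-1 convolution maps to one
#' channel, followed by Tanh. Encoder activations are leaky (slope 0.2),
#' decoder activations plain ReLU; batch-norm everywhere except the first
#' encoder stage.
#'
#' @param input_size Sinogram side length; power of 2, >= 16.
#' @param width Base channel width (64 reproduces the full architecture;
#'   smaller values give desk-scale networks).
#' @param in_channels Number of input channels (3: masked sinogram, prior,
#'   mask).
#' @param dropout_rate Dropout rate on the first three decoder stages.
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(input_size, width = 64, in_channels = 3,
                           dropout_rate = 0.5) {
  if (input_size < 16 || bitwAnd(input_size, input_size - 1L) != 0)
    stop("`input_size` must be a power of 2, >= 16")
  depth <- as.integer(round(log2(input_size)))
  enc <- width * pmin(2^(seq_len(depth) - 1), 8)
  rev_enc <- rev(enc)
  dec <- ifelse(seq_len(depth) == 1, 1, 2) * rev_enc
  structure(list(input_size = as.integer(input_size), depth = depth,
                 width = width, in_channels = as.integer(in_channels),
                 encoder_channels = enc, decoder_channels = dec,
                 dropout_rate = dropout_rate, n_dropout = 3L,
                 kernel = 4L, stride = 2L),
            class = "generator_spec")
}

#' Discriminator architecture specification
#'
#' The discriminator scores non-overlapping 16x16 patches of the
#' (sinogram, prior) stack: each patch runs through a C64-C128-C256-C512
#' stack of 4x4 stride-2 convolutions (16 -> 8 -> 4 -> 2 -> 1), then a 1x1
#' convolution to one value and a Sigmoid. Every output unit therefore
#' depends on exactly one 16x16 input patch.
#'
#' @param width Base channel width (64 reproduces the full architecture).
#' @param in_channels Number of conditioned input channels (2: sinogram and
#'   prior).
#' @param patch_size Patch side length (16).
#' @return A `discriminator_spec` list.
#' @export
discriminator_spec <- function(width = 64, in_channels = 2, patch_size = 16) {
  structure(list(width = width, in_channels = as.integer(in_channels),
                 patch_size = as.integer(patch_size),
                 channels = width * c(1, 2, 4, 8)),
            class = "discriminator_spec")
}

#' Training configuration for the adversarial inpainter
#'
#' Collects every training hyperparameter in one place. Defaults are the
#' reference operating point: Adam with learning rate 2e-4 and betas
#' (0.5, 0.999), L1 weight `lambda_l1 = 100`, batch size 8, 100 epochs,
#' top-k generator updates keeping the 2 of 8 samples the discriminator
#' scores as most realistic, one-sided label smoothing for real labels and
#' Gaussian instance noise (linearly decayed to zero) on discriminator
#' inputs.
#'
#' @param learning_rate Adam learning rate.
#' @param lambda_l1 Weight of the L1 term in the generator objective.
#' @param batch_size Samples per batch.
#' @param epochs Training epochs.
#' @param topk_keep Samples kept per batch for the generator update.
#' @param label_smoothing Real labels become `1 - label_smoothing`.
#' @param instance_noise_sigma Initial s.d. of the Gaussian noise added to
#'   discriminator inputs (in normalized units); decays linearly to 0.
#' @param dropout_rate Generator decoder dropout.
#' @param width Base channel width of both networks.
#' @param adam_beta1,adam_beta2 Adam moment decay rates.
#' @param seed Integer seed controlling initialization, shuffling, dropout
#'   and noise.
#' @return A `gan_config` list.
#' @export
gan_config <- function(learning_rate = 2e-4, lambda_l1 = 100, batch_size = 8,
                       epochs = 100, topk_keep = 2, label_smoothing = 0.1,
                       instance_noise_sigma = 0.05, dropout_rate = 0.5,
                       width = 64, adam_beta1 = 0.5, adam_beta2 = 0.999,
                       seed = 1) {
  cfg <- list(learning_rate = learning_rate, lambda_l1 = lambda_l1,
              batch_size = as.integer(batch_size),
              epochs = as.integer(epochs), topk_keep = as.integer(topk_keep),
              label_smoothing = label_smoothing,
              instance_noise_sigma = instance_noise_sigma,
              dropout_rate = dropout_rate, width = width,
              adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
              seed = as.integer(seed))
  stopifnot(cfg$learning_rate > 0, cfg$lambda_l1 >= 0, cfg$batch_size >= 1,
            cfg$epochs >= 1, cfg$topk_keep >= 1,
            cfg$topk_keep <= cfg$batch_size, cfg$label_smoothing >= 0,
            cfg$label_smoothing < 1, cfg$instance_noise_sigma >= 0)
  structure(cfg, class = "gan_config")
}

# ---- generator -------------------------------------------------------------

#' Build the U-net generator
#'
#' Instantiates the network described by [generator_spec()]. Weights are
#' drawn N(0, 0.02) from R's RNG, so `set.seed()` beforehand makes the
#' build reproducible.
#'
#' @param spec A [generator_spec()].
#' @return A `sino_generator` object.
#' @export
build_generator <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  d <- spec$depth
  enc <- vector("list", d)
  cin <- spec$in_channels
  for (i in seq_len(d)) {
    blk <- list(conv = layer_conv(cin, spec$encoder_channels[i]))
    if (i > 1) blk$bn <- layer_bn(spec$encoder_channels[i])
    blk$act <- layer_act("lrelu", slope = 0.2)
    enc[[i]] <- blk
    cin <- spec$encoder_channels[i]
  }
  dec <- vector("list", d)
  for (i in seq_len(d)) {
    cin_dec <- if (i == 1) spec$encoder_channels[d] else
      spec$decoder_channels[i - 1] + spec$encoder_channels[d + 1 - i]
    blk <- list(convt = layer_convt(cin_dec, spec$decoder_channels[i]),
                bn = layer_bn(spec$decoder_channels[i]))
    if (i <= spec$n_dropout) blk$dropout <- layer_dropout(spec$dropout_rate)
    blk$act <- layer_act("relu")
    dec[[i]] <- blk
  }
  final <- layer_conv(spec$decoder_channels[d], 1, k = 3, stride = 1, pad = 1)
  final_act <- layer_act("tanh")
  gen <- list(spec = spec, enc = enc, dec = dec, final = final,
              final_act = final_act)
  class(gen) <- "sino_generator"
  adam_init(generator_layers(gen))
  gen
}

generator_layers <- function(gen) {
  out <- list()
  for (blk in c(gen$enc, gen$dec)) out <- c(out, unname(blk))
  c(out, list(gen$final, gen$final_act))
}

#' Run the generator
#'
#' @param gen A `sino_generator`.
#' @param x Input array `[S, S, in_channels, N]`, values in `[-1, 1]`.
#' @param training Use batch statistics and dropout (`TRUE`) or running
#'   statistics with dropout off (`FALSE`).
#' @return Array `[S, S, 1, N]` with values in `[-1, 1]`.
#' @export
generator_forward <- function(gen, x, training = FALSE) {
  d <- gen$spec$depth
  skips <- vector("list", d)
  h <- x
  for (i in seq_len(d)) {
    for (l in gen$enc[[i]]) h <- layer_forward(l, h, training)
    skips[[i]] <- h
  }
  for (i in seq_len(d)) {
    if (i > 1) {
      sk <- skips[[d + 1 - i]]
      gen$dec[[i]]$convt$split <- c(dim(h)[3], dim(sk)[3])
      h <- abind4(h, sk)
    }
    for (l in gen$dec[[i]]) h <- layer_forward(l, h, training)
  }
  h <- layer_forward(gen$final, h, training)
  layer_forward(gen$final_act, h, training)
}

generator_backward <- function(gen, dy) {
  d <- gen$spec$depth
  g <- layer_backward(gen$final_act, dy)
  g <- layer_backward(gen$final, g)
  dskips <- vector("list", d)
  for (i in rev(seq_len(d))) {
    for (l in rev(gen$dec[[i]])) g <- layer_backward(l, g)
    if (i > 1) {
      sp <- gen$dec[[i]]$convt$split
      dskips[[d + 1 - i]] <- g[, , sp[1] + seq_len(sp[2]), , drop = FALSE]
      g <- g[, , seq_len(sp[1]), , drop = FALSE]
    }
  }
  # g now flows into the deepest encoder output; add skip gradients on the
  # way back up
  for (i in rev(seq_len(d))) {
    if (!is.null(dskips[[i]])) g <- g + dskips[[i]]
    for (l in rev(gen$enc[[i]])) g <- layer_backward(l, g)
  }
  g
}

abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# ---- discriminator ---------------------------------------------------------

#' Build the patch discriminator
#'
#' @param spec A [discriminator_spec()].
#' @return A `sino_discriminator` object.
#' @export
build_discriminator <- function(spec) {
  stopifnot(inherits(spec, "discriminator_spec"))
  layers <- list()
  cin <- spec$in_channels
  for (ch in spec$channels) {
    layers <- c(layers, list(layer_conv(cin, ch),
                             layer_bn(ch),
                             layer_act("lrelu", slope = 0.2)))
    cin <- ch
  }
  layers <- c(layers, list(layer_conv(cin, 1, k = 1, stride = 1, pad = 0),
                           layer_act("sigmoid")))
  disc <- list(spec = spec, layers = layers)
  class(disc) <- "sino_discriminator"
  adam_init(disc$layers)
  disc
}

# cut an [S,S,C,N] stack into non-overlapping p x p patches -> [p,p,C,N*P]
tile_patches <- function(x, p) {
  d <- dim(x)
  nb <- d[1] / p
  stopifnot(nb == round(nb))
  out <- array(0, c(p, p, d[3], nb * nb * d[4]))
  k <- 0
  for (n in seq_len(d[4])) for (b in seq_len(nb)) for (a in seq_len(nb)) {
    k <- k + 1
    out[, , , k] <- x[(a - 1) * p + seq_len(p), (b - 1) * p + seq_len(p), , n]
  }
  out
}

untile_patches <- function(px, S, N, p) {
  d <- dim(px)
  nb <- S / p
  out <- array(0, c(S, S, d[3], N))
  k <- 0
  for (n in seq_len(N)) for (b in seq_len(nb)) for (a in seq_len(nb)) {
    k <- k + 1
    out[(a - 1) * p + seq_len(p), (b - 1) * p + seq_len(p), , n] <-
      px[, , , k]
  }
  out
}

#' Run the discriminator
#'
#' @param disc A `sino_discriminator`.
#' @param x Conditioned input `[S, S, in_channels, N]` in `[-1, 1]` scale.
#' @param training Batch vs running statistics.
#' @return A `P x N` matrix of per-patch probabilities in (0, 1), where `P`
#'   is the number of 16x16 patches per sinogram.
#' @export
discriminator_forward <- function(disc, x, training = FALSE) {
  p <- disc$spec$patch_size
  d <- dim(x)
  h <- tile_patches(x, p)
  for (l in disc$layers) h <- layer_forward(l, h, training)
  P <- dim(h)[4] / d[4]
  matrix(as.numeric(h), nrow = P, ncol = d[4])
}

discriminator_backward <- function(disc, dprob, S, N) {
  p <- disc$spec$patch_size
  g <- array(as.numeric(dprob), dim = c(1, 1, 1, length(dprob)))
  for (l in rev(disc$layers)) g <- layer_backward(l, g)
  untile_patches(g, S, N, p)
}

#' Number of trainable parameters
#'
#' @param model A `sino_generator`, `sino_discriminator`, or trained
#'   inpainter model.
#' @return Integer parameter count (weights, biases, batch-norm scales and
#'   shifts).
#' @export
n_parameters <- function(model) {
  layers <- if (inherits(model, "sino_generator")) generator_layers(model)
    else if (inherits(model, "sino_discriminator")) model$layers
    else if (!is.null(model$generator)) generator_layers(model$generator)
    else stop("unsupported model type")
  sum(vapply(layers, layer_param_count, 0))
}

# ---- losses ----------------------------------------------------------------

#' Adversarial and reconstruction loss terms
#'
#' The discriminator loss is the binary cross-entropy
#' `-[log d_real + log(1 - d_fake)]`, the generator adversarial term is the
#' non-saturating `-log d_fake`, and the reconstruction term is the mean
#' absolute error; the total generator objective is
#' `g_adv + lambda_l1 * g_l1`.
#'
#' @param d_real,d_fake Discriminator probabilities in (0, 1), any shape.
#' @param g_out Generator output (composed sinogram), same shape as
#'   `target`.
#' @param target Target sinogram.
#' @param lambda_l1 Weight of the L1 term.
#' @return List with `d_loss`, `g_adv`, `g_l1`, `g_total`.
#' @export
gan_loss_terms <- function(d_real, d_fake, g_out, target, lambda_l1 = 100) {
  if (any(d_real <= 0 | d_real >= 1) || any(d_fake <= 0 | d_fake >= 1))
    stop("discriminator probabilities must lie strictly in (0, 1)")
  if (!identical(dim(g_out), dim(target)) &&
      length(g_out) != length(target))
    stop("`g_out` and `target` shapes differ")
  d_loss <- -mean(log(d_real)) - mean(log(1 - d_fake))
  g_adv <- -mean(log(d_fake))
  g_l1 <- mean(abs(g_out - target))
  list(d_loss = d_loss, g_adv = g_adv, g_l1 = g_l1,
       g_total = g_adv + lambda_l1 * g_l1)
}

#' Top-k sample selection for the generator update
#'
#' Returns the (1-based) indices of the `keep` batch samples the
#' discriminator scored as most realistic; the generator loss is averaged
#' over these only, discarding the rest. Ties break by original order
#' (stable sort).
#'
#' @param scores Per-sample discriminator scores (higher = more realistic).
#' @param keep Number of samples to keep (`<= length(scores)`).
#' @return Integer vector of `keep` indices, in increasing index order.
#' @export
topk_filter <- function(scores, keep) {
  if (keep <= 0) stop("`keep` must be positive")
  if (keep > length(scores)) stop("`keep` exceeds the batch size")
  ord <- order(scores, decreasing = TRUE)  # stable: ties keep input order
  sort(ord[seq_len(keep)])
}
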