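# Minimal convolutional network machinery backing the adversarial and
# U-net sinogram inpainters. Activations are [H, W, C, N] arrays; layers
# are mutable environments holding parameters, gradients, Adam state and
# forward caches. All randomness (initialization, dropout, noise) comes
# from R's RNG so that seeded training is bit-reproducible on one thread.

new_layer <- function(.kind, ...) {
  # dotted formal so `k = ` in ... cannot partially match it
  e <- new.env(parent = emptyenv())
  e$kind <- .kind
  cfg <- list(...)
  for (nm in names(cfg)) assign(nm, cfg[[nm]], envir = e)
  e
}

init_weights <- function(dims, sd = 0.02) {
  array(rnorm(prod(dims), 0, sd), dim = dims)
}

layer_conv <- function(cin, cout, k = 4, stride = 2, pad = 1) {
  l <- new_layer("conv", cin = cin, cout = cout, k = k, stride = stride,
                 pad = pad)
  l$W <- init_weights(c(k, k, cin, cout))
  l$b <- numeric(cout)
  l
}

# transposed convolution: exact adjoint of a (k, stride, pad) convolution
# mapping the *output* (big) grid to the input (small) grid, so the weight
# lives in conv orientation [k, k, cout_big, cin_small]
layer_convt <- function(cin, cout, k = 4, stride = 2, pad = 1) {
  l <- new_layer("convt", cin = cin, cout = cout, k = k, stride = stride,
                 pad = pad)
  l$W <- init_weights(c(k, k, cout, cin))
  l$b <- numeric(cout)
  l
}

layer_bn <- function(c, momentum = 0.1, eps = 1e-5) {
  l <- new_layer("bn", c = c, momentum = momentum, eps = eps)
  l$W <- rep(1, c)   # gamma
  l$b <- rep(0, c)   # beta
  l$running_mean <- rep(0, c)
  l$running_var <- rep(1, c)
  l
}

layer_act <- function(type = c("lrelu", "relu", "tanh", "sigmoid"),
                      slope = 0.2) {
  new_layer("act", type = match.arg(type), slope = slope)
}

layer_dropout <- function(rate = 0.5) {
  new_layer("dropout", rate = rate)
}

# channel-major flattening helper for batch-norm: [H,W,C,N] -> (H*W*N) x C
to_cmat <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1, 2, 4, 3)), nrow = d[1] * d[2] * d[4], ncol = d[3])
}
from_cmat <- function(m, d) {
  aperm(array(m, dim = c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
}

layer_forward <- function(l, x, training) {
  d <- dim(x)
  switch(l$kind,
    conv = {
      l$x <- x
      cpp_conv_fwd(x, d, l$W, l$k, l$cout, l$b, l$stride, l$pad)
    },
    convt = {
      l$x <- x
      Hout <- d[1] * l$stride
      y <- cpp_conv_bwd_data(x, d, l$W, l$k, l$cout, l$stride, l$pad,
                             Hout, Hout)
      sweep_bias(y, l$b)
    },
    bn = {
      m <- to_cmat(x)
      if (training) {
        mu <- colMeans(m)
        ctr <- sweep(m, 2, mu)
        va <- colMeans(ctr^2)
        l$running_mean <- (1 - l$momentum) * l$running_mean + l$momentum * mu
        l$running_var <- (1 - l$momentum) * l$running_var + l$momentum * va
      } else {
        mu <- l$running_mean
        va <- l$running_var
        ctr <- sweep(m, 2, mu)
      }
      ivar <- 1 / sqrt(va + l$eps)
      xhat <- sweep(ctr, 2, ivar, `*`)
      l$xhat <- xhat
      l$ivar <- ivar
      l$training <- training
      y <- sweep(sweep(xhat, 2, l$W, `*`), 2, l$b, `+`)
      from_cmat(y, d)
    },
    act = {
      y <- switch(l$type,
        lrelu = pmax(x, 0) + l$slope * pmin(x, 0),
        relu = pmax(x, 0),
        tanh = tanh(x),
        # clamp the pre-activation so probabilities never round to 0 or 1
        sigmoid = 1 / (1 + exp(-pmin(pmax(x, -30), 30))))
      if (l$type %in% c("lrelu", "relu")) l$x <- x else l$y <- y
      dim(y) <- d
      y
    },
    dropout = {
      if (training) {
        mask <- (runif(length(x)) >= l$rate) / (1 - l$rate)
        dim(mask) <- d
        l$mask <- mask
        x * mask
      } else {
        l$mask <- NULL
        x
      }
    },
    stop("unknown layer kind ", l$kind))
}

layer_backward <- function(l, dy) {
  switch(l$kind,
    conv = {
      d <- dim(l$x)
      g <- cpp_conv_bwd_param(l$x, d, dy, dim(dy), l$k, l$stride, l$pad)
      l$dW <- (l$dW %||% 0) + g$dw
      l$db <- (l$db %||% 0) + g$db
      cpp_conv_bwd_data(dy, dim(dy), l$W, l$k, l$cin, l$stride, l$pad,
                        d[1], d[2])
    },
    convt = {
      # forward was the adjoint; gradients come from the conv identities
      # with the roles of input and output exchanged
      g <- cpp_conv_bwd_param(dy, dim(dy), l$x, dim(l$x), l$k, l$stride,
                              l$pad)
      l$dW <- (l$dW %||% 0) + g$dw
      l$db <- (l$db %||% 0) + bias_grad(dy)
      cpp_conv_fwd(dy, dim(dy), l$W, l$k, l$cin,
                   numeric(l$cin), l$stride, l$pad)
    },
    bn = {
      d <- dim(dy)
      dym <- to_cmat(dy)
      M <- nrow(dym)
      l$dW <- (l$dW %||% 0) + colSums(dym * l$xhat)
      l$db <- (l$db %||% 0) + colSums(dym)
      dxhat <- sweep(dym, 2, l$W, `*`)
      if (isTRUE(l$training)) {
        s1 <- colSums(dxhat)
        s2 <- colSums(dxhat * l$xhat)
        dx <- sweep(dxhat, 2, s1 / M) - sweep(l$xhat, 2, s2 / M, `*`)
        dx <- sweep(dx, 2, l$ivar, `*`)
      } else {
        # running statistics are constants in evaluation mode
        dx <- sweep(dxhat, 2, l$ivar, `*`)
      }
      from_cmat(dx, d)
    },
    act = {
      d <- dim(dy)
      dx <- switch(l$type,
        lrelu = dy * ifelse(l$x > 0, 1, l$slope),
        relu = dy * (l$x > 0),
        tanh = dy * (1 - l$y^2),
        sigmoid = dy * l$y * (1 - l$y))
      dim(dx) <- d
      dx
    },
    dropout = {
      if (is.null(l$mask)) dy else dy * l$mask
    },
    stop("unknown layer kind ", l$kind))
}

sweep_bias <- function(y, b) {
  d <- dim(y)
  m <- to_cmat(y)
  m <- sweep(m, 2, b, `+`)
  from_cmat(m, d)
}

bias_grad <- function(dy) {
  colSums(to_cmat(dy))
}

has_params <- function(l) l$kind %in% c("conv", "convt", "bn")

zero_grads <- function(layers) {
  for (l in layers) if (has_params(l)) {
    l$dW <- NULL
    l$db <- NULL
  }
  invisible(NULL)
}

adam_init <- function(layers) {
  for (l in layers) if (has_params(l)) {
    l$mW <- array(0, dim = dim(l$W) %||% length(l$W))
    l$vW <- l$mW
    l$mb <- numeric(length(l$b))
    l$vb <- l$mb
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(layers, lr, beta1, beta2, t, eps = 1e-8) {
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  for (l in layers) if (has_params(l)) {
    if (is.null(l$dW)) next
    l$mW <- beta1 * l$mW + (1 - beta1) * l$dW
    l$vW <- beta2 * l$vW + (1 - beta2) * l$dW^2
    l$W <- l$W - lr * (l$mW / c1) / (sqrt(l$vW / c2) + eps)
    l$mb <- beta1 * l$mb + (1 - beta1) * l$db
    l$vb <- beta2 * l$vb + (1 - beta2) * l$db^2
    l$b <- l$b - lr * (l$mb / c1) / (sqrt(l$vb / c2) + eps)
  }
  invisible(NULL)
}

layer_param_count <- function(l) {
  if (!has_params(l)) return(0L)
  length(l$W) + length(l$b)
}
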