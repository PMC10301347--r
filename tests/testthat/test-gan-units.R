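test_that("the full-size architecture matches the reference layer widths", {
  gs <- generator_spec(256, width = 64)
  expect_equal(gs$depth, 8)
  expect_equal(gs$encoder_channels, c(64, 128, 256, 512, 512, 512, 512, 512))
  expect_equal(gs$decoder_channels,
               c(512, 1024, 1024, 1024, 1024, 512, 256, 128))
  expect_error(generator_spec(100), "power of 2")
  expect_error(generator_spec(8), "power of 2")
  ds <- discriminator_spec(width = 64)
  expect_equal(ds$channels, c(64, 128, 256, 512))
  expect_equal(ds$patch_size, 16)
})

test_that("the generator maps [-1,1] inputs to [-1,1] outputs deterministically", {
  set.seed(1)
  gen <- build_generator(generator_spec(32, width = 4))
  x <- array(runif(32 * 32 * 3 * 2, -1, 1), c(32, 32, 3, 2))
  y1 <- generator_forward(gen, x, training = FALSE)
  y2 <- generator_forward(gen, x, training = FALSE)
  expect_equal(dim(y1), c(32, 32, 1, 2))
  expect_true(all(is.finite(y1)))
  expect_true(all(y1 >= -1 & y1 <= 1))
  expect_identical(y1, y2)  # evaluation mode is deterministic
})

test_that("parameter counts match a closed-form audit of the layer spec", {
  for (cfg in list(c(32, 4), c(64, 8))) {
    S <- cfg[1]; w <- cfg[2]
    gs <- generator_spec(S, width = w)
    set.seed(2)
    gen <- build_generator(gs)
    d <- gs$depth
    enc <- gs$encoder_channels
    dec <- gs$decoder_channels
    want <- 0
    cin <- 3
    for (i in seq_len(d)) {  # conv 4x4 + bias, batch-norm (except stage 1)
      want <- want + 16 * cin * enc[i] + enc[i] + if (i > 1) 2 * enc[i] else 0
      cin <- enc[i]
    }
    for (i in seq_len(d)) {  # transposed conv 4x4 + bias + batch-norm
      cin <- if (i == 1) enc[d] else dec[i - 1] + enc[d + 1 - i]
      want <- want + 16 * cin * dec[i] + dec[i] + 2 * dec[i]
    }
    want <- want + 9 * dec[d] * 1 + 1  # final 3x3 conv to one channel
    expect_identical(n_parameters(gen), want)
  }
})

test_that("discriminator probabilities are in (0,1) and patch-local", {
  set.seed(3)
  disc <- build_discriminator(discriminator_spec(width = 4))
  x <- array(rnorm(32 * 32 * 2 * 1), c(32, 32, 2, 1))
  p1 <- discriminator_forward(disc, x, training = FALSE)
  expect_equal(dim(p1), c(4, 1))  # four 16x16 patches of a 32x32 input
  expect_true(all(p1 > 0 & p1 < 1))
  expect_identical(p1, discriminator_forward(disc, x, training = FALSE))
  # receptive-field audit: perturbing one patch leaves the other outputs
  # bit-identical
  x2 <- x
  x2[1:16, 1:16, , 1] <- x2[1:16, 1:16, , 1] + 5
  p2 <- discriminator_forward(disc, x2, training = FALSE)
  changed <- which(abs(p2 - p1) > 0)
  expect_identical(changed, 1L)
  x3 <- x
  x3[17:32, 17:32, , 1] <- 0
  p3 <- discriminator_forward(disc, x3, training = FALSE)
  expect_identical(p3[-4, 1], p1[-4, 1])
})

test_that("loss terms follow their closed forms", {
  lt <- gan_loss_terms(d_real = rep(0.5, 10), d_fake = rep(0.5, 10),
                       g_out = matrix(1, 4, 4), target = matrix(1, 4, 4),
                       lambda_l1 = 100)
  expect_equal(lt$d_loss, 2 * log(2))
  expect_equal(lt$g_l1, 0)

  lt2 <- gan_loss_terms(d_real = 0.9, d_fake = exp(-0.7),
                        g_out = matrix(1.01, 2, 2), target = matrix(1, 2, 2),
                        lambda_l1 = 100)
  expect_equal(lt2$g_adv, 0.7)
  expect_equal(lt2$g_l1, 0.01)
  expect_equal(lt2$g_total, 1.7, tolerance = 1e-12)

  expect_error(gan_loss_terms(1.2, 0.5, 1, 1, 1), "strictly in")
  expect_error(gan_loss_terms(0.5, 0, 1, 1, 1), "strictly in")
})

test_that("top-k selection keeps the highest-scored samples with stable ties", {
  scores <- c(.1, .9, .2, .8, .3, .4, .5, .6)
  expect_identical(topk_filter(scores, 2), c(2L, 4L))
  expect_identical(topk_filter(scores, 8), 1:8)
  expect_identical(topk_filter(rep(0.5, 6), 3), 1:3)
  expect_error(topk_filter(scores, 0), "positive")
  expect_error(topk_filter(scores, 9), "batch size")
})

test_that("inpainting composes through the mask even for an untrained model", {
  ds <- tiny_dataset()
  g <- ds$geometry
  set.seed(11)
  cfg <- gan_config(epochs = 1, width = 4, batch_size = 4, seed = 11)
  gen <- build_generator(generator_spec(32, width = 4))
  model <- structure(
    list(kind = "pix2pix", generator = gen, discriminator = NULL,
         config = cfg, norm_scale = max(unclass(ds$records[[1]]$sinogram)),
         input_size = 32L, geometry = g, use_prior = TRUE,
         history = NULL),
    class = "sino_inpainter_model")
  rec <- ds$records[[2]]
  out <- inpaint_gan(model, rec$masked, rec$prior, rec$mask)
  expect_identical(unclass(out)[rec$mask$observed, ],
                   unclass(rec$masked)[rec$mask$observed, ])
  expect_true(all(is.finite(out)))
  expect_true(all(unclass(out)[!rec$mask$observed, ] >= 0))
  expect_true(all(unclass(out)[!rec$mask$observed, ] <= model$norm_scale))
  # an all-observed mask returns the input unchanged
  m0 <- suppressWarnings(angular_mask(32, 0, 0))
  expect_identical(unclass(inpaint_gan(model, rec$sinogram, rec$prior, m0)),
                   unclass(rec$sinogram))
  # geometry mismatch is rejected
  bad <- as_sinogram(matrix(0, 16, 16), scan_geometry(16, 16))
  expect_error(inpaint_gan(model, bad, bad, suppressWarnings(
    angular_mask(16, 0, 0))), "does not match")
})

test_that("seeded adversarial training is bit-reproducible", {
  ds <- tiny_dataset()
  cfg <- gan_config(epochs = 2, width = 4, batch_size = 4, seed = 21)
  m1 <- train_gan(ds, cfg)
  m2 <- train_gan(ds, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$generator$enc[[1]]$conv$W, m2$generator$enc[[1]]$conv$W)
  expect_identical(m1$generator$final$W, m2$generator$final$W)
  expect_true(all(is.finite(as.matrix(m1$history[, -1]))))
  # a different seed gives a different trajectory
  m3 <- train_gan(ds, gan_config(epochs = 2, width = 4, batch_size = 4,
                                 seed = 22))
  expect_false(identical(m1$history, m3$history))
})

test_that("the U-net trainer is deterministic and capacity-sufficient", {
  ds <- tiny_dataset()
  cfg <- gan_config(epochs = 2, width = 4, batch_size = 4, seed = 31)
  u1 <- train_unet_baseline(ds, cfg)
  u2 <- train_unet_baseline(ds, cfg)
  expect_identical(u1$history, u2$history)

  # single-sample overfit: two copies of one slice, 500 generator steps,
  # dropout off, L1 must fall below 10% of its initial value
  ds1 <- ds
  ds1$records <- ds$records[c(1, 1)]
  ds1$split <- list(train = c(1, 2), test = integer(0))
  cfg1 <- gan_config(epochs = 500, width = 4, batch_size = 2, seed = 5,
                     dropout_rate = 0)
  u3 <- train_unet_baseline(ds1, cfg1)
  expect_lt(u3$history$g_l1[500], 0.1 * u3$history$g_l1[1])
})

test_that("the L1 term is what drives reconstruction fidelity", {
  ds <- tiny_dataset()
  base <- list(epochs = 6, width = 4, batch_size = 4, seed = 41)
  with_l1 <- do.call(gan_config, c(base, list(lambda_l1 = 100)))
  no_l1 <- do.call(gan_config, c(base, list(lambda_l1 = 0)))
  m_with <- train_gan(ds, with_l1)
  m_without <- train_gan(ds, no_l1)
  expect_lt(mean(tail(m_with$history$g_l1, 2)),
            mean(tail(m_without$history$g_l1, 2)))
})
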