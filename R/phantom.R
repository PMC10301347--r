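#' Configuration of the synthetic bead phantom generator
#'
#' Slices emulate cross-sections through a tube of glass beads: several
#' non-overlapping circles of uniform attenuation 25 on a background of
#' attenuation 1, with Gaussian noise added to the object material.
#' Optional internal defects ("holes" reset to background attenuation) can
#' be punched into the objects without being recorded in the shape
#' specification, so the prior stays blind to them.
#'
#' @param image_size Slice side length in pixels.
#' @param n_circles_range Integer range of circle counts per slice.
#' @param radius_range Circle radius range, pixels.
#' @param object_attenuation Attenuation inside objects.
#' @param background_attenuation Attenuation elsewhere.
#' @param noise_sigma S.d. of Gaussian noise added to object pixels
#'   (0 disables). Default 0.5 (2% of the object attenuation).
#' @param defect `"none"` or `"holes"`.
#' @param defect_radius_range Hole radius range, pixels.
#' @param defects_per_object_range Integer range of holes per object.
#' @param background_mode `"disc"` fills the background attenuation only
#'   inside the inscribed field-of-view circle (so total attenuation stays
#'   angle-independent, as a fully-visible specimen requires); `"full"`
#'   fills the whole square.
#' @param withhold_fraction Fraction of circles randomly dropped from the
#'   returned shape specification (emulates priors that miss features);
#'   default 0.
#' @param margin Minimum gap between circles and to the inscribed
#'   field-of-view circle, pixels.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(image_size = 256, n_circles_range = c(6, 10),
                           radius_range = c(10, 30),
                           object_attenuation = 25,
                           background_attenuation = 1, noise_sigma = 0.5,
                           defect = c("none", "holes"),
                           defect_radius_range = c(2, 4),
                           defects_per_object_range = c(1, 3),
                           background_mode = c("disc", "full"),
                           withhold_fraction = 0, margin = 2) {
  defect <- match.arg(defect)
  background_mode <- match.arg(background_mode)
  stopifnot(object_attenuation > background_attenuation,
            radius_range[1] > 0, image_size >= 16,
            withhold_fraction >= 0, withhold_fraction < 1)
  structure(list(image_size = as.integer(image_size),
                 n_circles_range = as.integer(n_circles_range),
                 radius_range = radius_range,
                 object_attenuation = object_attenuation,
                 background_attenuation = background_attenuation,
                 noise_sigma = noise_sigma, defect = defect,
                 defect_radius_range = defect_radius_range,
                 defects_per_object_range =
                   as.integer(defects_per_object_range),
                 background_mode = background_mode,
                 withhold_fraction = withhold_fraction, margin = margin),
            class = "phantom_config")
}

# uniform draw from an integer range, robust to degenerate ranges
sample_int_range <- function(range) {
  v <- range[1]:range[2]
  if (length(v) == 1) v else sample(v, 1)
}

#' Generate one bead phantom slice and its shape specification
#'
#' Circles are placed by rejection sampling: radii and positions are drawn
#' uniformly inside the inscribed field of view, and candidates
#' overlapping an existing circle are rejected (bounded retries). Object
#' pixels get `object_attenuation` plus optional Gaussian noise (clipped
#' at 0); everything else is `background_attenuation`. The returned
#' `shape_spec` is the exact generating geometry — the "CAD drawing" —
#' with densities recorded.
#'
#' @param config A [phantom_config()].
#' @param seed Optional integer seed.
#' @return List with `image` (matrix) and `spec` ([shape_spec()]).
#' @export
make_bead_phantom <- function(config = phantom_config(), seed = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(seed, {
    S <- config$image_size
    ctr <- (S - 1) / 2
    fov <- (S - 1) / 2 - config$margin
    n <- sample_int_range(config$n_circles_range)
    cx <- numeric(0); cy <- numeric(0); r <- numeric(0)
    tries <- 0
    while (length(r) < n) {
      tries <- tries + 1
      if (tries > 200 * n)
        stop("could not place ", n, " non-overlapping circles of radius ",
             config$radius_range[1], "-", config$radius_range[2],
             " in a ", S, "px slice after ", tries, " attempts; ",
             "reduce the circle count or radii")
      ri <- runif(1, config$radius_range[1], config$radius_range[2])
      rho <- sqrt(runif(1)) * max(fov - ri, 0)
      phi <- runif(1, 0, 2 * pi)
      xi <- ctr + rho * cos(phi)
      yi <- ctr + rho * sin(phi)
      if (length(r) > 0 &&
          any((cx - xi)^2 + (cy - yi)^2 <
              (r + ri + config$margin)^2)) next
      cx <- c(cx, xi); cy <- c(cy, yi); r <- c(r, ri)
    }
    spec <- shape_spec(cx = cx, cy = cy, r = r,
                       density = rep(config$object_attenuation, n))
    img <- rasterize_shapes(spec, S, density_mode = "fixed")
    obj <- img == config$object_attenuation
    if (identical(config$background_mode %||% "disc", "full")) {
      img[!obj] <- config$background_attenuation
    } else {
      bg <- !obj & disc_image(S, (S - 1) / 2) > 0
      img[bg] <- config$background_attenuation
    }
    if (config$noise_sigma > 0)
      img[obj] <- pmax(0, img[obj] + rnorm(sum(obj), 0, config$noise_sigma))
    list(image = img, spec = spec)
  })
}

#' Punch internal defects into a phantom
#'
#' Adds the configured number of small background-attenuation holes
#' strictly inside each object. The shape specification is deliberately
#' *not* updated: defects are the features the prior does not know about.
#'
#' @param image Phantom image from [make_bead_phantom()].
#' @param spec Its generating [shape_spec()].
#' @param config A [phantom_config()] with `defect = "holes"`.
#' @param seed Optional integer seed.
#' @return List with `image` (defective phantom) and `holes` (a
#'   [shape_spec()] of the holes, for evaluation only).
#' @export
add_defects <- function(image, spec, config, seed = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  if (config$defect != "holes")
    stop("`config$defect` must be \"holes\"")
  if (config$defect_radius_range[2] >= min(spec$r))
    stop("defect radius ", config$defect_radius_range[2],
         " is not smaller than the smallest object radius ", min(spec$r))
  with_seed(seed, {
    S <- nrow(image)
    hx <- numeric(0); hy <- numeric(0); hr <- numeric(0)
    for (i in seq_len(nrow(spec))) {
      nh <- sample_int_range(config$defects_per_object_range)
      for (k in seq_len(nh)) {
        rr <- runif(1, config$defect_radius_range[1],
                    config$defect_radius_range[2])
        rho <- sqrt(runif(1)) * max(spec$r[i] - rr - 1, 0)
        phi <- runif(1, 0, 2 * pi)
        hx <- c(hx, spec$cx[i] + rho * cos(phi))
        hy <- c(hy, spec$cy[i] + rho * sin(phi))
        hr <- c(hr, rr)
      }
    }
    holes <- shape_spec(cx = hx, cy = hy, r = hr,
                        density = rep(config$background_attenuation,
                                      length(hr)))
    out <- image
    if (nrow(holes) > 0) {
      xs <- matrix(rep(0:(S - 1), each = S), S, S)
      ys <- matrix(rep(0:(S - 1), times = S), S, S)
      for (i in seq_len(nrow(holes))) {
        inside <- (xs - holes$cx[i])^2 + (ys - holes$cy[i])^2 <= holes$r[i]^2
        out[inside] <- config$background_attenuation
      }
    }
    list(image = out, holes = holes)
  })
}

#' Build a synthetic inpainting dataset
#'
#' For each slice: a bead phantom (optionally with defects), its target
#' sinogram, a contiguous-block angular mask (fraction drawn from
#' `missing_fractions`, start angle randomized per slice), the masked
#' sinogram, and the shape-prior sinogram (random densities, then
#' per-angle total-attenuation scaling against the masked measurement).
#' The last 10% of slices form the test split. All per-slice seeds derive
#' from `seed` and are recorded, so the same call reproduces the dataset
#' exactly.
#'
#' @param n_slices Number of slices.
#' @param geometry A [scan_geometry()].
#' @param missing_fractions Numeric vector; each slice's missing fraction
#'   is sampled from it.
#' @param config A [phantom_config()].
#' @param seed Master integer seed.
#' @param test_fraction Fraction of slices held out for testing (default
#'   0.1).
#' @return A `sino_dataset`: list with `records` (per-slice lists:
#'   `image`, `spec`, `holes`, `sinogram`, `mask`, `masked`, `prior_raw`,
#'   `prior`, `seed`), `geometry`, `config`, `split` (`train`/`test`
#'   indices), `seed`.
#' @export
build_dataset <- function(n_slices, geometry, missing_fractions = 0.5,
                          config = phantom_config(), seed = 1,
                          test_fraction = 0.1) {
  stopifnot(n_slices >= 1, is_scan_geometry(geometry))
  slice_seeds <- with_seed(seed,
    sample.int(.Machine$integer.max - 1, n_slices))
  records <- vector("list", n_slices)
  for (i in seq_len(n_slices)) {
    records[[i]] <- with_seed(slice_seeds[i], {
      ph <- make_bead_phantom(config)
      holes <- NULL
      img <- ph$image
      if (config$defect == "holes") {
        def <- add_defects(img, ph$spec, config)
        img <- def$image
        holes <- def$holes
      }
      prior_spec <- ph$spec
      prior_spec$density <- NA_real_  # densities unknown to the prior
      if (config$withhold_fraction > 0 && nrow(prior_spec) > 1) {
        drop_n <- floor(config$withhold_fraction * nrow(prior_spec))
        if (drop_n > 0) {
          keep <- sort(sample.int(nrow(prior_spec),
                                  nrow(prior_spec) - drop_n))
          prior_spec <- prior_spec[keep, ]
          class(prior_spec) <- c("shape_spec", "data.frame")
        }
      }
      sino <- forward_project(img, geometry)
      frac <- if (length(missing_fractions) == 1) missing_fractions
        else sample(missing_fractions, 1)
      mask <- angular_mask(geometry$n_angles, frac)
      masked <- apply_mask(sino, mask)
      dr <- config$object_attenuation * c(0.5, 1.5)
      prior_raw <- encode_prior(prior_spec, geometry,
                                image_size = config$image_size,
                                density_range = dr)
      prior <- scale_prior_columns(prior_raw, masked, mask)
      list(image = img, spec = ph$spec, prior_spec = prior_spec,
           holes = holes, sinogram = sino, mask = mask, masked = masked,
           prior_raw = prior_raw, prior = prior, seed = slice_seeds[i])
    })
  }
  n_test <- max(1, round(test_fraction * n_slices))
  if (n_slices == 1) n_test <- 0
  test <- if (n_test > 0) (n_slices - n_test + 1):n_slices else integer(0)
  train <- setdiff(seq_len(n_slices), test)
  structure(list(records = records, geometry = geometry, config = config,
                 split = list(train = train, test = test), seed = seed,
                 slice_seeds = slice_seeds),
            class = "sino_dataset")
}

#' @export
print.sino_dataset <- function(x, ...) {
  cat(sprintf("<sino_dataset> %d slices (%d train / %d test), %d x %d sinograms\n",
              length(x$records), length(x$split$train), length(x$split$test),
              x$geometry$n_angles, x$geometry$n_detectors))
  invisible(x)
}

#' Save / load a dataset
#'
#' The dataset is written as an RDS container next to a JSON manifest
#' recording the split membership and every seed, so a run can be audited
#' and reproduced without loading the container.
#'
#' @param dataset A `sino_dataset`.
#' @param path RDS file path; the manifest goes to `<path>.manifest.json`.
#' @return `save_dataset` returns `path` invisibly; `load_dataset` the
#'   dataset.
#' @export
save_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "sino_dataset"))
  saveRDS(dataset, path)
  manifest <- list(
    n_slices = length(dataset$records),
    n_angles = dataset$geometry$n_angles,
    n_detectors = dataset$geometry$n_detectors,
    master_seed = dataset$seed,
    slice_seeds = dataset$slice_seeds,
    train = dataset$split$train,
    test = dataset$split$test
  )
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) {
  ds <- readRDS(path)
  stopifnot(inherits(ds, "sino_dataset"))
  ds
}
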