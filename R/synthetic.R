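#' Specification for a synthetic image generator
#'
#' The synthetic generators stand in for stained tissue sections wherever a
#' known ground truth is needed: noise fields with a flat spectrum, blob
#' lattices with a known fundamental spatial frequency, and anticorrelated
#' two-compartment patterns that mimic the cortex/medulla organization of a
#' thymus section. All generators are pure functions of their spec,
#' including the seed.
#'
#' @param pattern One of `"white_noise"`, `"blob_lattice"`, `"compartments"`.
#' @param shape Integer vector `c(rows, cols)` in pixels; both >= 16.
#' @param pixel_size_um Pixel size in micrometres (> 0).
#' @param seed Integer seed (< 2^31) making the generator deterministic.
#' @param sigma White-noise standard deviation (>= 0).
#' @param spacing_um Blob-lattice spacing in micrometres; must be at least
#'   two pixels (the Nyquist limit).
#' @param blob_radius_um Gaussian blob radius (sd) in micrometres; must be
#'   below half the spacing.
#' @param jitter_um Standard deviation of the positional jitter applied to
#'   each blob centre, in micrometres (0 = perfect lattice).
#' @param compartment_scale_um Correlation length of the compartment
#'   pattern in micrometres; must be smaller than the image extent.
#' @param fill_fraction Fraction of pixels assigned to compartment A,
#'   strictly between 0 and 1.
#' @param replicate_variability Nonnegative number in `[0, 1]` controlling
#'   how much the compartment scale varies from replicate to replicate:
#'   each realization rescales `compartment_scale_um` by
#'   `exp(replicate_variability * z)` with `z` a standard normal draw
#'   (0 = identical scale in every replicate).
#'
#' @return An object of class `generator_spec`.
#' @examples
#' spec <- generator_spec("white_noise", shape = c(64, 64),
#'                        pixel_size_um = 2, seed = 1, sigma = 1)
#' img <- make_white_noise(spec)
#' @export
generator_spec <- function(pattern = c("white_noise", "blob_lattice",
                                       "compartments"),
                           shape, pixel_size_um, seed,
                           sigma = 1,
                           spacing_um = 40, blob_radius_um = 6,
                           jitter_um = 0,
                           compartment_scale_um = 100, fill_fraction = 0.4,
                           replicate_variability = 0) {
  pattern <- match.arg(pattern)
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(is.na(shape)) || any(shape < 16L))
    stop("`shape` must be two integers, each >= 16")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be positive")
  seed <- as.integer(seed)
  if (is.na(seed)) stop("`seed` must be an integer")
  if (sigma < 0) stop("`sigma` must be nonnegative")
  for (nm in c("spacing_um", "blob_radius_um", "compartment_scale_um"))
    if (get(nm) <= 0) stop("`", nm, "` must be positive")
  if (jitter_um < 0) stop("`jitter_um` must be nonnegative")
  if (fill_fraction <= 0 || fill_fraction >= 1)
    stop("`fill_fraction` must lie strictly between 0 and 1")
  if (replicate_variability < 0 || replicate_variability > 1)
    stop("`replicate_variability` must lie in [0, 1]")
  structure(list(pattern = pattern, shape = shape,
                 pixel_size_um = as.numeric(pixel_size_um),
                 seed = seed, sigma = as.numeric(sigma),
                 spacing_um = as.numeric(spacing_um),
                 blob_radius_um = as.numeric(blob_radius_um),
                 jitter_um = as.numeric(jitter_um),
                 compartment_scale_um = as.numeric(compartment_scale_um),
                 fill_fraction = as.numeric(fill_fraction),
                 replicate_variability = as.numeric(replicate_variability)),
            class = "generator_spec")
}

#' Generate a Gaussian white-noise image
#'
#' Independent N(0, sigma^2) pixels; the expected power spectrum is flat.
#'
#' @param spec A [generator_spec] with `pattern = "white_noise"`.
#' @return An [image_channel].
#' @export
make_white_noise <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  if (spec$pattern != "white_noise")
    stop("`spec` has pattern '", spec$pattern, "', expected 'white_noise'")
  vals <- withr::with_seed(spec$seed,
    matrix(stats::rnorm(prod(spec$shape), mean = 0, sd = spec$sigma),
           nrow = spec$shape[1], ncol = spec$shape[2]))
  image_channel(vals, spec$pixel_size_um)
}

#' Generate a blob-lattice image
#'
#' Gaussian-profile blobs on a square lattice of the stated spacing, with
#' optional positional jitter. The radial log-spectrum of such an image
#' peaks at the lattice fundamental, spatial frequency `1/spacing_um`,
#' which is what makes it a useful ground-truth fixture: structures spaced
#' d apart put power at frequency 1/d.
#'
#' Blob profiles are truncated at three radii, so intensities are smooth
#' and nonnegative. With `jitter_um = 0` and an integer spacing in pixels,
#' blob centres land exactly on pixels, `spacing_um / pixel_size_um`
#' pixels apart.
#'
#' @param spec A [generator_spec] with `pattern = "blob_lattice"`.
#' @return An [image_channel].
#' @export
make_blob_lattice <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  if (spec$pattern != "blob_lattice")
    stop("`spec` has pattern '", spec$pattern, "', expected 'blob_lattice'")
  px <- spec$pixel_size_um
  spacing_px <- spec$spacing_um / px
  if (spacing_px < 2)
    stop("lattice spacing of ", spec$spacing_um, " um is below the Nyquist ",
         "limit of 2 pixels (", 2 * px, " um) at ", px, " um/px")
  if (spec$blob_radius_um >= spec$spacing_um / 2)
    stop("`blob_radius_um` must be below half the lattice spacing")
  nr <- spec$shape[1]; nc <- spec$shape[2]
  # 0-based pixel-centre coordinates; first centre half a period in
  centres_r <- seq(spacing_px / 2, nr - 1, by = spacing_px)
  centres_c <- seq(spacing_px / 2, nc - 1, by = spacing_px)
  radius_px <- spec$blob_radius_um / px
  jitter_px <- spec$jitter_um / px
  img <- withr::with_seed(spec$seed, {
    m <- matrix(0, nr, nc)
    trunc_px <- 3 * radius_px
    for (cr in centres_r) for (cc in centres_c) {
      r0 <- cr + if (jitter_px > 0) stats::rnorm(1, 0, jitter_px) else 0
      c0 <- cc + if (jitter_px > 0) stats::rnorm(1, 0, jitter_px) else 0
      rows <- max(0, floor(r0 - trunc_px)):min(nr - 1, ceiling(r0 + trunc_px))
      cols <- max(0, floor(c0 - trunc_px)):min(nc - 1, ceiling(c0 + trunc_px))
      if (!length(rows) || !length(cols)) next
      d2 <- outer((rows - r0)^2, (cols - c0)^2, "+")
      prof <- exp(-d2 / (2 * radius_px^2))
      prof[d2 > trunc_px^2] <- 0
      m[rows + 1, cols + 1] <- m[rows + 1, cols + 1] + prof
    }
    m
  })
  image_channel(img, px)
}

# Gaussian random field with given correlation length, periodic (FFT)
# smoothing of a white-noise field. Returns the raw (unnormalized) field.
gaussian_random_field <- function(noise, sigma_px) {
  nr <- nrow(noise); nc <- ncol(noise)
  fr <- fft_frequencies(nr, 1)  # cycles/px
  fc <- fft_frequencies(nc, 1)
  transfer <- exp(-2 * pi^2 * sigma_px^2 * outer(fr^2, fc^2, "+"))
  Re(stats::fft(stats::fft(noise) * transfer, inverse = TRUE)) / (nr * nc)
}

scale01 <- function(m) (m - min(m)) / max(max(m) - min(m), 1e-12)

#' Generate an anticorrelated two-compartment image pair
#'
#' A Gaussian random field smoothed to the stated correlation length is
#' thresholded at the quantile that assigns `fill_fraction` of pixels to
#' compartment A. Channel A carries marker intensity inside the mask and
#' channel B inside the complement, so the two channels occupy disjoint
#' supports — emulating mutually exclusive tissue compartments such as
#' thymic cortex and medulla. Within its compartment each channel's
#' intensity is granular (an independent pixel-scale texture), the way a
#' cellular stain is: compartment-scale structure lives in the masks, while
#' fine scales behave like stain granularity rather than a smooth field.
#'
#' When `replicate_variability > 0`, each realization first rescales the
#' compartment scale by a lognormal factor `exp(replicate_variability * z)`,
#' modelling section-to-section inconsistency of organization (the
#' "variance phenotype"); at 0 every replicate has exactly the same scale.
#'
#' @param spec A [generator_spec] with `pattern = "compartments"`.
#' @return A list with elements `a` and `b`, both [image_channel] objects.
#' @export
make_compartment_pair <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  if (spec$pattern != "compartments")
    stop("`spec` has pattern '", spec$pattern, "', expected 'compartments'")
  px <- spec$pixel_size_um
  extent_um <- min(spec$shape) * px
  if (spec$compartment_scale_um >= extent_um)
    stop("`compartment_scale_um` (", spec$compartment_scale_um,
         " um) must be smaller than the image extent (", extent_um, " um)")
  nr <- spec$shape[1]; nc <- spec$shape[2]
  out <- withr::with_seed(spec$seed, {
    scale_factor <- exp(spec$replicate_variability * stats::rnorm(1))
    sigma_px <- (spec$compartment_scale_um * scale_factor) / (2 * px)
    noise <- matrix(stats::rnorm(nr * nc), nr, nc)
    field <- gaussian_random_field(noise, sigma_px)
    thr <- stats::quantile(field, probs = 1 - spec$fill_fraction,
                           names = FALSE)
    mask <- field > thr
    # granular stain textures, independent per channel
    tex_a <- scale01(noise)
    tex_b <- scale01(matrix(stats::rnorm(nr * nc), nr, nc))
    list(a = tex_a * mask, b = tex_b * !mask)
  })
  list(a = image_channel(out$a, px), b = image_channel(out$b, px))
}

# Deterministic seed splitting for replicates; keeps seeds < 2^31.
derive_seed <- function(base_seed, index, offset = 0) {
  as.integer((as.numeric(base_seed) + index * 1000003 + offset) %% 2147483647)
}

#' Generate a full synthetic condition dataset
#'
#' Produces N independent two-channel image pairs from one generator spec,
#' with per-replicate seeds derived deterministically from `base_seed`
#' (`seed_i = (base_seed + i * 1000003) mod (2^31 - 1)`). For the
#' `compartments` pattern each pair comes from [make_compartment_pair];
#' for `white_noise` and `blob_lattice` the two channels are independent
#' draws of the same generator (channel B offsets the derived seed).
#'
#' @param n_images Number of image pairs N (>= 1).
#' @param spec A [generator_spec]; its `seed` field is ignored in favour of
#'   seeds derived from `base_seed`.
#' @param base_seed Integer seed for the whole dataset.
#' @param label Condition label passed through to the dataset.
#' @return A [condition_dataset] with `n_images = N`.
#' @export
make_condition <- function(n_images, spec, base_seed, label = spec$pattern) {
  stopifnot(inherits(spec, "generator_spec"))
  n_images <- as.integer(n_images)
  if (is.na(n_images) || n_images < 1L) stop("`n_images` must be >= 1")
  pairs <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    si <- derive_seed(base_seed, i)
    if (spec$pattern == "compartments") {
      sp <- spec; sp$seed <- si
      pairs[[i]] <- make_compartment_pair(sp)
    } else {
      gen <- if (spec$pattern == "white_noise") make_white_noise
             else make_blob_lattice
      sa <- spec; sa$seed <- si
      sb <- spec; sb$seed <- derive_seed(base_seed, i, offset = 499979)
      pairs[[i]] <- list(a = gen(sa), b = gen(sb))
    }
  }
  condition_dataset(pairs, label = label)
}

#' Write a synthetic condition to per-channel 16-bit TIFF files
#'
#' Materializes a synthetic dataset on disk in the paired single-channel
#' layout understood by [load_condition] (`<stem>_ch1.tif` /
#' `<stem>_ch2.tif`), plus a JSON sidecar recording the full generator
#' spec, the base seed and N. Intensities are rescaled to the 16-bit range
#' per pair.
#'
#' @param n_images,spec,base_seed As in [make_condition].
#' @param directory Output directory (created if needed).
#' @return Invisibly, the written dataset.
#' @export
simulate_condition_files <- function(n_images, spec, base_seed, directory) {
  ds <- make_condition(n_images, spec, base_seed)
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(ds$pairs)) {
    p <- ds$pairs[[i]]
    hi <- max(p$a$intensities, p$b$intensities, 1e-12)
    lo <- min(p$a$intensities, p$b$intensities, 0)
    sc <- function(m) (m - lo) / (hi - lo)
    stem <- file.path(directory, sprintf("sim_%03d", i))
    tiff::writeTIFF(sc(p$a$intensities), paste0(stem, "_ch1.tif"),
                    bits.per.sample = 16L)
    tiff::writeTIFF(sc(p$b$intensities), paste0(stem, "_ch2.tif"),
                    bits.per.sample = 16L)
  }
  sidecar <- c(unclass(spec), list(n_images = n_images,
                                   base_seed = base_seed))
  jsonlite::write_json(sidecar, file.path(directory, "generator_spec.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(ds)
}
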