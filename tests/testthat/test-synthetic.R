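test_that("white-noise generator is deterministic with the stated moments", {
  spec <- generator_spec("white_noise", c(256, 256), 2, seed = 7, sigma = 1)
  img1 <- make_white_noise(spec)
  img2 <- make_white_noise(spec)
  expect_identical(img1$intensities, img2$intensities)

  # law of large numbers: sample variance within 5% of sigma^2 = 1
  expect_lt(abs(stats::var(as.vector(img1$intensities)) - 1), 0.05)

  zero <- make_white_noise(generator_spec("white_noise", c(32, 32), 2,
                                          seed = 1, sigma = 0))
  expect_true(all(zero$intensities == 0))

  bad <- generator_spec("blob_lattice", c(32, 32), 2, seed = 1)
  expect_error(make_white_noise(bad), "white_noise")
})

test_that("blob lattice places centres on the stated grid", {
  # spacing 40 um at 2 um/px -> centres exactly 20 px apart
  spec <- generator_spec("blob_lattice", c(128, 128), 2, seed = 1,
                         spacing_um = 40, blob_radius_um = 4, jitter_um = 0)
  img <- make_blob_lattice(spec)$intensities
  peaks <- which(img == max(img), arr.ind = TRUE)
  rows <- sort(unique(peaks[, 1]))
  expect_true(all(diff(rows) == 20))
  expect_true(all(diff(sort(unique(peaks[, 2]))) == 20))

  # one lattice period per image -> exactly one blob
  one <- make_blob_lattice(generator_spec("blob_lattice", c(20, 20), 2,
                                          seed = 1, spacing_um = 40,
                                          blob_radius_um = 4))
  lab <- EBImage::bwlabel(EBImage::Image(one$intensities > 1e-3))
  expect_equal(max(lab), 1)

  expect_error(make_blob_lattice(generator_spec("blob_lattice", c(32, 32), 2,
                                                seed = 1, spacing_um = 3,
                                                blob_radius_um = 1)),
               "Nyquist")
})

test_that("blob lattice concentrates spectral power at 1/spacing (direct DFT oracle)", {
  spec <- generator_spec("blob_lattice", c(64, 64), 2, seed = 3,
                         spacing_um = 32, blob_radius_um = 5, jitter_um = 3)
  x <- make_blob_lattice(spec)$intensities
  x <- x - mean(x)
  P <- Mod(direct_dft2(x))^2
  grid <- native_radial_grid(c(64, 64), 2, 20)
  rf <- circular_average(log(P + 1e-300), grid, 2)
  pk <- which.max(rf$values)
  target <- findInterval(1 / 32, grid$bin_edges)
  expect_lte(abs(pk - target), 1)
})

test_that("compartment pairs have complementary supports at the stated fill", {
  spec <- generator_spec("compartments", c(128, 128), 2, seed = 5,
                         compartment_scale_um = 40, fill_fraction = 0.3)
  pr <- make_compartment_pair(spec)
  fill <- mean(pr$a$intensities > 0)
  expect_lt(abs(fill - 0.3), 0.01)
  expect_equal(sum(pr$a$intensities > 0 & pr$b$intensities > 0), 0)

  # determinism
  pr2 <- make_compartment_pair(spec)
  expect_identical(pr$a$intensities, pr2$a$intensities)

  expect_error(make_compartment_pair(
    generator_spec("compartments", c(32, 32), 2, seed = 1,
                   compartment_scale_um = 100)), "extent")
})

test_that("replicate_variability controls compartment-scale spread across replicates", {
  # mask perimeter density ~ 1/scale: with rv = 0 it is stable across
  # replicates, with rv = 0.5 it spreads
  perim_density <- function(rv, seed) {
    pr <- make_compartment_pair(generator_spec(
      "compartments", c(192, 192), 2, seed = seed,
      compartment_scale_um = 40, fill_fraction = 0.4,
      replicate_variability = rv))
    m <- pr$a$intensities > 0
    edges <- sum(m[-1, ] != m[-nrow(m), ]) + sum(m[, -1] != m[, -ncol(m)])
    edges / sum(m)
  }
  p0 <- vapply(1:6, function(s) perim_density(0, s), numeric(1))
  p5 <- vapply(1:6, function(s) perim_density(0.5, s), numeric(1))
  cv <- function(x) stats::sd(x) / mean(x)
  expect_lt(cv(p0), 0.1)
  expect_gt(cv(p5), 2 * cv(p0))
})

test_that("make_condition derives reproducible, distinct replicates", {
  spec <- generator_spec("white_noise", c(32, 32), 2, seed = 1)
  ds1 <- make_condition(3, spec, base_seed = 42)
  ds2 <- make_condition(3, spec, base_seed = 42)
  expect_equal(ds1$n_images, 3)
  expect_identical(ds1$pairs[[2]]$a$intensities, ds2$pairs[[2]]$a$intensities)
  # pairwise non-identical images
  for (i in 1:2) for (j in (i + 1):3)
    expect_false(identical(ds1$pairs[[i]]$a$intensities,
                           ds1$pairs[[j]]$a$intensities))
  # channels within a pair differ too
  expect_false(identical(ds1$pairs[[1]]$a$intensities,
                         ds1$pairs[[1]]$b$intensities))
  expect_error(make_condition(0, spec, 1), ">= 1")
})

test_that("white noise has a flat expected power spectrum (Monte-Carlo oracle)", {
  # mean periodogram over many draws is flat across a low and a high
  # frequency cell
  set.seed(99)
  cells <- rbind(c(2, 3), c(9, 25), c(17, 30))
  acc <- numeric(nrow(cells))
  R <- 400
  for (r in seq_len(R)) {
    x <- matrix(stats::rnorm(32 * 32), 32, 32)
    P <- Mod(stats::fft(x))^2 / (32 * 32)
    acc <- acc + P[cells]
  }
  acc <- acc / R
  expect_true(all(abs(acc - 1) < 0.2))
})
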