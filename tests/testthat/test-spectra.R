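test_that("tapered coefficients obey mean subtraction and Parseval", {
  cfg <- analysis_config(radial_grid_size = 10)
  const <- image_channel(matrix(5, 32, 32), 2)
  ds <- condition_dataset(list(list(a = const, b = const)))
  tc <- tapered_coefficients(ds, cfg)
  expect_equal(tc$NM, 7)
  for (e in tc$estimates) expect_lt(max(Mod(e$a)), 1e-10)

  ds2 <- condition_dataset(list(white_pair(c(32, 32), seed = 11)))
  tc2 <- tapered_coefficients(ds2, cfg)
  ts <- taper_set_2d(32, 32, 2, 7)
  x <- ds2$pairs[[1]]$a$intensities
  x <- x - mean(x)
  for (m in c(1, 4)) {
    tx <- x * ts$tapers[[m]]
    expect_equal(sum(Mod(tc2$estimates[[m]]$a)^2),
                 length(tx) * sum(tx^2), tolerance = 1e-10)
  }
})

test_that("fft agrees with the direct DFT oracle on 16x16 inputs", {
  set.seed(4)
  x <- matrix(stats::rnorm(16 * 16), 16, 16)
  F1 <- stats::fft(x)
  F2 <- direct_dft2(x)
  expect_lt(max(Mod(F1 - F2)) / max(Mod(F2)), 1e-9)
})

test_that("a pure cosine concentrates tapered power within the bandwidth of its frequency", {
  n <- 32
  k0 <- 8   # cycles per image along rows
  xg <- outer(0:(n - 1), rep(1, n))
  img <- image_channel(cos(2 * pi * k0 * xg / n) + 2, 2)
  ds <- condition_dataset(list(list(a = img, b = img)))
  tc <- tapered_coefficients(ds, analysis_config())
  # direct-DFT check of one tapered image agrees with the stored fft
  ts <- taper_set_2d(n, n, 2, 7)
  tx <- (img$intensities - mean(img$intensities)) * ts$tapers[[1]]
  expect_equal(tc$estimates[[1]]$a, direct_dft2(tx), tolerance = 1e-9)
  # >= 90% of non-DC power within the bandwidth (2 index units) of +/- k0
  for (m in 1:7) {
    P <- Mod(tc$estimates[[m]]$a)^2
    P[1, 1] <- 0
    idx_r <- c((k0 - 2):(k0 + 2), (n - k0 - 2):(n - k0 + 2)) + 1
    expect_gt(sum(P[idx_r, 1:3]) + sum(P[idx_r, (n - 1):n]), 0.9 * sum(P))
  }
})

test_that("log-spectra scale additively and stay finite at zero power", {
  ds <- condition_dataset(list(white_pair(c(32, 32), seed = 3)))
  cfg <- analysis_config()
  tc <- tapered_coefficients(ds, cfg)
  ls <- log_spectrum_2d(tc, "a")
  ds2 <- condition_dataset(list(list(
    a = image_channel(ds$pairs[[1]]$a$intensities * 2, 2),
    b = ds$pairs[[1]]$b)))
  ls2 <- log_spectrum_2d(tapered_coefficients(ds2, cfg), "a")
  d <- (ls2[[1]] - ls[[1]])[-1]   # drop DC (log floor dominates there)
  expect_equal(max(abs(d - log(4))), 0, tolerance = 1e-6)

  const <- image_channel(matrix(1, 32, 32), 2)
  tc0 <- tapered_coefficients(condition_dataset(list(list(a = const, b = const))), cfg)
  ls0 <- log_spectrum_2d(tc0, "a")
  expect_true(all(is.finite(ls0[[1]])))
})

test_that("log-spectrum Monte-Carlo mean matches the log-exponential oracle", {
  # for unit white noise each non-DC complex cell has |J|^2 ~ Exp(1), so
  # E log|J|^2 = -gamma
  cfg <- analysis_config()
  cell <- c(6, 10)
  acc <- 0; nacc <- 0
  n_imgs <- ceiling(10000 / 7)
  for (i in seq_len(n_imgs)) {
    ds <- condition_dataset(list(white_pair(c(32, 32), seed = 700000 + i)))
    for (m in log_spectrum_2d(tapered_coefficients(ds, cfg), "a")) {
      acc <- acc + m[cell[1], cell[2]]
      nacc <- nacc + 1
    }
  }
  gamma_euler <- 0.57721566490153286
  # SE = sqrt(pi^2/6 / 10000) ~ 0.013; allow 4 SE
  expect_lt(abs(acc / nacc + gamma_euler), 0.052)
})

test_that("pooled coherence handles degenerate and null channels correctly", {
  cfg <- analysis_config()
  img <- make_white_noise(generator_spec("white_noise", c(32, 32), 2, 21))
  # self-coherence -> capped atanh everywhere (excluding DC)
  ds_same <- condition_dataset(list(list(a = img, b = img)))
  C <- pooled_coherence(tapered_coefficients(ds_same, cfg))
  expect_equal(max(C[-1]), atanh(1 - 1e-6), tolerance = 1e-9)
  expect_gt(min(C[-1]), atanh(1 - 1e-6) - 1e-6)
  # magnitude coherence is phase-blind: b = -a identical to b = a
  neg <- image_channel(-img$intensities, 2)
  ds_neg <- condition_dataset(list(list(a = img, b = neg)))
  expect_equal(pooled_coherence(tapered_coefficients(ds_neg, cfg)), C)
})

test_that("null coherence bias matches the closed-form magnitude-coherence mean", {
  # independent channels, NM = 21 pooled estimates: C^2 ~ Beta(1, 20), so
  # E C = Gamma(3/2) Gamma(21) / Gamma(21.5)
  cfg <- analysis_config()
  cell <- c(7, 12)
  R <- 300
  acc <- 0
  for (r in seq_len(R)) {
    ds <- white_dataset(3, c(32, 32), base_seed = 40000 + r)
    C <- tanh(pooled_coherence(tapered_coefficients(ds, cfg)))
    acc <- acc + C[cell[1], cell[2]]
  }
  expected <- exp(lgamma(1.5) + lgamma(21) - lgamma(21.5))
  expect_lt(abs(acc / R - expected), 0.02)
})

test_that("pooled coherence is permutation-invariant and conjugate-symmetric", {
  cfg <- analysis_config()
  ds <- white_dataset(2, c(32, 32), base_seed = 9)
  tc <- tapered_coefficients(ds, cfg)
  C <- pooled_coherence(tc)
  tc_perm <- tc
  perm <- sample(seq_len(tc$NM))
  tc_perm$estimates <- tc$estimates[perm]
  tc_perm$image_index <- tc$image_index[perm]
  tc_perm$taper_index <- tc$taper_index[perm]
  expect_equal(pooled_coherence(tc_perm), C, tolerance = 1e-12)

  # conjugate symmetry for real inputs: value at k equals value at -k
  n <- 32
  flip <- function(M) M[c(1, n:2), c(1, n:2)]
  expect_equal(C, flip(C), tolerance = 1e-9)
  ls <- log_spectrum_2d(tc, "a")[[1]]
  expect_equal(ls, flip(ls), tolerance = 1e-9)

  # a single estimate cannot define coherence
  tc1 <- tc
  tc1$estimates <- tc$estimates[1]
  tc1$image_index <- tc$image_index[1]
  tc1$NM <- 1L; tc1$N <- 1L
  expect_error(pooled_coherence(tc1), "at least two")
})
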