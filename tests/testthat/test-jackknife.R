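test_that("delete-one jackknife SE of a mean equals s/sqrt(n) exactly", {
  grid <- native_radial_grid(c(16, 16), 1, 8)
  set.seed(31)
  x <- stats::rnorm(10, mean = 4, sd = 2)
  ci <- jackknife_mean_ci(matrix(x, 10, 8), 0.99, grid)
  se <- (ci$ci_upper - ci$estimate) / stats::qt(0.995, 9)
  expect_equal(unname(se), rep(stats::sd(x) / sqrt(10), 8),
               tolerance = 1e-12)
  expect_equal(ci$estimate, rep(mean(x), 8))
  expect_equal(ci$dof, 9)
})

test_that("cluster jackknife of a mean equals the between-cluster s/sqrt(K)", {
  grid <- native_radial_grid(c(16, 16), 1, 8)
  set.seed(32)
  x <- stats::rnorm(12)
  cl <- rep(1:4, each = 3)
  ci <- jackknife_mean_ci(matrix(x, 12, 8), 0.95, grid, cluster = cl)
  cm <- tapply(x, cl, mean)
  se <- (ci$ci_upper - ci$estimate) / stats::qt(0.975, 3)
  expect_equal(unname(se), rep(stats::sd(cm) / sqrt(4), 8), tolerance = 1e-12)
  expect_equal(ci$dof, 3)
})

test_that("identical estimates give a zero-width interval", {
  grid <- native_radial_grid(c(16, 16), 1, 8)
  ci <- jackknife_mean_ci(matrix(2.5, 6, 8), 0.99, grid)
  expect_equal(ci$ci_lower, ci$ci_upper)
  expect_equal(ci$estimate, rep(2.5, 8))
  v <- variance_function(matrix(2.5, 6, 8), 0.99, grid)
  expect_equal(v$estimate, rep(0, 8))
  expect_equal(v$ci_lower, rep(0, 8))
  expect_equal(v$ci_upper, rep(0, 8))
  expect_error(jackknife_mean_ci(matrix(1, 1, 8), 0.99, grid), "at least 2")
})

test_that("chi-square variance intervals attain nominal coverage on normals", {
  set.seed(77)
  n <- 21; R <- 3000
  x <- matrix(stats::rnorm(n * R), n, R)
  s2 <- apply(x, 2, stats::var)
  lo <- (n - 1) * s2 / stats::qchisq(0.995, n - 1)
  hi <- (n - 1) * s2 / stats::qchisq(0.005, n - 1)
  cover <- mean(lo <= 1 & 1 <= hi)
  # binomial SE ~ 0.0018; allow 4 SE
  expect_lt(abs(cover - 0.99), 0.008)
})

test_that("variance curves are location-invariant", {
  grid <- native_radial_grid(c(32, 32), 2, 10)
  set.seed(5)
  x <- matrix(stats::rnorm(60), 6, 10)
  v1 <- variance_function(x, 0.99, grid)
  v2 <- variance_function(x + 100, 0.99, grid)
  expect_equal(v1$estimate, v2$estimate, tolerance = 1e-9)
  expect_equal(v1$ci_upper, v2$ci_upper, tolerance = 1e-9)
})

test_that("the full analysis records NM degrees of freedom and is deterministic", {
  ds <- white_dataset(3, c(64, 64), base_seed = 17)
  cfg <- analysis_config(radial_grid_size = 20)
  res1 <- micasa_analyze(ds, cfg)
  expect_equal(res1$N, 3); expect_equal(res1$M, 7); expect_equal(res1$NM, 21)
  res2 <- micasa_analyze(ds, cfg)
  for (nm in micasa:::result_curve_names) {
    expect_identical(res1[[nm]]$estimate, res2[[nm]]$estimate)
    expect_identical(res1[[nm]]$ci_lower, res2[[nm]]$ci_lower)
  }
  # all six curves share one grid and honour ci_lower <= est <= ci_upper
  for (nm in micasa:::result_curve_names) {
    ci <- res1[[nm]]
    expect_true(micasa:::same_grid(ci$grid, res1$grid))
    ok <- !ci$mask
    expect_true(all(ci$ci_lower[ok] <= ci$estimate[ok] + 1e-12))
    expect_true(all(ci$estimate[ok] <= ci$ci_upper[ok] + 1e-12))
  }
})

test_that("a blob lattice's log-spectrum peaks at the lattice fundamental", {
  spec <- generator_spec("blob_lattice", c(256, 256), 2, seed = 3,
                         spacing_um = 40, blob_radius_um = 6, jitter_um = 4)
  ds <- make_condition(3, spec, base_seed = 5)
  res <- micasa_analyze(ds)
  pk <- which.max(res$log_spectrum_a$estimate)
  target <- findInterval(1 / 40, res$grid$bin_edges)
  expect_lte(abs(pk - target), 1)
})

test_that("coherence jackknife handles degenerate and identical channels", {
  img <- make_white_noise(generator_spec("white_noise", c(48, 48), 2, 77))
  pairs <- lapply(1:3, function(i) {
    ch <- make_white_noise(generator_spec("white_noise", c(48, 48), 2, 77 + i))
    list(a = ch, b = ch)
  })
  ds <- condition_dataset(pairs)
  cfg <- analysis_config(radial_grid_size = 15)
  tc <- tapered_coefficients(ds, cfg)
  grid <- micasa:::dataset_grid(tc, 15)
  out <- jackknife_coherence_ci(tc, grid, 0.99, unit = "image")
  ok <- !out$ci$mask
  # self-coherent channels: estimate at the atanh cap with zero spread
  expect_equal(out$ci$estimate[ok],
               rep(atanh(1 - 1e-6), sum(ok)), tolerance = 1e-9)
  expect_lt(max(out$ci$ci_upper[ok] - out$ci$ci_lower[ok]), 1e-6)
  # deleting and re-adding a unit reproduces the all-in curve
  out2 <- jackknife_coherence_ci(tc, grid, 0.99, unit = "image")
  expect_identical(out$ci$estimate, out2$ci$estimate)
  expect_identical(out$deleted, out2$deleted)
})

test_that("estimate-level coherence jackknife reproduces the classical NM dof", {
  ds <- white_dataset(2, c(48, 48), base_seed = 3)
  cfg <- analysis_config(radial_grid_size = 15)
  tc <- tapered_coefficients(ds, cfg)
  grid <- micasa:::dataset_grid(tc, 15)
  out <- jackknife_coherence_ci(tc, grid, 0.99, unit = "estimate")
  expect_equal(nrow(out$deleted), 14)
  expect_equal(out$ci$dof, 13)
  out_img <- jackknife_coherence_ci(tc, grid, 0.99, unit = "image")
  expect_equal(nrow(out_img$deleted), 2)
  expect_equal(out_img$ci$dof, 1)
  # the all-in estimate is the same under either unit
  expect_equal(out$ci$estimate, out_img$ci$estimate)
})

test_that("confidence intervals narrow as N grows", {
  cfg <- analysis_config(radial_grid_size = 15)
  width_of <- function(n, seed) {
    res <- micasa_analyze(white_dataset(n, c(64, 64), base_seed = seed), cfg)
    ci <- res$log_spectrum_a
    stats::median(ci$ci_upper[!ci$mask] - ci$ci_lower[!ci$mask])
  }
  w3 <- vapply(1:12, function(s) width_of(3, 100 + s), numeric(1))
  w6 <- vapply(1:12, function(s) width_of(6, 200 + s), numeric(1))
  expect_lt(stats::median(w6), stats::median(w3))
})

test_that("comparisons are symmetric, self-empty, and band-exact", {
  ds_a <- white_dataset(3, c(64, 64), base_seed = 21)
  ds_b <- white_dataset(3, c(64, 64), base_seed = 22)
  cfg <- analysis_config(radial_grid_size = 20)
  ra <- micasa_analyze(ds_a, cfg); rb <- micasa_analyze(ds_b, cfg)
  # self-comparison: no bands anywhere
  expect_equal(nrow(compare_conditions(ra, ra)$bands), 0)
  # symmetry with flipped direction
  ab <- compare_conditions(ra, rb); ba <- compare_conditions(rb, ra)
  expect_equal(ab$bands[c("curve", "bin_start", "bin_end")],
               ba$bands[c("curve", "bin_start", "bin_end")])
  if (nrow(ab$bands) > 0)
    expect_true(all(ab$bands$direction != ba$bands$direction))

  # hand-built curves disjoint exactly on bins 5-9
  grid <- native_radial_grid(c(64, 64), 2, 20)
  base <- rep(0, 20)
  up <- base; up[5:9] <- 10
  fa <- fake_result(grid, base, base - 1, base + 1, "ctl")
  fb <- fake_result(grid, up, up - 1, up + 1, "mut")
  rep <- compare_conditions(fa, fb)
  coh <- rep$bands[rep$bands$curve == "atanh_coherence", ]
  expect_equal(nrow(coh), 1)
  expect_equal(coh$bin_start, 5)
  expect_equal(coh$bin_end, 9)
  expect_equal(coh$direction, "mut")
  expect_equal(coh$length_scale_lo_um, 1 / grid$bin_edges[10])
  expect_equal(coh$length_scale_hi_um, 1 / grid$bin_edges[5])
})

test_that("mixed image sizes are pooled per shape and compared on the common band", {
  pairs <- c(list(white_pair(c(96, 96), seed = 1)),
             list(white_pair(c(128, 112), seed = 2)),
             list(white_pair(c(96, 96), seed = 3)))
  ds <- condition_dataset(pairs, label = "mixed")
  cfg <- analysis_config(radial_grid_size = 25)
  res <- micasa_analyze(ds, cfg)
  expect_equal(res$NM, 21)
  # shared grid spans only the common band: fundamental of the smaller image
  expect_equal(res$grid$bin_edges[1], 1 / (96 * 2), tolerance = 1e-12)
  expect_equal(res$grid$bin_edges[26], 0.25, tolerance = 1e-12)
  ok <- !res$atanh_coherence$mask
  expect_gt(sum(ok), 10)
  expect_true(all(is.finite(res$atanh_coherence$estimate[ok])))
})

test_that("a single-image dataset still yields intervals (estimate-level fallback)", {
  ds <- condition_dataset(list(white_pair(c(64, 64), seed = 41)))
  res <- micasa_analyze(ds, analysis_config(radial_grid_size = 15))
  expect_equal(res$N, 1)
  expect_equal(res$log_spectrum_a$dof, 6)   # M - 1
  ok <- !res$log_spectrum_a$mask
  expect_true(all(res$log_spectrum_a$ci_lower[ok] <
                    res$log_spectrum_a$ci_upper[ok]))
})
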