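ax_mm <- 4.9 / 1000

test_that("attenuation fit recovers mu from clean exponentials", {
  z <- (0:199) * ax_mm
  expect_lt(abs(attenuation_fit(exp(-2 * 2.0 * z), ax_mm) - 2.0), 0.01)
  expect_equal(attenuation_fit(rep(0.7, 50), ax_mm), 0)
  # invariant to positive scaling
  seg <- exp(-2 * 3.5 * z)
  expect_equal(attenuation_fit(seg, ax_mm), attenuation_fit(13 * seg, ax_mm),
               tolerance = 1e-9)
  expect_warning(attenuation_fit(c(1, 0.5, 0, 0.2, 0.1), ax_mm), "nonpositive")
})

test_that("penetration depth finds the 1/e point by interpolation", {
  # I(z) = I0 exp(-z / 0.5 mm): 1/e depth exactly 0.5 mm
  z <- (0:299) * ax_mm
  d <- penetration_depth(2.5 * exp(-z / 0.5), ax_mm)
  expect_lt(abs(as.numeric(d) - 0.5), ax_mm / 2)
  expect_true(attr(d, "reached"))
  up <- penetration_depth(seq(1, 2, length.out = 50), ax_mm)
  expect_false(attr(up, "reached"))
  expect_equal(as.numeric(up), 49 * ax_mm)
  z0 <- penetration_depth(c(0, 1, 2), ax_mm)
  expect_identical(as.numeric(z0), 0)
  # invariant to positive scaling
  seg <- exp(-z / 0.3)
  expect_equal(as.numeric(penetration_depth(seg, ax_mm)),
               as.numeric(penetration_depth(7 * seg, ax_mm)), tolerance = 1e-12)
})

test_that("histogram equalization flattens intensity histograms", {
  cimg <- matrix(0.4, 20, 20)
  expect_identical(equalize_and_median(cimg), cimg)
  img <- apply_speckle(matrix(0.5, 150, 150), 1, seed = 3L)
  eq <- equalize_and_median(img, median_kernel = 1L)
  cv <- function(x, nb = 64L) {
    h <- tabulate(pmin(floor(pmin(pmax(x, 0), 1 - 1e-9) * nb) + 1L, nb), nb)
    stats::sd(h) / mean(h)
  }
  norm <- (img - min(img)) / diff(range(img))
  expect_lt(cv(eq), cv(norm))
  expect_true(all(eq >= 0 & eq <= 1))
})

test_that("moments use the population formulas with kurtosis -> 3", {
  expect_equal(moments(c(-1, 0, 1))[["skewness"]], 0)
  withr::with_seed(4L, x <- stats::rnorm(1e5))
  expect_lt(abs(moments(x)[["kurtosis"]] - 3), 0.05)
  # brute-force oracle on a skewed set
  v <- c(0, 0, 0, 1)
  m2 <- mean((v - mean(v))^2); m3 <- mean((v - mean(v))^3)
  expect_equal(moments(v)[["skewness"]], m3 / m2^1.5, tolerance = 1e-12)
  deg <- moments(c(2, 2, 2))
  expect_equal(as.numeric(deg), c(0, 3))
  expect_true(attr(deg, "degenerate"))
})

test_that("local filters and entropy behave on constant and structured regions", {
  con <- matrix(0.5, 10, 10)
  lf <- local_stat_filters(con)
  expect_identical(lf$stdfilt_mean, 0)
  expect_identical(lf$rangefilt_mean, 0)
  expect_identical(lf$entropy, 0)
  # two-level checkerboard: every 3x3 window sees both levels
  cb <- outer(1:12, 1:12, function(i, j) 0.2 + 0.5 * ((i + j) %% 2))
  lfc <- local_stat_filters(cb)
  expect_equal(lfc$rangefilt_mean, 0.5, tolerance = 1e-12)
  # uniform 256-level sample: 8 bits
  vals <- (rep(0:255, 4) + 0.5) / 256
  expect_equal(shannon_entropy(vals), 8)
})

test_that("TCN codes constant, noisy and blocky textures as specified", {
  con <- matrix(1, 8, 8)
  tc <- tcn_encode(con, epsilon = 0.01)
  st <- tcn_stats(tc)
  expect_identical(st$coarseness, 1)
  expect_identical(st$homogeneity, 1)
  # the all-within code is sum(1 * 3^k) over k = 0..7
  expect_true(all(tc$codes[2:7, 2:7] == sum(3^(0:7))))
  withr::with_seed(5L, noisy <- matrix(stats::runif(400), 20, 20))
  expect_identical(tcn_stats(tcn_encode(noisy, epsilon = 0))$coarseness, 0)
  # coarser blocks raise coarseness: 3x3 blocks vs 1x1 checkerboard
  cb1 <- outer(1:12, 1:12, function(i, j) (i + j) %% 2)
  cb3 <- outer(1:12, 1:12, function(i, j) (floor((i - 1) / 3) + floor((j - 1) / 3)) %% 2)
  expect_gt(tcn_stats(tcn_encode(cb3, 0))$coarseness,
            tcn_stats(tcn_encode(cb1, 0))$coarseness)
  expect_error(tcn_encode(matrix(1, 2, 5), 0), "3x3")
})

test_that("GLCM features match a brute-force pair enumeration", {
  con <- matrix(0.3, 6, 6)
  g <- glcm_features(con)
  expect_identical(g$contrast, 0)
  expect_identical(g$energy, 1)
  expect_true(is.na(g$correlation))
  # strict two-level checkerboard: all mass off-diagonal at distance 15
  cb <- outer(1:8, 1:8, function(i, j) (i + j) %% 2)
  gc <- glcm_features(cb, levels = 16L)
  expect_equal(gc$contrast, 15^2)
  withr::with_seed(6L, {
    for (i in 1:100) {
      reg <- matrix(stats::runif(64), 8, 8)
      got <- glcm_features(reg, levels = 16L)
      want <- glcm_bruteforce(reg, levels = 16L)
      expect_equal(got$contrast, want$contrast, tolerance = 1e-9)
      expect_equal(got$energy, want$energy, tolerance = 1e-9)
      expect_lte(got$energy, 1)
    }
  })
})

test_that("the per-layer feature vector has the frozen 16-entry layout", {
  cfg <- small_config(seed = 3L, speckle = TRUE)
  gb <- generate_bscan(cfg)
  seg <- suppressWarnings(segment_bscan(gb$bscan))
  fv <- extract_features(seg$flattened, seg$regions[[1]], seg$surface_row)
  expect_length(fv, 16)
  expect_identical(names(fv), FEATURE_NAMES)
  expect_true(all(is.finite(fv)))
  expect_gte(fv[["entropy"]], 0)
  expect_true(fv[["glcm_energy"]] > 0 && fv[["glcm_energy"]] <= 1)
  expect_false(is.null(attr(fv, "glcm_correlation")))
})

test_that("distance to surface is the layer's geometric centre depth", {
  m <- matrix(stats::runif(100 * 40, 0.4, 0.6), 100, 40)
  bs <- bscan(m, 4.9, 5)
  rg <- layer_region("x", rep(20, 40), rep(60, 40), 1L)
  fv <- extract_features(bs, rg, surface = 20)
  # centre of [20, 60) is ~19.5 px below the surface
  expect_equal(fv[["dist_to_surface"]], 19.5 * ax_mm, tolerance = 1e-6)
})

test_that("attenuation differences alone separate two phantom layers", {
  att_gap <- vapply(1:10, function(s) {
    l1 <- layer_spec("loose_collagen", 100L, 0.8, 1.0, "smooth")
    l2 <- layer_spec("dense_collagen", 100L, 0.8, 4.0, "smooth")
    cfg <- phantom_config(layers = list(l1, l2), width_px = 200L, depth_px = 256L,
                          surface_depth_px = 30L, speckle_on = TRUE, seed = s)
    gb <- generate_bscan(cfg)
    tb <- gb$truth$boundaries$boundaries
    r1 <- layer_region("p", tb[[1]] + 5, tb[[2]], 1L)
    r2 <- layer_region("p", tb[[2]], tb[[2]] + 95, 2L)
    f1 <- extract_features(gb$bscan, r1, surface = 30)
    f2 <- extract_features(gb$bscan, r2, surface = 30)
    f2[["att_mean"]] - f1[["att_mean"]]
  }, numeric(1))
  # gap ~3 mm^-1, far beyond the seed-to-seed spread
  expect_gt(mean(att_gap), 3 * stats::sd(att_gap))
  expect_gt(mean(att_gap), 1.5)
})
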