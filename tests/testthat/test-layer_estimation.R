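test_that("rmsd matches its definition", {
  expect_identical(rmsd(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_identical(rmsd(c(0, 2), c(1, 1)), 1)           # sqrt((1 + 1)/2)
  expect_error(rmsd(1:3, 1:4), "mismatch")
  # homogeneity: scaling every residual by c scales rmsd by |c|
  withr::with_seed(1L, {
    for (cc in c(-2, 0.5, 3)) {
      y <- stats::rnorm(10); r <- stats::rnorm(10)
      expect_equal(rmsd(y, y + cc * r), abs(cc) * rmsd(y, y + r),
                   tolerance = 1e-12)
    }
  })
})

test_that("rmsd equals a brute-force enumeration on random inputs", {
  withr::with_seed(7L, {
    for (i in 1:100) {
      n <- sample(1:20, 1)
      y <- stats::rnorm(n); f <- stats::rnorm(n)
      brute <- sqrt(sum((f - y)^2) / n)
      expect_equal(rmsd(y, f), brute, tolerance = 1e-12)
    }
  })
})

test_that("averaged A-lines are centred per the stated layout", {
  img <- bscan(matrix(stats::runif(512 * 800), 512, 800), 4.9, 5)
  als <- select_averaged_alines(img, n = 5L, spacing_um = 200, avg_width = 20L)
  expect_equal(vapply(als, function(a) a$center_column, integer(1)),
               c(320L, 360L, 400L, 440L, 480L))
  # avg_width = 1, no log: profile equals the raw A-line
  als1 <- select_averaged_alines(img, n = 1L, avg_width = 1L, log_transform = FALSE)
  expect_equal(als1[[1]]$values, img$intensity[, 400])
  # constant image gives constant profiles
  cimg <- bscan(matrix(0.5, 64, 400), 4.9, 5)
  alsc <- select_averaged_alines(cimg, n = 3L)
  for (a in alsc) expect_equal(diff(range(a$values)), 0)
})

test_that("too-narrow images reduce the A-line count with a warning", {
  img <- bscan(matrix(stats::runif(64 * 120), 64, 120), 4.9, 5)
  expect_warning(als <- select_averaged_alines(img, n = 5L), "reduced")
  expect_lt(length(als), 5)
})

test_that("piecewise fit finds a single slope break near its true location", {
  # two linear pieces: slope -0.5/px for 60 px then slope -3/px
  prof <- c(10 - 0.5 * (0:59), 10 - 0.5 * 59 - 3 * (1:140))
  cps <- piecewise_linear_fit(prof, rmsd_threshold = 0.05,
                              skip_below_anchor = 0L)
  expect_length(cps$points, 1)
  expect_lte(abs(cps$points[1] - 60), 13)   # init_window + extend_by
})

test_that("a single-slope profile yields one layer; infinite threshold too", {
  prof <- 5 - 0.3 * (0:199)
  expect_identical(piecewise_linear_fit(prof, skip_below_anchor = 0L)$n_layers, 1L)
  noisy <- prof + stats::rnorm(200, sd = 2)
  expect_identical(
    piecewise_linear_fit(noisy, rmsd_threshold = Inf, skip_below_anchor = 0L)$n_layers,
    1L)
})

test_that("piecewise fit is invariant to adding a constant to the profile", {
  withr::with_seed(3L, {
    prof <- c(8 - 0.2 * (0:99), 8 - 0.2 * 99 - 2 * (1:100)) + stats::rnorm(200, sd = 0.05)
  })
  a <- piecewise_linear_fit(prof, rmsd_threshold = 0.2, skip_below_anchor = 0L)
  b <- piecewise_linear_fit(prof + 42, rmsd_threshold = 0.2, skip_below_anchor = 0L)
  expect_identical(a$points, b$points)
  expect_identical(a$n_layers, b$n_layers)
})

test_that("pruning merges close points at the half-down midpoint", {
  cps <- changing_point_set(c(100L, 115L), anchor = 10L)
  pruned <- prune_changing_points(cps, min_sep = 30L)
  expect_identical(pruned$points, 107L)
  far <- changing_point_set(c(100L, 200L), anchor = 10L)
  expect_identical(prune_changing_points(far, min_sep = 30L)$points, c(100L, 200L))
  empty <- changing_point_set(integer(0), anchor = 10L)
  expect_identical(prune_changing_points(empty)$points, integer(0))
})

test_that("pruning is idempotent and never adds points", {
  withr::with_seed(5L, {
    for (i in 1:20) {
      pts <- sort(sample(30:400, sample(0:8, 1)))
      cps <- changing_point_set(pts, anchor = 15L)
      p1 <- prune_changing_points(cps, min_sep = 30L)
      expect_lte(length(p1$points), length(pts))
      if (length(p1$points) >= 2) expect_true(all(diff(p1$points) >= 30))
      p2 <- prune_changing_points(p1, min_sep = 30L)
      expect_identical(p2$points, p1$points)
    }
  })
})

test_that("the peak-variance rule deletes changing points at the specular peak", {
  profile <- c(rep(0.1, 40), 5, 8, 5, rep(0.1, 160))  # violent peak at 41:43
  cps <- changing_point_set(c(45L, 150L), anchor = 42L)
  pruned <- prune_changing_points(cps, min_sep = 30L, profile = profile,
                                  peak_std_window = 10L, peak_std_factor = 1.5)
  expect_identical(pruned$points, 150L)
})

test_that("voting takes the modal count and per-boundary medians", {
  mk <- function(pts, n) changing_point_set(as.integer(pts), anchor = 5L)
  votes <- list(mk(c(98, 200)), mk(c(100, 210)), mk(c(104, 205)),
                mk(150), mk(c(101, 204)))
  li <- vote_layer_info(votes)
  expect_identical(li$n_layers, 3L)
  expect_identical(li$initial_points[1], 100.5)   # median of 98,100,104,101
  # ties break toward the smaller count
  tied <- list(mk(c(98, 200)), mk(c(100, 210)), mk(150), mk(160))
  expect_identical(vote_layer_info(tied)$n_layers, 2L)
  # a single A-line returns its own result
  solo <- vote_layer_info(list(mk(c(98, 200))))
  expect_identical(solo$n_layers, 3L)
  expect_equal(solo$initial_points, c(98, 200))
})

test_that("layer counts are recovered on noise-free 3-layer phantoms", {
  for (s in 1:5) {
    cfg <- small_config(
      classes = c("dense_collagen", "loose_collagen", "normal_myocardium"),
      seed = s, speckle = FALSE)
    gb <- generate_bscan(cfg)
    den <- denoise(gb$bscan)
    fl <- flatten(den, detect_surface(den))
    li <- estimate_layer_info(fl$flattened)
    expect_identical(li$n_layers, 3L)
  }
})
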