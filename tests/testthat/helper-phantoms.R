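# Shared fixture builders: every fixture is generated in code at test time.

# layer specs for the given classes, filling the depth below the surface
fill_layers <- function(classes, depth_px = 512L, surface_depth_px = 40L) {
  K <- length(classes)
  th <- rep((depth_px - surface_depth_px) %/% K, K)
  th[K] <- depth_px - surface_depth_px - sum(th[-K])
  presets <- tissue_presets()
  lapply(seq_len(K), function(i) {
    s <- presets[[classes[i]]]
    s$thickness_px <- as.integer(th[i])
    s
  })
}

# standard 3-layer full-size phantom config
phantom3_config <- function(seed = 1L, speckle = TRUE, ...) {
  phantom_config(
    layers = fill_layers(c("dense_collagen", "loose_collagen", "normal_myocardium")),
    speckle_on = speckle, seed = seed, ...)
}

# small, fast phantom for module-level tests (256 deep, 200 wide)
small_config <- function(classes = c("dense_collagen", "normal_myocardium"),
                         seed = 1L, speckle = FALSE, ...) {
  phantom_config(layers = fill_layers(classes, depth_px = 256L, surface_depth_px = 30L),
                 width_px = 200L, depth_px = 256L, surface_depth_px = 30L,
                 speckle_on = speckle, seed = seed, ...)
}

# mean absolute boundary error of a segmentation against phantom truth,
# averaged over boundaries (truth mapped into the flattened frame)
segmentation_mae <- function(gb, seg) {
  tb <- gb$truth$boundaries$boundaries
  est <- seg$boundaries$boundaries
  if (length(est) != length(tb)) return(NA_real_)
  mean(vapply(seq_along(est), function(k)
    mean(abs(est[[k]] - (tb[[k]] + seg$shifts))), numeric(1)))
}

# two seeded Gaussian blobs for classifier tests
make_blobs <- function(n_per = 100L, sep = 3, seed = 42L, d = 2L) {
  withr::with_seed(seed, {
    X <- rbind(matrix(stats::rnorm(d * n_per), n_per, d),
               matrix(stats::rnorm(d * n_per, mean = sep), n_per, d))
  })
  list(X = X, t = rep(c(0, 1), each = n_per))
}

# brute-force GLCM by explicit pair enumeration (independent oracle)
glcm_bruteforce <- function(region, levels = 16L) {
  r <- range(region)
  q <- floor((region - r[1]) / (r[2] - r[1]) * levels)
  q[q == levels] <- levels - 1L
  C <- matrix(0, levels, levels)
  for (i in seq_len(nrow(q))) for (j in seq_len(ncol(q) - 1L)) {
    a <- q[i, j] + 1L; b <- q[i, j + 1L] + 1L
    C[a, b] <- C[a, b] + 1
    C[b, a] <- C[b, a] + 1
  }
  P <- C / sum(C)
  ij <- 0:(levels - 1L)
  I <- matrix(ij, levels, levels); J <- t(I)
  list(contrast = sum((I - J)^2 * P), energy = sum(P^2))
}

# exhaustive dynamic-programming best monotone-step path (oracle for the
# greedy boundary search on small maps)
dp_best_path <- function(cost, delta_z) {
  nz <- nrow(cost); nx <- ncol(cost)
  val <- matrix(-Inf, nz, nx)
  back <- matrix(0L, nz, nx)
  val[, 1] <- cost[, 1]
  for (x in 2:nx) for (z in 1:nz) {
    lo <- max(1L, z - delta_z); hi <- min(nz, z + delta_z)
    prev <- val[lo:hi, x - 1]
    b <- which.max(prev)
    val[z, x] <- cost[z, x] + prev[b]
    back[z, x] <- lo + b - 1L
  }
  path <- integer(nx)
  path[nx] <- which.max(val[, nx])
  for (x in nx:2) path[x - 1] <- back[path[x], x]
  path
}
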