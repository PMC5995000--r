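# Per-layer feature extraction: optical properties (attenuation,
# penetration depth), statistical moments, and texture (local std/range
# filters, entropy, texture code numbers, GLCM).

#' Canonical feature order
#'
#' The fixed names and order of the 16-entry per-layer feature vector.
#'
#' @format Character vector of length 16.
#' @export
FEATURE_NAMES <- c(
  "att_mean", "att_std", "pen_depth_mean", "pen_depth_std",
  "stdfilt_mean", "stdfilt_std", "rangefilt_mean", "rangefilt_std",
  "entropy", "tcn_coarseness", "tcn_homogeneity",
  "glcm_contrast", "glcm_energy", "dist_to_surface",
  "skewness", "kurtosis")

#' Attenuation coefficient from an A-line segment
#'
#' Single-scattering model: intensity decays as `I0 * exp(-2 * mu * z)`, so
#' mu is minus half the least-squares slope of `log(intensity)` against
#' depth in mm.
#'
#' @param aline_segment Numeric intensity segment (linear scale, >= 5
#'   samples).
#' @param axial_mm_per_px Axial spacing in mm per pixel.
#' @return Attenuation coefficient in 1/mm. Invariant to positive scaling
#'   of the segment.
#' @export
attenuation_fit <- function(aline_segment, axial_mm_per_px) {
  stopifnot(length(aline_segment) >= 5, axial_mm_per_px > 0)
  if (any(aline_segment <= 0)) {
    warning("nonpositive intensities offset by machine epsilon before log")
    aline_segment <- pmax(aline_segment, .Machine$double.eps)
  }
  z <- (seq_along(aline_segment) - 1) * axial_mm_per_px
  y <- log(aline_segment)
  zb <- mean(z)
  slope <- sum((z - zb) * (y - mean(y))) / sum((z - zb)^2)
  -slope / 2
}

#' Penetration depth of an A-line segment
#'
#' The first depth (linear interpolation between samples) at which the
#' intensity drops to `1/e` of its value at the segment start, measured
#' from the segment start. If the threshold is never reached the full
#' segment length is returned with attribute `reached = FALSE`.
#'
#' @param aline_segment Numeric intensity segment.
#' @param axial_mm_per_px Axial spacing in mm per pixel.
#' @return Depth in mm (attribute `reached` says whether the 1/e point was
#'   found). Invariant to positive scaling of the segment.
#' @export
penetration_depth <- function(aline_segment, axial_mm_per_px) {
  stopifnot(length(aline_segment) >= 1, axial_mm_per_px > 0)
  I0 <- aline_segment[1]
  if (I0 <= 0) return(structure(0, reached = TRUE))
  thr <- I0 / exp(1)
  below <- which(aline_segment <= thr)
  if (!length(below))
    return(structure((length(aline_segment) - 1) * axial_mm_per_px,
                     reached = FALSE))
  k <- below[1]
  if (k == 1) return(structure(0, reached = TRUE))
  frac <- (aline_segment[k - 1] - thr) / (aline_segment[k - 1] - aline_segment[k])
  structure((k - 2 + frac) * axial_mm_per_px, reached = TRUE)
}

#' Histogram equalization followed by median filtering
#'
#' Rescales to \[0, 1\], equalizes the histogram toward a uniform target
#' over 256 levels (EBImage backend) and median-filters with the given odd
#' kernel (`median_kernel = 1` skips the filter). Output values lie in
#' \[0, 1\]; a constant image passes through unchanged.
#'
#' @param img Numeric matrix.
#' @param median_kernel Odd window width in pixels.
#' @return Matrix of the same shape in \[0, 1\].
#' @export
equalize_and_median <- function(img, median_kernel = 3L) {
  stopifnot(is.matrix(img))
  r <- range(img)
  if (r[1] == r[2]) return(img)
  norm <- (img - r[1]) / (r[2] - r[1])
  eq <- as.matrix(EBImage::equalize(norm, range = c(0, 1), levels = 256))
  if (median_kernel > 1) {
    if (median_kernel %% 2 != 1) stop("median kernel must be odd")
    eq <- as.matrix(EBImage::medianFilter(eq, size = (median_kernel - 1L) %/% 2L))
  }
  eq
}

#' Skewness and kurtosis of region values
#'
#' Standardized third and fourth central moments (population formulas;
#' kurtosis in the non-excess convention, normal -> 3).
#'
#' @param region_values Numeric vector (>= 3 values).
#' @return Named numeric `c(skewness, kurtosis)`; a zero-variance region
#'   yields `c(0, 3)` with attribute `degenerate = TRUE`.
#' @export
moments <- function(region_values) {
  stopifnot(length(region_values) >= 3)
  if (stats::var(region_values) == 0)
    return(structure(c(skewness = 0, kurtosis = 3), degenerate = TRUE))
  c(skewness = e1071::skewness(region_values, type = 1),
    kurtosis = e1071::kurtosis(region_values, type = 1) + 3)
}

# stack of 3x3 neighbour-shifted copies with edge replication
shift_stack3 <- function(m) {
  nz <- nrow(m); nx <- ncol(m)
  pad <- m[c(1, seq_len(nz), nz), c(1, seq_len(nx), nx)]
  lapply(-1:1, function(dz) lapply(-1:1, function(dx)
    pad[(2 + dz):(nz + 1 + dz), (2 + dx):(nx + 1 + dx)]))
}

#' Local standard-deviation / range filters and region entropy
#'
#' Per-pixel local (3x3, edge-replicated) sample standard deviation and
#' local range (max - min), summarized as mean and standard deviation over
#' the region, plus the Shannon entropy (base 2) of the region's 256-bin
#' intensity histogram over \[0, 1\].
#'
#' @param img Numeric matrix (conventionally in \[0, 1\], e.g. output of
#'   [equalize_and_median()]).
#' @param mask Optional logical matrix restricting the region.
#' @return List: `stdfilt_mean`, `stdfilt_std`, `rangefilt_mean`,
#'   `rangefilt_std`, `entropy`, and the per-pixel maps `stdfilt`,
#'   `rangefilt`.
#' @export
local_stat_filters <- function(img, mask = NULL) {
  stopifnot(is.matrix(img), nrow(img) >= 3, ncol(img) >= 3)
  st <- shift_stack3(img)
  mats <- unlist(st, recursive = FALSE)
  s1 <- Reduce(`+`, mats)
  s2 <- Reduce(`+`, lapply(mats, function(x) x^2))
  v <- pmax(0, (s2 - s1^2 / 9) / 8)
  stdf <- sqrt(v)
  rangef <- Reduce(pmax, mats) - Reduce(pmin, mats)
  sel <- if (is.null(mask)) rep(TRUE, length(img)) else as.vector(mask)
  vals <- img[sel]
  list(stdfilt_mean = mean(stdf[sel]), stdfilt_std = stats::sd(stdf[sel]),
       rangefilt_mean = mean(rangef[sel]), rangefilt_std = stats::sd(rangef[sel]),
       entropy = shannon_entropy(vals),
       stdfilt = stdf, rangefilt = rangef)
}

#' Shannon entropy of an intensity sample
#'
#' Base-2 entropy of the 256-bin histogram over \[0, 1\] (values clipped).
#'
#' @param values Numeric vector.
#' @param bins Number of histogram bins.
#' @return Entropy in bits (0 for a constant sample, `log2(bins)` max).
#' @export
shannon_entropy <- function(values, bins = 256L) {
  b <- pmin(pmax(floor(pmin(pmax(values, 0), 1) * bins), 0), bins - 1L)
  p <- tabulate(b + 1L, nbins = bins)
  p <- p[p > 0] / length(values)
  -sum(p * log2(p))
}

#' Texture code numbers (TCN)
#'
#' Each interior pixel is coded by the intensity relation to its eight
#' neighbours, clockwise from north: each neighbour contributes a ternary
#' digit (0 = lower by more than `epsilon`, 1 = within `epsilon`, 2 = higher
#' by more than `epsilon`), giving a code in `[0, 3^8)`. Border pixels are
#' NA.
#'
#' @param img Numeric matrix, at least 3x3.
#' @param epsilon Nonnegative equality tolerance.
#' @return A `tcn_map`: integer code matrix (`codes`), `within_count`
#'   (per-pixel number of "within epsilon" neighbours) and `epsilon`.
#' @export
tcn_encode <- function(img, epsilon) {
  if (nrow(img) < 3 || ncol(img) < 3) stop("TCN needs a region of at least 3x3")
  if (epsilon < 0) stop("epsilon must be nonnegative")
  st <- shift_stack3(img)
  nb <- function(dz, dx) st[[dz + 2]][[dx + 2]]
  # clockwise from north: N, NE, E, SE, S, SW, W, NW
  offs <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  codes <- matrix(0, nrow(img), ncol(img))
  within <- matrix(0L, nrow(img), ncol(img))
  for (k in seq_along(offs)) {
    d <- nb(offs[[k]][1], offs[[k]][2]) - img
    t_k <- ifelse(d > epsilon, 2L, ifelse(d < -epsilon, 0L, 1L))
    within <- within + (t_k == 1L)
    codes <- codes + t_k * 3^(k - 1)
  }
  codes[c(1, nrow(img)), ] <- NA
  codes[, c(1, ncol(img))] <- NA
  within[c(1, nrow(img)), ] <- NA
  within[, c(1, ncol(img))] <- NA
  structure(list(codes = codes, within_count = within, epsilon = epsilon),
            class = "tcn_map")
}

#' Coarseness and homogeneity from a TCN map
#'
#' Homogeneity is the sum of squared bin frequencies of the normalized code
#' histogram (1 for a constant texture); coarseness is the mean fraction of
#' "within epsilon" neighbours per pixel (1 when every neighbourhood is
#' flat, 0 for continuous i.i.d. noise at `epsilon = 0`).
#'
#' @param map A `tcn_map` from [tcn_encode()].
#' @param mask Optional logical matrix restricting the region.
#' @return List `coarseness`, `homogeneity`.
#' @export
tcn_stats <- function(map, mask = NULL) {
  sel <- !is.na(map$codes)
  if (!is.null(mask)) sel <- sel & mask
  codes <- map$codes[sel]
  if (!length(codes)) stop("no interior pixels in region for TCN statistics")
  h <- table(codes) / length(codes)
  list(coarseness = mean(map$within_count[sel]) / 8,
       homogeneity = sum(h^2))
}

#' Gray-level co-occurrence features
#'
#' Intensities are quantized to `levels` equal-width bins over the region's
#' range; the co-occurrence matrix counts horizontally adjacent in-mask
#' pairs (offset (0, 1)), symmetrized and normalized to `P`. Contrast is
#' `sum((i - j)^2 * P)`, energy `sum(P^2)` and correlation the normalized
#' covariance of the level marginals.
#'
#' @param region Numeric matrix.
#' @param mask Optional logical matrix; pairs need both pixels in-mask.
#' @param levels Number of gray levels (default 16).
#' @return List `contrast`, `energy`, `correlation` (NA with attribute
#'   `degenerate` for a single-level region), `P`.
#' @export
glcm_features <- function(region, mask = NULL, levels = 16L) {
  stopifnot(is.matrix(region), levels >= 2)
  r <- range(region)
  if (r[1] == r[2]) {
    return(list(contrast = 0, energy = 1,
                correlation = structure(NA_real_, degenerate = TRUE),
                P = NULL))
  }
  q <- floor((region - r[1]) / (r[2] - r[1]) * levels)
  q[q == levels] <- levels - 1L
  nx <- ncol(q)
  a <- q[, -nx, drop = FALSE]; b <- q[, -1, drop = FALSE]
  if (!is.null(mask)) {
    ok <- mask[, -nx, drop = FALSE] & mask[, -1, drop = FALSE]
  } else ok <- matrix(TRUE, nrow(a), ncol(a))
  if (sum(ok) < 2) stop("need at least 2 in-mask pixel pairs for GLCM")
  C <- table(factor(a[ok], levels = 0:(levels - 1L)),
             factor(b[ok], levels = 0:(levels - 1L)))
  C <- unclass(C) + t(unclass(C))
  P <- C / sum(C)
  ij <- 0:(levels - 1L)
  I <- matrix(ij, levels, levels)
  J <- t(I)
  mu_i <- sum(I * P); mu_j <- sum(J * P)
  s_i <- sqrt(sum((I - mu_i)^2 * P)); s_j <- sqrt(sum((J - mu_j)^2 * P))
  corr <- if (s_i > 0 && s_j > 0) sum((I - mu_i) * (J - mu_j) * P) / (s_i * s_j)
          else structure(NA_real_, degenerate = TRUE)
  list(contrast = sum((I - J)^2 * P), energy = sum(P^2),
       correlation = corr, P = P)
}

#' Extract the 16-entry per-layer feature vector
#'
#' Optical features (attenuation, penetration depth) are fitted per A-line
#' on the raw (linear-intensity) rows inside the region — columns with
#' fewer than 5 in-region rows are skipped — and summarized as mean and
#' standard deviation over columns. Statistical and texture features are
#' computed on the histogram-equalized, median-filtered crop of the region.
#' Distance to surface is the mean axial gap between the region's centre
#' and the surface, in mm. The result is a named vector in [FEATURE_NAMES]
#' order; GLCM correlation is attached as attribute `glcm_correlation`
#' (computed but not part of the 16).
#'
#' @param img Flattened, denoised [bscan] (linear intensity).
#' @param region A [layer_region] in the same frame.
#' @param surface Surface rows in the flattened frame (scalar, vector, or
#'   `surface_profile`).
#' @param params List: `median_kernel` (3), `glcm_levels` (16),
#'   `tcn_epsilon` (fraction of the equalized range, 0.02).
#' @return Named numeric vector of length 16.
#' @export
extract_features <- function(img, region, surface, params = list()) {
  p <- utils::modifyList(list(median_kernel = 3L, glcm_levels = 16L,
                              tcn_epsilon = 0.02), params)
  stopifnot(inherits(img, "bscan"), inherits(region, "layer_region"))
  m <- img$intensity
  nz <- nrow(m); nx <- ncol(m)
  ax_mm <- img$axial_um_per_px / 1000
  up <- pmin(pmax(round(region$upper), 1), nz)
  lo <- pmin(pmax(round(region$lower), 1), nz + 1)

  # per-A-line optical fits
  mus <- pens <- rep(NA_real_, nx)
  for (x in seq_len(nx)) {
    rows <- seq.int(up[x], lo[x] - 1L)
    if (length(rows) < 5) next
    seg <- m[rows, x]
    mus[x] <- attenuation_fit(seg, ax_mm)
    pens[x] <- as.numeric(penetration_depth(seg, ax_mm))
  }
  if (all(is.na(mus))) stop("region too thin for optical features at every column")

  # equalized crop + mask for statistical/texture features
  top <- min(up); bot <- max(lo) - 1L
  crop <- m[top:bot, , drop = FALSE]
  zi <- matrix(seq.int(top, bot), nrow(crop), nx)
  mask <- zi >= matrix(up, nrow(crop), nx, byrow = TRUE) &
          zi < matrix(lo, nrow(crop), nx, byrow = TRUE)
  eq <- equalize_and_median(crop, median_kernel = p$median_kernel)

  lsf <- local_stat_filters(eq, mask = mask)
  tcn <- tcn_encode(eq, epsilon = p$tcn_epsilon * max(1e-12, diff(range(eq))))
  tst <- tcn_stats(tcn, mask = mask)
  gl <- glcm_features(eq, mask = mask, levels = p$glcm_levels)
  mom <- moments(eq[mask])

  surf <- if (inherits(surface, "surface_profile")) surface$position
          else if (length(surface) == 1) rep(as.numeric(surface), nx)
          else as.numeric(surface)
  dist_mm <- mean((up + lo - 1) / 2 - surf) * ax_mm

  out <- c(
    att_mean = mean(mus, na.rm = TRUE), att_std = stats::sd(mus[!is.na(mus)]),
    pen_depth_mean = mean(pens, na.rm = TRUE),
    pen_depth_std = stats::sd(pens[!is.na(pens)]),
    stdfilt_mean = lsf$stdfilt_mean, stdfilt_std = lsf$stdfilt_std,
    rangefilt_mean = lsf$rangefilt_mean, rangefilt_std = lsf$rangefilt_std,
    entropy = lsf$entropy,
    tcn_coarseness = tst$coarseness, tcn_homogeneity = tst$homogeneity,
    glcm_contrast = gl$contrast, glcm_energy = gl$energy,
    dist_to_surface = dist_mm,
    skewness = unname(mom["skewness"]), kurtosis = unname(mom["kurtosis"]))
  out[!is.finite(out)] <- 0   # single-column regions have undefined std
  stopifnot(identical(names(out), FEATURE_NAMES))
  attr(out, "glcm_correlation") <- as.numeric(gl$correlation)
  out
}
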