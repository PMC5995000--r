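# Preprocessing: denoise, detect the tissue surface, flatten.

#' Denoise a B-scan
#'
#' Methods: `"median"` (2-D median filter, EBImage backend; the default and
#' the fallback the pipeline records when no BM3D plug-in is present),
#' `"none"` (identity), `"bm3d"` (block-matching 3-D collaborative
#' filtering; only available when the user registers an implementation via
#' `options(octlayers.bm3d = function(matrix) matrix)` — otherwise a clear
#' error is raised, never a silent substitution).
#'
#' @param img A [bscan].
#' @param method Denoiser name.
#' @param params List of parameters; for `"median"`, `kernel` (odd window
#'   width in px, default 5).
#' @return A denoised [bscan]; attribute `"denoiser"` records what ran.
#' @export
denoise <- function(img, method = c("median", "none", "bm3d"),
                    params = list()) {
  method <- match.arg(method)
  stopifnot(inherits(img, "bscan"))
  out <- switch(method,
    none = img$intensity,
    median = {
      kernel <- if (is.null(params$kernel)) 5L else as.integer(params$kernel)
      if (kernel %% 2 != 1 || kernel < 1) stop("median kernel must be odd and >= 1")
      if (kernel == 1) img$intensity else median_filter2(img$intensity, kernel)
    },
    bm3d = {
      fn <- getOption("octlayers.bm3d")
      if (!is.function(fn))
        stop("BM3D denoiser is not available in this installation; ",
             "register one with options(octlayers.bm3d = fn) or use ",
             "method = 'median' as the fallback")
      fn(img$intensity)
    })
  res <- bscan(out, img$axial_um_per_px, img$lateral_um_per_px, img$id)
  attr(res, "denoiser") <- method
  res
}

# running median of width 5 with replicated ends (NAs ignored)
running_median5 <- function(v) {
  n <- length(v)
  vapply(seq_len(n), function(i) {
    w <- v[max(1, i - 2):min(n, i + 2)]
    stats::median(w, na.rm = TRUE)
  }, numeric(1))
}

# 2-D median filter on an arbitrary-range matrix.  EBImage::medianFilter
# operates on [0, 1] data at 16-bit resolution; OCT intensities span many
# decades, so the filter runs on a log-compressed copy (the median commutes
# with strictly monotone transforms, so this is the same median at uniform
# relative precision) and is mapped back afterwards.
median_filter2 <- function(m, kernel) {
  r <- range(m)
  if (r[1] == r[2]) return(m)
  d <- r[2] - r[1]
  lg <- log(m - r[1] + d * 1e-9)
  lr <- range(lg)
  norm <- (lg - lr[1]) / (lr[2] - lr[1])
  f <- as.matrix(EBImage::medianFilter(norm, size = (kernel - 1L) %/% 2L))
  exp(f * (lr[2] - lr[1]) + lr[1]) + r[1] - d * 1e-9
}

#' Detect the tissue surface
#'
#' In atrial OCT the endocardial surface is the most hyper-reflective
#' structure, so on every retained (downsampled) A-line the surface is the
#' argmax of intensity along depth (ties broken toward the shallowest row);
#' the full-width profile is linearly interpolated between retained columns.
#'
#' Under speckle an isolated A-line can have its global maximum inside a
#' bright deep structure rather than at the surface; because the true
#' surface varies smoothly, retained positions deviating more than
#' `outlier_px` from the running median of their neighbours are treated
#' like undefined columns and refilled by interpolation. Noise-free images
#' have no such outliers, so detection stays exact there.
#'
#' @param img A (denoised) [bscan].
#' @param downsample_factor Keep every k-th A-line (k >= 1).
#' @param outlier_px Deviation from the local running median (over 5
#'   retained columns) beyond which a position is discarded and refilled.
#' @return A `surface_profile`: list with `position` (per-column axial row,
#'   real px) and `method` metadata.
#' @export
detect_surface <- function(img, downsample_factor = 10L, outlier_px = 15) {
  stopifnot(inherits(img, "bscan"), downsample_factor >= 1)
  m <- img$intensity
  nx <- ncol(m)
  k <- as.integer(downsample_factor)
  cols <- seq(1L, nx, by = k)
  pos <- vapply(cols, function(x) {
    # retained A-line = mean of its column block (antialiased downsampling)
    a <- rowMeans(m[, x:min(nx, x + k - 1L), drop = FALSE])
    if (all(a == 0)) NA_real_ else as.numeric(which.max(a))
  }, numeric(1))
  if (anyNA(pos))
    warning("all-zero A-line(s); surface filled from neighbouring columns")
  if (length(pos) >= 3) {
    med <- running_median5(pos)
    pos[!is.na(pos) & abs(pos - med) > outlier_px] <- NA
  }
  ok <- !is.na(pos)
  if (!any(ok)) stop("surface undefined: image is all zero")
  pos <- stats::approx(cols[ok], pos[ok], xout = cols, rule = 2)$y
  full <- stats::approx(cols, pos, xout = seq_len(nx), rule = 2)$y
  structure(list(position = full,
                 method = list(name = "argmax",
                               downsample_factor = as.integer(downsample_factor))),
            class = "surface_profile")
}

#' Flatten a B-scan on its surface
#'
#' Shifts every column by an integer so the detected surface lands on one
#' common row (the rounded median of the input surface positions). Vacated
#' rows are filled with that column's minimum intensity. Only shifts pixels,
#' so each A-line's multiset of in-tissue values is preserved.
#'
#' @param img A [bscan].
#' @param surface A `surface_profile` from [detect_surface()].
#' @return A `flatten_result`: list with `flattened` ([bscan]), `shifts`
#'   (per-column integer shift applied, positive = moved deeper) and
#'   `surface_row` (the common row).
#' @export
flatten <- function(img, surface) {
  stopifnot(inherits(img, "bscan"), inherits(surface, "surface_profile"))
  m <- img$intensity
  nz <- nrow(m); nx <- ncol(m)
  pos <- surface$position
  if (any(pos < 1 | pos > nz)) stop("surface positions outside image depth")
  target <- as.integer(round(stats::median(pos)))
  shifts <- target - as.integer(round(pos))
  if (any(abs(shifts) >= nz))
    stop("flattening shift would push an entire column out of frame")
  out <- m
  for (x in seq_len(nx)) {
    s <- shifts[x]
    if (s == 0) next
    fill <- min(m[, x])
    col <- m[, x]
    if (s > 0) out[, x] <- c(rep(fill, s), col[seq_len(nz - s)])
    else out[, x] <- c(col[(1 - s):nz], rep(fill, -s))
  }
  structure(list(
    flattened = bscan(out, img$axial_um_per_px, img$lateral_um_per_px, img$id),
    shifts = shifts, surface_row = target),
    class = "flatten_result")
}
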