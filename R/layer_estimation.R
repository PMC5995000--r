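# Layer-information estimation: how many layers, and where (roughly) their
# boundaries sit, from averaged A-lines near the image centre.
#
# Each averaged A-line is log-transformed, so the per-layer exponential decay
# becomes a piecewise-linear trend; a growing-window least-squares fit breaks
# the profile into linear pieces at "changing points", which are pruned and
# then pooled across A-lines by voting.

#' Root mean square deviation
#'
#' `sqrt(mean((fitted - observed)^2))`, the fit-quality score that decides
#' whether a sliding window still sits inside one linear piece.
#'
#' @param observed,fitted Equal-length numeric vectors.
#' @return Nonnegative scalar.
#' @export
rmsd <- function(observed, fitted) {
  if (length(observed) != length(fitted)) stop("length mismatch")
  if (length(observed) < 1) stop("need at least one sample")
  sqrt(mean((fitted - observed)^2))
}

#' Select averaged A-lines around the image centre
#'
#' Picks `n` lateral positions centred on the middle column, adjacent
#' centres `spacing_um` apart (converted to pixels through the lateral
#' spacing); each profile is the mean of `avg_width` neighbouring A-lines
#' and is then log-transformed (lateral averaging in linear intensity
#' suppresses speckle before the log).
#'
#' @param img A flattened, denoised [bscan].
#' @param n Number of profiles (odd recommended).
#' @param spacing_um Centre-to-centre spacing in micrometres.
#' @param avg_width Number of A-lines averaged per profile.
#' @param log_transform Take the natural log of the averaged profile?
#' @return List of `averaged_aline` objects: `values`, `center_column`,
#'   `n_averaged`.
#' @export
select_averaged_alines <- function(img, n = 5L, spacing_um = 200,
                                   avg_width = 20L, log_transform = TRUE) {
  stopifnot(inherits(img, "bscan"), n >= 1, avg_width >= 1)
  nx <- ncol(img$intensity)
  spacing_px <- round(um_to_px(spacing_um, img$lateral_um_per_px))
  center <- floor(nx / 2)
  hw <- floor(avg_width / 2)
  offsets <- function(k) (seq_len(k) - (k + 1) / 2) * spacing_px
  centers <- center + offsets(n)
  while (n > 1 && (min(centers) - hw < 1 || max(centers) + hw > nx)) {
    n <- n - 2L
    if (n < 1) n <- 1L
    warning("image too narrow for requested A-line layout; reduced to n = ", n)
    centers <- center + offsets(n)
  }
  if (min(centers) - hw < 1 || max(centers) + hw > nx)
    stop("image too narrow for even one averaged A-line")
  lapply(centers, function(cc) {
    cols <- (cc - hw):(cc - hw + avg_width - 1L)
    v <- rowMeans(img$intensity[, cols, drop = FALSE])
    if (log_transform) v <- log(pmax(v, 1e-12))
    structure(list(values = v, center_column = as.integer(cc),
                   n_averaged = as.integer(avg_width)),
              class = "averaged_aline")
  })
}

# OLS line fit over x = 1..n; returns fitted values
ls_line <- function(y) {
  n <- length(y)
  x <- seq_len(n)
  xb <- (n + 1) / 2
  sxx <- sum((x - xb)^2)
  b <- if (sxx > 0) sum((x - xb) * (y - mean(y))) / sxx else 0
  mean(y) + b * (x - xb)
}

#' Piecewise-linear fit of an averaged A-line
#'
#' Starting from the profile maximum (the first anchor, normally the tissue
#' surface), fits a line inside a growing window: while the window's RMSD
#' stays below `rmsd_threshold` the window is extended by `extend_by`
#' pixels; when it exceeds the threshold the window end is recorded as a
#' changing point and a new anchor is placed one `anchor_offset` beyond it.
#' The number of layers is the number of linear pieces.
#'
#' @param aline An `averaged_aline` (or bare numeric profile).
#' @param init_window Initial window length in pixels.
#' @param extend_by Window growth per accepted iteration.
#' @param rmsd_threshold Break threshold; default 0.06 x the profile's
#'   dynamic range (calibrated so clean single slopes pass and slope breaks
#'   fail; see the methods vignette).
#' @param anchor_offset Gap between a changing point and the next anchor.
#' @param skip_below_anchor Offset (px) between the first anchor and the
#'   start of the first window. The profile maximum is the specular surface
#'   peak, which is not part of the first layer's decay; starting the fit a
#'   few pixels below it keeps the peak from polluting the first piece.
#' @return A `changing_point_set`: `points` (sorted changing-point rows),
#'   `anchor` (first anchor row), `n_layers` (= linear pieces).
#' @export
piecewise_linear_fit <- function(aline, init_window = 10L, extend_by = 3L,
                                 rmsd_threshold = NULL,
                                 anchor_offset = init_window,
                                 skip_below_anchor = 6L) {
  values <- if (inherits(aline, "averaged_aline")) aline$values else as.numeric(aline)
  N <- length(values)
  stopifnot(N > init_window, extend_by >= 1)
  if (is.null(rmsd_threshold))
    rmsd_threshold <- 0.06 * diff(range(values))
  if (!isTRUE(rmsd_threshold > 0)) stop("rmsd_threshold must be positive")

  anchor <- which.max(values)
  points <- integer(0)
  a <- anchor + as.integer(skip_below_anchor)
  while (a + init_window - 1L <= N) {
    e <- a + init_window - 1L
    repeat {
      win <- values[a:e]
      if (rmsd(win, ls_line(win)) >= rmsd_threshold) {
        # a break too close to the profile end leaves no room to fit
        # another layer; treat it as the end of the final piece instead
        if (e > N - init_window) { a <- N + 1L; break }
        points <- c(points, e)
        a <- e + anchor_offset
        break
      }
      if (e >= N) { a <- N + 1L; break }   # final piece reached the end
      e <- min(N, e + extend_by)
    }
  }
  changing_point_set(points, anchor)
}

#' @rdname piecewise_linear_fit
#' @param points Sorted changing-point rows.
#' @param anchor Row of the profile maximum.
#' @export
changing_point_set <- function(points, anchor) {
  points <- as.integer(sort(points))
  if (any(points <= anchor)) stop("changing points must lie deeper than the anchor")
  structure(list(points = points, anchor = as.integer(anchor),
                 n_layers = length(points) + 1L),
            class = "changing_point_set")
}

#' Prune changing points
#'
#' Two rules: (1) any two neighbouring points closer than `min_sep` pixels
#' are replaced by their midpoint (rounding half-down), iterated until
#' stable; (2) a point within `peak_std_window` pixels of the anchor whose
#' local intensity standard deviation exceeds `peak_std_factor` times the
#' profile-wide standard deviation is deleted — such points are artifacts of
#' the bright, high-variance specular peak, not layer boundaries.
#'
#' @param cps A `changing_point_set`.
#' @param min_sep Minimum separation in pixels.
#' @param profile The profile the points were fitted on (numeric vector);
#'   needed for the peak rule, optional otherwise.
#' @param peak_std_window Reach (px) of the peak-deletion rule and width of
#'   its local window.
#' @param peak_std_factor Multiplier on the profile-wide standard deviation.
#' @return A pruned `changing_point_set` (idempotent; never adds points).
#' @export
prune_changing_points <- function(cps, min_sep = 30L, profile = NULL,
                                  peak_std_window = 10L, peak_std_factor = 1.5) {
  pts <- cps$points
  if (!is.null(profile) && length(pts)) {
    N <- length(profile)
    sd_all <- stats::sd(profile)
    hw <- max(1L, peak_std_window %/% 2L)
    keep <- vapply(pts, function(p) {
      if (abs(p - cps$anchor) > peak_std_window) return(TRUE)
      loc <- stats::sd(profile[max(1, p - hw):min(N, p + hw)])
      !(is.finite(loc) && loc > peak_std_factor * sd_all)
    }, logical(1))
    pts <- pts[keep]
  }
  repeat {
    if (length(pts) < 2) break
    gaps <- diff(pts)
    i <- which(gaps < min_sep)
    if (!length(i)) break
    i <- i[1]
    mid <- as.integer(ceiling((pts[i] + pts[i + 1]) / 2 - 0.5))  # half-down
    pts <- sort(c(pts[-c(i, i + 1)], mid))
  }
  changing_point_set(pts, cps$anchor)
}

#' Vote layer information across A-lines
#'
#' The global number of layers is the mode of the per-A-line layer counts
#' (ties broken toward the smaller count, favouring under-segmentation);
#' each initial boundary point is the median changing-point depth across the
#' A-lines that voted for the winning count.
#'
#' @param per_aline List of `changing_point_set`s, one per averaged A-line.
#' @return A `layer_info`: `n_layers`, `initial_points` (length
#'   `n_layers - 1`), `votes` (the inputs, for provenance).
#' @export
vote_layer_info <- function(per_aline) {
  stopifnot(length(per_aline) >= 1)
  counts <- vapply(per_aline, function(cp) cp$n_layers, integer(1))
  tab <- table(counts)
  winners <- as.integer(names(tab)[tab == max(tab)])
  n_layers <- min(winners)
  voters <- per_aline[counts == n_layers]
  initial <- if (n_layers > 1) {
    vapply(seq_len(n_layers - 1L), function(j)
      stats::median(vapply(voters, function(cp) as.numeric(cp$points[j]), numeric(1))),
      numeric(1))
  } else numeric(0)
  structure(list(n_layers = n_layers, initial_points = initial,
                 votes = per_aline),
            class = "layer_info")
}

#' Estimate layer information for a B-scan
#'
#' Convenience wrapper: averaged A-lines, piecewise-linear fit, pruning, and
#' the vote, with all stage parameters in one list.
#'
#' @param img Flattened, denoised [bscan].
#' @param params List: `n_alines`, `spacing_um`, `avg_width`, `init_window`,
#'   `extend_by`, `rmsd_threshold`, `min_sep`, `peak_std_window`,
#'   `peak_std_factor`. Missing entries take the operation defaults.
#' @return A `layer_info`.
#' @export
estimate_layer_info <- function(img, params = list()) {
  p <- utils::modifyList(list(
    n_alines = 5L, spacing_um = 200, avg_width = 20L,
    init_window = 10L, extend_by = 3L, rmsd_threshold = NULL,
    skip_below_anchor = 6L,
    min_sep = 30L, peak_std_window = 10L, peak_std_factor = 1.5), params)
  alines <- select_averaged_alines(img, n = p$n_alines,
                                   spacing_um = p$spacing_um,
                                   avg_width = p$avg_width)
  cps <- lapply(alines, function(al) {
    fit <- piecewise_linear_fit(al, init_window = p$init_window,
                                extend_by = p$extend_by,
                                rmsd_threshold = p$rmsd_threshold,
                                skip_below_anchor = p$skip_below_anchor)
    prune_changing_points(fit, min_sep = p$min_sep, profile = al$values,
                          peak_std_window = p$peak_std_window,
                          peak_std_factor = p$peak_std_factor)
  })
  vote_layer_info(cps)
}
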