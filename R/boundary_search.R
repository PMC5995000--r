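# Greedy column-wise boundary search over a three-term cost map.
#
# A boundary pixel should have (1) a high positive axial gradient, (2) a
# high intensity, and (3) lie close to the initial changing points from the
# layer-information stage.  The combined cost is
#     c(x, z) = c1 * g(x, z) + c2 * i(x, z) + c3 * p(x, z),  c1+c2+c3 = 1,
# and each boundary is traced from the centre column outward, taking at
# every new column the argmax of cost within +-delta_z of the previous
# column's row.

#' Build cost maps for boundary search
#'
#' The working image is the log intensity (per-layer exponential decay turns
#' linear, and boundary jumps become offsets). `g` is the positive part of
#' the axial (row-wise backward) derivative rescaled to \[0, 1\]; `i` is the
#' log intensity rescaled to \[0, 1\]; `p` is the axial shape prior from
#' [shape_prior()] broadcast over columns. Default weights (0.56, 0.38,
#' 0.06) follow the gradient-dominant setting used for atrial B-scans.
#'
#' @param img Flattened, denoised [bscan].
#' @param layer_info A `layer_info` (or numeric vector of initial boundary
#'   rows) giving the interior changing points.
#' @param weights Numeric triple (c1, c2, c3), nonnegative, summing to 1.
#' @param prior_floor Minimum value of the shape prior.
#' @param log_scale Build the maps on log intensity (default) or raw.
#' @return A `cost_maps` object: `g`, `i`, `p`, `cost`, `weights`.
#' @export
build_cost_maps <- function(img, layer_info, weights = c(0.56, 0.38, 0.06),
                            prior_floor = 0.1, log_scale = TRUE) {
  stopifnot(inherits(img, "bscan"), length(weights) == 3)
  if (any(weights < 0)) stop("cost weights must be nonnegative")
  if (abs(sum(weights) - 1) > 1e-9) stop("cost weights must sum to 1")
  pts <- if (inherits(layer_info, "layer_info")) layer_info$initial_points
         else as.numeric(layer_info)
  m <- img$intensity
  W <- if (log_scale) log(pmax(m, 1e-12)) else m
  nz <- nrow(W)
  g <- rbind(0, W[-1, , drop = FALSE] - W[-nz, , drop = FALSE])
  g[g < 0] <- 0
  if (max(g) > 0) g <- g / max(g)
  i <- (W - min(W)) / max(1e-12, diff(range(W)))
  pcol <- shape_prior(pts, nz, floor = prior_floor)
  p <- matrix(pcol, nz, ncol(W))
  structure(list(g = g, i = i, p = p,
                 cost = weights[1] * g + weights[2] * i + weights[3] * p,
                 weights = weights),
            class = "cost_maps")
}

#' Axial shape prior from initial boundary points
#'
#' Value 1 exactly at each initial point, decaying linearly (triangular)
#' with axial distance to a strictly positive floor, attaining its minimum
#' midway between adjacent points. With no points the prior is uniformly 1.
#'
#' @param initial_points Sorted axial rows (may be empty).
#' @param depth_px Profile length.
#' @param floor Minimum prior value in (0, 1).
#' @param outer_halfwidth Decay half-width (px) used above the first and
#'   below the last point (where there is no midpoint); default 30.
#' @return Numeric vector of length `depth_px` in `[floor, 1]`.
#' @export
shape_prior <- function(initial_points, depth_px, floor = 0.1,
                        outer_halfwidth = 30) {
  stopifnot(depth_px >= 1, floor > 0, floor < 1)
  pts <- sort(as.numeric(initial_points))
  if (!length(pts)) return(rep(1, depth_px))
  z <- seq_len(depth_px)
  d <- vapply(z, function(zz) min(abs(zz - pts)), numeric(1))
  # local decay scale: half the gap to the neighbouring point, or the outer
  # half-width beyond the first/last point
  halfgap <- function(zz) {
    below <- pts[pts <= zz]; above <- pts[pts >= zz]
    if (length(below) && length(above) && max(below) < min(above))
      (min(above) - max(below)) / 2
    else outer_halfwidth
  }
  L <- vapply(z, halfgap, numeric(1))
  L[L <= 0] <- outer_halfwidth
  pmax(floor, 1 - (1 - floor) * d / L)
}

#' Greedy per-column boundary search
#'
#' Starting from `start` (column, row), first refines the start row to the
#' cost argmax within `+-delta_z` of the given row, then walks rightward and
#' leftward: at each new column the boundary row is the argmax of cost
#' within `+-delta_z` of the previous column's row (window clipped at the
#' image edge, never wrapped; ties go to the shallower row).
#'
#' @param cost Cost matrix (rows = depth) or a `cost_maps` object.
#' @param start Length-2 vector `c(column, row)`.
#' @param delta_z Half-width of the search window (>= 0).
#' @return Integer vector of boundary rows, one per column.
#' @export
search_boundary <- function(cost, start, delta_z = 5L) {
  if (inherits(cost, "cost_maps")) cost <- cost$cost
  nz <- nrow(cost); nx <- ncol(cost)
  x0 <- as.integer(start[1]); z0 <- as.integer(start[2])
  stopifnot(x0 >= 1, x0 <= nx, z0 >= 1, z0 <= nz, delta_z >= 0, delta_z < nz)
  step <- function(prev) {
    lo <- max(1L, prev - delta_z); hi <- min(nz, prev + delta_z)
    lo + which.max(cost[lo:hi, x]) - 1L
  }
  rows <- integer(nx)
  # refine the start row within the same window
  x <- x0
  rows[x0] <- step(z0)
  if (x0 < nx) for (x in (x0 + 1L):nx) rows[x] <- step(rows[x - 1L])
  if (x0 > 1) for (x in (x0 - 1L):1L) rows[x] <- step(rows[x + 1L])
  rows
}

#' Segment a B-scan into layers
#'
#' Runs one greedy search per interior changing point on the shared cost
#' map, prepends the surface as boundary 1, enforces the non-crossing
#' invariant by clamping (`boundary_k + 1 <= boundary_{k+1}` at every
#' column), and merges any boundary that collapses onto its neighbour over
#' more than half the columns (with a warning; the layer count drops).
#'
#' @param img Flattened, denoised [bscan].
#' @param layer_info A `layer_info` from [estimate_layer_info()].
#' @param surface Surface rows in the flattened frame: a `surface_profile`,
#'   a single row, or a per-column vector.
#' @param params List: `delta_z` (default 5), `weights`, `prior_floor`,
#'   `start_column` (default centre).
#' @return List with `boundaries` (a [boundary_set]), `regions` (list of
#'   [layer_region]) and `cost_maps`.
#' @export
segment_layers <- function(img, layer_info, surface, params = list()) {
  p <- utils::modifyList(list(delta_z = 5L, weights = c(0.56, 0.38, 0.06),
                              prior_floor = 0.1, start_column = NULL), params)
  m <- img$intensity
  nz <- nrow(m); nx <- ncol(m)
  surf <- if (inherits(surface, "surface_profile")) surface$position
          else if (length(surface) == 1) rep(as.numeric(surface), nx)
          else as.numeric(surface)
  stopifnot(length(surf) == nx)
  start_col <- if (is.null(p$start_column)) max(1L, nx %/% 2L) else as.integer(p$start_column)

  pts <- layer_info$initial_points
  bounds <- list(surf)
  if (length(pts)) {
    cm <- build_cost_maps(img, layer_info, weights = p$weights,
                          prior_floor = p$prior_floor)
    for (z0 in pts) {
      z0 <- min(max(round(z0), 1), nz)
      bounds[[length(bounds) + 1L]] <-
        as.numeric(search_boundary(cm, c(start_col, z0), delta_z = p$delta_z))
    }
  } else cm <- NULL

  # order boundaries by mean depth, then clamp to enforce non-crossing
  if (length(bounds) > 1) {
    ord <- order(vapply(bounds, mean, numeric(1)))
    bounds <- bounds[ord]
    for (k in 2:length(bounds))
      bounds[[k]] <- pmin(pmax(bounds[[k]], bounds[[k - 1]] + 1), nz)
    # merge boundaries that collapsed onto their neighbour
    keep <- rep(TRUE, length(bounds))
    for (k in 2:length(bounds)) {
      touching <- mean(bounds[[k]] - bounds[[k - 1]] <= 1)
      if (touching > 0.5) {
        warning("boundaries ", k - 1, " and ", k,
                " collapsed over >50% of columns; merged")
        keep[k] <- FALSE
      }
    }
    bounds <- bounds[keep]
  }
  bs <- boundary_set(bounds, nx)
  list(boundaries = bs,
       regions = regions_from_boundaries(bs, nz, img$id),
       cost_maps = cm)
}
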