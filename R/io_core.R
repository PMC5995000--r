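# Core containers and I/O shared by every pipeline stage.
#
# Coordinate conventions (used consistently everywhere):
#   * intensity matrices are indexed [z, x]: row = axial depth, column =
#     lateral position; row 1 is the shallowest sample (closest to the probe)
#   * boundary positions are 1-based axial row indices, real-valued
#     (sub-pixel positions are allowed after smoothing)
#   * layer k occupies the half-open row interval [upper, lower) at each
#     column; rasterization rounds half-up (round())

#' Tissue class vocabulary
#'
#' The five atrial tissue compositions the classifier distinguishes, in the
#' canonical order used for confusion matrices and one-vs-rest submodels.
#'
#' @format Character vector of length 5.
#' @export
TISSUE_CLASSES <- c(
  "normal_myocardium", "loose_collagen", "adipose",
  "fibrotic_myocardium", "dense_collagen"
)

#' Construct a B-scan
#'
#' A B-scan is a 2-D cross-sectional OCT image: a grid of backscattered
#' intensity indexed `[z, x]` (axial row, lateral column) with physical
#' pixel spacings in micrometres.
#'
#' @param intensity Numeric matrix, rows = axial depth, columns = lateral.
#' @param axial_um_per_px Axial pixel spacing in micrometres (> 0).
#' @param lateral_um_per_px Lateral pixel spacing in micrometres (> 0).
#' @param id Identifier string.
#' @return An object of class `bscan`.
#' @export
bscan <- function(intensity, axial_um_per_px, lateral_um_per_px, id = "bscan") {
  stopifnot(is.matrix(intensity), all(is.finite(intensity)))
  if (!isTRUE(axial_um_per_px > 0) || !isTRUE(lateral_um_per_px > 0))
    stop("pixel spacings must be positive")
  structure(
    list(intensity = intensity,
         axial_um_per_px = as.numeric(axial_um_per_px),
         lateral_um_per_px = as.numeric(lateral_um_per_px),
         id = as.character(id)),
    class = "bscan")
}

#' @export
print.bscan <- function(x, ...) {
  cat(sprintf("<bscan '%s'> %d x %d px (%.3g um axial, %.3g um lateral)\n",
              x$id, nrow(x$intensity), ncol(x$intensity),
              x$axial_um_per_px, x$lateral_um_per_px))
  invisible(x)
}

#' Construct a boundary set
#'
#' An ordered collection of per-column axial boundary positions partitioning
#' a B-scan into layers. Boundary 1 is the tissue surface. Each boundary has
#' exactly one position per column and boundaries never cross:
#' `boundary[k] < boundary[k + 1]` at every column.
#'
#' @param boundaries List of numeric vectors (one per boundary), each of
#'   length `n_columns`, shallow to deep.
#' @param n_columns Number of image columns.
#' @return An object of class `boundary_set`.
#' @export
boundary_set <- function(boundaries, n_columns = length(boundaries[[1]])) {
  stopifnot(is.list(boundaries), length(boundaries) >= 1)
  for (b in boundaries) {
    if (length(b) != n_columns) stop("each boundary needs one position per column")
    if (!all(is.finite(b))) stop("boundary positions must be finite")
  }
  if (length(boundaries) > 1) {
    for (k in seq_len(length(boundaries) - 1)) {
      if (!all(boundaries[[k]] < boundaries[[k + 1]]))
        stop("boundaries must be strictly ordered in depth at every column")
    }
  }
  structure(list(boundaries = boundaries, n_columns = n_columns),
            class = "boundary_set")
}

#' Construct a layer region
#'
#' The half-open band of pixels `[upper, lower)` between two boundaries at
#' every column of one B-scan.
#'
#' @param bscan_id Identifier of the parent B-scan.
#' @param upper,lower Per-column axial positions; `upper < lower` everywhere.
#' @param layer_index 1-based index, 1 = most superficial.
#' @return An object of class `layer_region`.
#' @export
layer_region <- function(bscan_id, upper, lower, layer_index) {
  stopifnot(length(upper) == length(lower))
  if (!all(upper < lower)) stop("layer region empty: upper must be < lower at every column")
  structure(list(bscan_id = bscan_id, upper = upper, lower = lower,
                 layer_index = as.integer(layer_index)),
            class = "layer_region")
}

#' Per-layer class labels over a boundary set
#'
#' @param classes Character vector of tissue classes, one per layer, drawn
#'   from [TISSUE_CLASSES].
#' @param pixel_map Optional per-pixel class image (integer matrix indexing
#'   into `classes`, NA outside tissue).
#' @return An object of class `label_map`.
#' @export
label_map <- function(classes, pixel_map = NULL) {
  if (!all(classes %in% TISSUE_CLASSES))
    stop("unknown tissue class; see TISSUE_CLASSES")
  structure(list(classes = classes, pixel_map = pixel_map), class = "label_map")
}

#' Convert pixels to micrometres and back
#'
#' Exact linear scaling between pixel and physical units; the two functions
#' compose to the identity.
#'
#' @param value_px,value_um Quantity in pixels / micrometres.
#' @param spacing_um_per_px Pixel spacing in micrometres per pixel (> 0).
#' @return Numeric vector in the other unit.
#' @export
px_to_um <- function(value_px, spacing_um_per_px) {
  if (!isTRUE(all(spacing_um_per_px > 0))) stop("spacing must be positive")
  value_px * spacing_um_per_px
}

#' @rdname px_to_um
#' @export
um_to_px <- function(value_um, spacing_um_per_px) {
  if (!isTRUE(all(spacing_um_per_px > 0))) stop("spacing must be positive")
  value_um / spacing_um_per_px
}

# ---------------------------------------------------------------------------
# Volume I/O.  Two on-disk formats:
#   tiff_stack  : multi-page 32-bit float TIFF (values scaled into [0,1])
#                 plus a JSON sidecar <path>.json holding spacings and the
#                 intensity scale factor.  Round-trips to ~1e-7 relative.
#   raw_sidecar : little-endian binary doubles plus the same JSON sidecar;
#                 round-trips bit-identically.

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stop("metadata sidecar not found: ", sp)
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  for (key in c("axial_um_per_px", "lateral_um_per_px")) {
    if (is.null(meta[[key]]) || !is.finite(as.numeric(meta[[key]])))
      stop("sidecar is missing required spacing metadata: ", key)
  }
  meta
}

#' Write / read a stack of B-scans
#'
#' `write_volume()` stores a list of [bscan] objects either as a multi-page
#' 32-bit float TIFF or as raw binary doubles, always with a JSON sidecar
#' (`<path>.json`) recording pixel spacings, grid shape and the intensity
#' scale. `read_volume()` reverses it; a missing or incomplete sidecar is an
#' error, never a silent default.
#'
#' The raw format round-trips bit-identically; the TIFF format at 32-bit
#' float precision (relative error below 1e-6).
#'
#' @param volume List of [bscan] objects with identical shape and spacings.
#' @param path Output path (the sidecar is written next to it).
#' @param format `"tiff_stack"` or `"raw_sidecar"`.
#' @return `write_volume()` the path, invisibly; `read_volume()` a list of
#'   [bscan] objects.
#' @export
write_volume <- function(volume, path, format = c("tiff_stack", "raw_sidecar")) {
  format <- match.arg(format)
  stopifnot(length(volume) >= 1)
  b1 <- volume[[1]]
  meta <- list(
    format = format,
    axial_um_per_px = b1$axial_um_per_px,
    lateral_um_per_px = b1$lateral_um_per_px,
    depth_px = nrow(b1$intensity),
    width_px = ncol(b1$intensity),
    n_bscans = length(volume),
    ids = vapply(volume, function(b) b$id, character(1)))
  if (format == "tiff_stack") {
    scale <- max(1, vapply(volume, function(b) max(b$intensity), numeric(1)))
    meta$intensity_scale <- scale
    pages <- lapply(volume, function(b) b$intensity / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32, compression = "none")
  } else {
    meta$intensity_scale <- 1
    con <- file(path, "wb")
    on.exit(close(con))
    for (b in volume) writeBin(as.vector(b$intensity), con, endian = "little")
  }
  write_sidecar(path, meta)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, format = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  meta <- read_sidecar(path)
  if (is.null(format)) format <- meta$format
  scale <- if (is.null(meta$intensity_scale)) 1 else meta$intensity_scale
  nz <- meta$depth_px; nx <- meta$width_px; nb <- meta$n_bscans
  ids <- if (is.null(meta$ids)) sprintf("bscan_%03d", seq_len(nb)) else meta$ids
  if (identical(format, "tiff_stack")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    mats <- lapply(pages, function(p) p * scale)
  } else if (identical(format, "raw_sidecar")) {
    con <- file(path, "rb")
    on.exit(close(con))
    mats <- lapply(seq_len(nb), function(i)
      matrix(readBin(con, "double", n = nz * nx, endian = "little"), nrow = nz))
  } else stop("unknown volume format: ", format)
  mapply(function(m, id) bscan(m, meta$axial_um_per_px, meta$lateral_um_per_px, id),
         mats, ids[seq_along(mats)], SIMPLIFY = FALSE)
}

#' Write / read boundary sets as CSV
#'
#' One row per image column, one CSV column per boundary (plus a leading
#' column index). Refuses to write a set that violates the non-crossing
#' invariant. Positions round-trip to within 1e-6 px.
#'
#' @param bs A [boundary_set].
#' @param path CSV path.
#' @return `read_boundaries()` returns a [boundary_set].
#' @export
write_boundaries <- function(bs, path) {
  stopifnot(inherits(bs, "boundary_set"))
  # re-validate: objects can be modified after construction
  boundary_set(bs$boundaries, bs$n_columns)
  df <- data.frame(column = seq_len(bs$n_columns))
  for (k in seq_along(bs$boundaries))
    df[[sprintf("boundary_%d", k)]] <- bs$boundaries[[k]]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_boundaries
#' @export
read_boundaries <- function(path) {
  df <- utils::read.csv(path)
  cols <- grep("^boundary_", names(df), value = TRUE)
  boundary_set(lapply(cols, function(cn) df[[cn]]), n_columns = nrow(df))
}

#' Derive layer regions from a boundary set
#'
#' Layer k spans `[boundary_k, boundary_{k+1})`; the deepest layer extends to
#' the bottom of the image.
#'
#' @param bs A [boundary_set].
#' @param depth_px Image depth in pixels.
#' @param bscan_id Identifier recorded on each region.
#' @return List of [layer_region] objects.
#' @export
regions_from_boundaries <- function(bs, depth_px, bscan_id = "bscan") {
  K <- length(bs$boundaries)
  lapply(seq_len(K), function(k) {
    lower <- if (k < K) bs$boundaries[[k + 1]] else rep(depth_px + 1, bs$n_columns)
    layer_region(bscan_id, bs$boundaries[[k]], lower, k)
  })
}
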