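# Synthetic layered-speckle phantoms with exact ground truth.
#
# A phantom B-scan is built in linear intensity: each layer decays
# exponentially with depth below its own top (round-trip single-scattering,
# I = I0 * exp(-2 * mu * dz)), modulated by a per-layer texture field, with a
# thin bright specular band at the tissue surface (the endocardial
# reflection that surface detection keys on) and optional unit-mean
# multiplicative exponential speckle.

#' Describe one phantom tissue layer
#'
#' @param tissue_class One of [TISSUE_CLASSES].
#' @param thickness_px Layer thickness in pixels (> 0).
#' @param base_intensity Linear backscatter intensity at the layer top,
#'   in (0, 1].
#' @param attenuation_mm_inv Attenuation coefficient mu in 1/mm (> 0);
#'   intensity decays as `exp(-2 * mu * depth_mm)` inside the layer.
#' @param texture `"smooth"`, `"granular"` or `"honeycomb"` (the honeycomb
#'   emulates adipose cell walls).
#' @param texture_scale_px Characteristic texture scale: granule correlation
#'   length or honeycomb cell diameter, in pixels.
#' @return A `layer_spec` object.
#' @export
layer_spec <- function(tissue_class, thickness_px, base_intensity,
                       attenuation_mm_inv,
                       texture = c("smooth", "granular", "honeycomb"),
                       texture_scale_px = 8) {
  texture <- match.arg(texture)
  if (!tissue_class %in% TISSUE_CLASSES) stop("unknown tissue class: ", tissue_class)
  stopifnot(thickness_px > 0, base_intensity > 0, base_intensity <= 1,
            is.finite(attenuation_mm_inv), attenuation_mm_inv > 0,
            texture_scale_px >= 1)
  structure(list(tissue_class = tissue_class,
                 thickness_px = as.integer(thickness_px),
                 base_intensity = base_intensity,
                 attenuation_mm_inv = attenuation_mm_inv,
                 texture = texture,
                 texture_scale_px = texture_scale_px),
            class = "layer_spec")
}

#' Default optical/texture presets per tissue class
#'
#' Representative linear-intensity reflectivity, attenuation and texture for
#' each of the five tissue compositions: dense collagen is bright and
#' strongly attenuating, loose collagen dim and weakly attenuating, adipose
#' carries the honeycomb texture, myocardium and fibrotic myocardium sit in
#' between with granular texture of different grain.
#'
#' @param thickness_px Thickness given to every preset layer.
#' @return Named list of [layer_spec] objects, one per tissue class.
#' @export
tissue_presets <- function(thickness_px = 150) {
  list(
    normal_myocardium = layer_spec("normal_myocardium", thickness_px, 0.80, 2.5,
                                   "granular", texture_scale_px = 2),
    loose_collagen = layer_spec("loose_collagen", thickness_px, 0.45, 1.2,
                                "smooth"),
    adipose = layer_spec("adipose", thickness_px, 0.60, 1.8,
                         "honeycomb", texture_scale_px = 12),
    fibrotic_myocardium = layer_spec("fibrotic_myocardium", thickness_px, 0.70, 3.2,
                                     "granular", texture_scale_px = 5),
    dense_collagen = layer_spec("dense_collagen", thickness_px, 0.95, 4.5,
                                "smooth"))
}

#' Configure a synthetic phantom
#'
#' Geometry defaults follow a 4 mm x 2.51 mm field of view sampled on an
#' 800 x 512 grid (5 um lateral, 4.9 um axial per pixel); tests use smaller
#' grids.
#'
#' @param layers Ordered list of [layer_spec] (shallow to deep).
#' @param width_px,depth_px Grid size (columns, rows).
#' @param n_bscans Number of B-scans in the volume.
#' @param surface_profile `"flat"`, `"tilt"` (linear ramp of
#'   `surface_amplitude_px` across the width) or `"sine"` (sinusoid of that
#'   amplitude).
#' @param surface_amplitude_px Peak surface excursion in pixels.
#' @param surface_depth_px Mean surface depth in pixels.
#' @param speckle_on Multiply by unit-mean exponential speckle?
#' @param noise_scale Speckle strength in \[0, 1\]: 0 = noise-free, 1 = fully
#'   developed exponential speckle.
#' @param axial_um_per_px,lateral_um_per_px Pixel spacings (um).
#' @param surface_band_px Thickness of the bright specular band at the
#'   surface (pixels; 0 disables it). The band emulates the strong Fresnel
#'   reflection at the saline/endocardium interface that makes the tissue
#'   surface the most hyper-reflective structure in an atrial B-scan.
#' @param surface_reflectivity Linear intensity of the specular band; above
#'   1 by design so the band outshines any tissue backscatter.
#' @param background_intensity Linear intensity outside the tissue.
#' @param seed Integer seed; all randomness in the generator flows through
#'   one generator derived from it.
#' @return A `phantom_config` object.
#' @export
phantom_config <- function(layers,
                           width_px = 800, depth_px = 512, n_bscans = 1,
                           surface_profile = c("flat", "tilt", "sine"),
                           surface_amplitude_px = 0,
                           surface_depth_px = 40,
                           speckle_on = TRUE, noise_scale = 1,
                           axial_um_per_px = 4.9, lateral_um_per_px = 5,
                           surface_band_px = 5, surface_reflectivity = 2,
                           background_intensity = 0.005,
                           seed = 1L) {
  surface_profile <- match.arg(surface_profile)
  if (inherits(layers, "layer_spec")) layers <- list(layers)
  stopifnot(length(layers) >= 1, all(vapply(layers, inherits, logical(1), "layer_spec")),
            width_px >= 8, depth_px >= 8, n_bscans >= 1,
            noise_scale >= 0, noise_scale <= 1,
            axial_um_per_px > 0, lateral_um_per_px > 0)
  total <- sum(vapply(layers, function(l) l$thickness_px, integer(1)))
  if (total > depth_px - surface_depth_px - surface_amplitude_px)
    stop("layer thicknesses exceed the image depth below the surface")
  structure(list(layers = layers, width_px = as.integer(width_px),
                 depth_px = as.integer(depth_px), n_bscans = as.integer(n_bscans),
                 surface_profile = surface_profile,
                 surface_amplitude_px = surface_amplitude_px,
                 surface_depth_px = surface_depth_px,
                 speckle_on = isTRUE(speckle_on), noise_scale = noise_scale,
                 axial_um_per_px = axial_um_per_px,
                 lateral_um_per_px = lateral_um_per_px,
                 surface_band_px = as.integer(surface_band_px),
                 surface_reflectivity = surface_reflectivity,
                 background_intensity = background_intensity,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# derive a per-bscan sub-seed (kept well under 2^31)
phantom_subseed <- function(seed, bscan_index) {
  (abs(seed) * 7919L + bscan_index * 104729L) %% 2000000011L
}

phantom_surface <- function(config, bscan_index) {
  x <- seq_len(config$width_px)
  base <- config$surface_depth_px
  amp <- config$surface_amplitude_px
  prof <- switch(config$surface_profile,
    flat = rep(0, config$width_px),
    tilt = amp * (x - 1) / max(1, config$width_px - 1),
    sine = amp * sin(2 * pi * (x - 1) / config$width_px +
                       0.02 * (bscan_index - 1)))
  round(base + prof)
}

# texture fields, all with mean ~ 1 --------------------------------------

texture_smooth <- function(nz, nx) matrix(1, nz, nx)

texture_granular <- function(nz, nx, scale) {
  w <- max(1L, as.integer(round(scale)))
  noise <- matrix(stats::rnorm(nz * nx), nz, nx)
  if (w > 1) {
    k <- rep(1 / w, w)
    noise <- apply(noise, 2, function(v) as.numeric(stats::filter(v, k, circular = TRUE)))
    noise <- t(apply(noise, 1, function(v) as.numeric(stats::filter(v, k, circular = TRUE))))
  }
  s <- stats::sd(noise)
  if (s > 0) noise <- noise / s
  pmin(pmax(1 + 0.30 * noise, 0.4), 1.6)
}

# jittered hexagonal lattice: dark cell interiors, bright borders
texture_honeycomb <- function(nz, nx, scale) {
  dy <- scale * sqrt(3) / 2
  nr <- ceiling(nz / dy) + 3L
  nc <- ceiling(nx / scale) + 3L
  jy <- matrix(stats::runif(nr * nc, -0.15, 0.15) * scale, nr, nc)
  jx <- matrix(stats::runif(nr * nc, -0.15, 0.15) * scale, nr, nc)
  z <- matrix(seq_len(nz), nz, nx)
  x <- matrix(seq_len(nx), nz, nx, byrow = TRUE)
  r0 <- round(z / dy)
  d2min <- matrix(Inf, nz, nx)
  for (dr in -1:1) {
    r <- r0 + dr
    cy <- r * dy
    xoff <- 0.5 * scale * (r %% 2)
    c0 <- round((x - xoff) / scale)
    for (dc in -1:1) {
      cc <- c0 + dc
      ri <- pmin(pmax(r + 2L, 1L), nr)
      ci <- pmin(pmax(cc + 2L, 1L), nc)
      idx <- cbind(as.vector(ri), as.vector(ci))
      cyj <- cy + matrix(jy[idx], nz, nx)
      cxj <- cc * scale + xoff + matrix(jx[idx], nz, nx)
      d2 <- (z - cyj)^2 + (x - cxj)^2
      d2min <- pmin(d2min, d2)
    }
  }
  ifelse(sqrt(d2min) < 0.33 * scale, 0.35, 1.25)
}

layer_texture <- function(spec, nz, nx) {
  switch(spec$texture,
         smooth = texture_smooth(nz, nx),
         granular = texture_granular(nz, nx, spec$texture_scale_px),
         honeycomb = texture_honeycomb(nz, nx, spec$texture_scale_px))
}

#' Multiplicative speckle
#'
#' Multiplies an image by a unit-mean speckle field
#' `S = 1 + noise_scale * (E - 1)` with `E ~ Exp(1)`, so the expected
#' pixelwise mean is preserved; `noise_scale = 1` gives fully developed
#' exponential speckle in intensity and `noise_scale = 0` is the identity.
#'
#' @param image Nonnegative numeric matrix.
#' @param noise_scale Speckle strength in \[0, 1\].
#' @param seed Integer seed for the speckle field.
#' @return Matrix of the same shape.
#' @export
apply_speckle <- function(image, noise_scale, seed) {
  if (noise_scale < 0) stop("noise_scale must be nonnegative")
  if (noise_scale > 1) stop("noise_scale above 1 would allow negative intensities")
  if (any(image < 0)) stop("image values must be nonnegative")
  if (noise_scale == 0) return(image)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  S <- 1 + noise_scale * (matrix(stats::rexp(length(image)), nrow(image)) - 1)
  image * S
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate one phantom B-scan with ground truth
#'
#' Noise-free intensity at depth z inside layer l is
#' `base_intensity_l * exp(-2 * mu_l * (z - z_l) * axial_mm_per_px)` times the
#' layer's texture field, with a bright specular band at the surface and a
#' constant dim background outside the tissue. With `speckle_on` the image is
#' multiplied by unit-mean exponential speckle. The returned ground truth
#' matches the construction exactly.
#'
#' @param config A [phantom_config].
#' @param bscan_index 1-based index within the volume (drives the
#'   deterministic per-scan seed and slow surface drift).
#' @return List with elements `bscan` (a [bscan]) and `truth` (list with
#'   `boundaries` = [boundary_set] of surface + interior interfaces,
#'   `labels` = per-layer classes, `seed` = the sub-seed used).
#' @export
generate_bscan <- function(config, bscan_index = 1L) {
  stopifnot(inherits(config, "phantom_config"))
  sub <- phantom_subseed(config$seed, bscan_index)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(sub)

  nz <- config$depth_px; nx <- config$width_px
  ax_mm <- config$axial_um_per_px / 1000
  surface <- phantom_surface(config, bscan_index)
  K <- length(config$layers)
  thick <- vapply(config$layers, function(l) l$thickness_px, integer(1))
  # interface k (k = 1 surface, then interior tops)
  tops <- lapply(seq_len(K), function(k) surface + sum(thick[seq_len(k - 1)]))
  bottoms <- lapply(seq_len(K), function(k) surface + sum(thick[seq_len(k)]))
  if (max(bottoms[[K]]) > nz + 1) stop("layers exceed image depth")

  img <- matrix(config$background_intensity, nz, nx)
  zidx <- matrix(seq_len(nz), nz, nx)
  topm <- lapply(tops, function(t) matrix(t, nz, nx, byrow = TRUE))
  botm <- lapply(bottoms, function(b) matrix(b, nz, nx, byrow = TRUE))
  for (k in seq_len(K)) {
    spec <- config$layers[[k]]
    tex <- layer_texture(spec, nz, nx)
    inlayer <- zidx >= topm[[k]] & zidx < botm[[k]]
    decay <- spec$base_intensity *
      exp(-2 * spec$attenuation_mm_inv * (zidx - topm[[k]]) * ax_mm)
    img[inlayer] <- (decay * tex)[inlayer]
  }
  if (config$surface_band_px > 0) {
    surfm <- matrix(surface, nz, nx, byrow = TRUE)
    band <- zidx >= surfm & zidx < surfm + config$surface_band_px
    img[band] <- config$surface_reflectivity
  }
  if (config$speckle_on && config$noise_scale > 0)
    img <- apply_speckle(img, config$noise_scale, seed = sub + 1L)

  bs <- bscan(img, config$axial_um_per_px, config$lateral_um_per_px,
              id = sprintf("phantom_s%d_b%03d", config$seed, bscan_index))
  truth <- list(
    boundaries = boundary_set(tops, nx),
    labels = vapply(config$layers, function(l) l$tissue_class, character(1)),
    seed = sub)
  list(bscan = bs, truth = truth)
}

#' Generate a phantom volume
#'
#' Applies [generate_bscan()] at indices `1..n_bscans`; boundary geometry
#' varies smoothly (at most 1 px column-wise drift) between consecutive
#' B-scans.
#'
#' @param config A [phantom_config].
#' @return List with `bscans` (list of [bscan]) and `truths` (list of ground
#'   truths as in [generate_bscan()]).
#' @export
generate_volume <- function(config) {
  out <- lapply(seq_len(config$n_bscans), function(i) generate_bscan(config, i))
  list(bscans = lapply(out, `[[`, "bscan"),
       truths = lapply(out, `[[`, "truth"))
}

#' Write a phantom volume with ground truth to disk
#'
#' Writes the image stack (TIFF + sidecar), the ground-truth boundaries and
#' labels as JSON, and the generating configuration as YAML.
#'
#' @param vol Result of [generate_volume()].
#' @param config The generating [phantom_config].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(vol, config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(vol$bscans, file.path(dir, "volume.tif"), "tiff_stack")
  truth <- lapply(vol$truths, function(tr) list(
    boundaries = lapply(tr$boundaries$boundaries, as.integer),
    labels = tr$labels, seed = tr$seed))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg <- unclass(config)
  cfg$layers <- lapply(cfg$layers, unclass)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
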