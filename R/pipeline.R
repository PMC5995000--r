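# Orchestration: segment -> features -> classify over volumes,
# leave-one-group-out evaluation, 3-D boundary smoothing, HSV overlays.

#' Default pipeline configuration
#'
#' Nested list of every stage parameter with its default; deep-merged with
#' user overrides by [merge_config()] and serializable to YAML.
#'
#' @return Named nested list.
#' @export
default_config <- function() {
  list(
    denoise = list(method = "median", params = list(kernel = 5L)),
    surface = list(downsample_factor = 10L),
    layers = list(n_alines = 5L, spacing_um = 200, avg_width = 20L,
                  init_window = 10L, extend_by = 3L, rmsd_threshold = NULL,
                  skip_below_anchor = 6L,
                  min_sep = 30L, peak_std_window = 10L, peak_std_factor = 1.5),
    search = list(delta_z = 5L, weights = c(0.56, 0.38, 0.06),
                  prior_floor = 0.1),
    features = list(median_kernel = 3L, glcm_levels = 16L, tcn_epsilon = 0.02),
    rvm = list(kernel = NULL, max_outer = 200L, tol = 1e-4,
               prune_threshold = 1e12),
    smooth3d = list(kernel = c(3L, 5L)),
    seed = 1L)
}

#' @rdname default_config
#' @param overrides Partial config list to merge over the defaults.
#' @export
merge_config <- function(overrides = list()) {
  utils::modifyList(default_config(), overrides)
}

#' Segment one B-scan end to end
#'
#' Denoise, detect and flatten the surface, estimate layer information and
#' run the boundary search, returning everything downstream stages need.
#'
#' @param bs A [bscan] (linear intensity, unflattened).
#' @param config Pipeline configuration ([default_config()] structure).
#' @return List: `flattened` ([bscan]), `surface_row`, `shifts`,
#'   `layer_info`, `boundaries` ([boundary_set], surface first), `regions`.
#' @export
segment_bscan <- function(bs, config = default_config()) {
  den <- denoise(bs, method = config$denoise$method,
                 params = config$denoise$params)
  surf <- detect_surface(den, config$surface$downsample_factor)
  fl <- flatten(den, surf)
  li <- estimate_layer_info(fl$flattened, config$layers)
  seg <- segment_layers(fl$flattened, li, fl$surface_row,
                        params = config$search)
  list(flattened = fl$flattened, surface_row = fl$surface_row,
       shifts = fl$shifts, layer_info = li,
       boundaries = seg$boundaries, regions = seg$regions)
}

#' Segment and classify a volume
#'
#' Runs [segment_bscan()], [extract_features()] and [rvm_classify()] on
#' every B-scan. A failure in one B-scan is recorded and the pipeline
#' continues with the rest.
#'
#' @param volume List of [bscan] objects.
#' @param model A trained `rvm_multiclass`.
#' @param config Pipeline configuration.
#' @return List per B-scan with `boundaries`, `labels` (a [label_map]),
#'   `features` (layers x 16 matrix), `segment` (full segmentation), or
#'   `error` (message) for failed scans.
#' @export
segment_classify_volume <- function(volume, model, config = default_config()) {
  lapply(volume, function(bs) {
    tryCatch({
      seg <- segment_bscan(bs, config)
      feats <- t(vapply(seg$regions, function(rg)
        extract_features(seg$flattened, rg, seg$surface_row, config$features),
        numeric(16)))
      cls <- rvm_classify(model, feats)
      list(boundaries = seg$boundaries,
           labels = label_map(cls$class),
           probs = cls$probs, features = feats, segment = seg)
    }, error = function(e) list(error = conditionMessage(e), id = bs$id))
  })
}

# 2-D median filter with replicated edges on a plain matrix (small inputs)
median2_small <- function(m, kr, kc) {
  nr <- nrow(m); nc <- ncol(m)
  hr <- kr %/% 2L; hc <- kc %/% 2L
  out <- m
  for (i in seq_len(nr)) {
    rs <- pmin(pmax((i - hr):(i + hr), 1), nr)
    for (j in seq_len(nc)) {
      cs <- pmin(pmax((j - hc):(j + hc), 1), nc)
      out[i, j] <- stats::median(m[rs, cs])
    }
  }
  out
}

#' Median-smooth boundaries across a volume
#'
#' Each boundary is treated as a 2-D surface over (B-scan, column) and
#' median-filtered with the given kernel; the non-crossing invariant is
#' re-enforced afterwards by clamping.
#'
#' @param boundary_sets List of [boundary_set] (one per B-scan, equal
#'   column counts and boundary counts).
#' @param kernel Integer pair `(rows = B-scans, cols = columns)`; odd
#'   values; `(1, 1)` is the identity. Clamped to the stack size with a
#'   warning.
#' @return List of smoothed [boundary_set]s.
#' @export
smooth_3d <- function(boundary_sets, kernel = c(3L, 5L)) {
  stopifnot(length(boundary_sets) >= 1)
  nb <- length(boundary_sets[[1]]$boundaries)
  nx <- boundary_sets[[1]]$n_columns
  ns <- length(boundary_sets)
  if (any(vapply(boundary_sets, function(b) length(b$boundaries), integer(1)) != nb))
    stop("all B-scans must have the same number of boundaries for 3-D smoothing")
  kr <- as.integer(kernel[1]); kc <- as.integer(kernel[2])
  if (kr > ns) { warning("smoothing kernel larger than stack; clamped"); kr <- ns }
  if (kc > nx) { warning("smoothing kernel wider than image; clamped"); kc <- nx }
  surfs <- lapply(seq_len(nb), function(k)
    do.call(rbind, lapply(boundary_sets, function(b) b$boundaries[[k]])))
  sm <- lapply(surfs, median2_small, kr = kr, kc = kc)
  lapply(seq_len(ns), function(s) {
    bl <- lapply(sm, function(srf) srf[s, ])
    if (nb > 1) for (k in 2:nb) bl[[k]] <- pmax(bl[[k]], bl[[k - 1]] + 1)
    boundary_set(bl, nx)
  })
}

#' Leave-one-group-out evaluation
#'
#' For each group (e.g. heart or phantom seed): train a multiclass RVM on
#' all other groups and classify the held-out group; aggregate a confusion
#' matrix (rows = truth, columns = predicted, [TISSUE_CLASSES] order) and
#' the layer-wise accuracy. Held-out layers whose class is absent from the
#' training folds are scored as errors and flagged.
#'
#' @param X Feature matrix (rows = layers).
#' @param labels True tissue classes.
#' @param groups Group identifier per row.
#' @param config Pipeline configuration (the `rvm` block is used).
#' @return List: `confusion` (5x5 integer matrix), `accuracy`,
#'   `per_fold` (data frame of fold records), `flagged` (count of layers
#'   with class absent from training).
#' @export
loo_evaluate <- function(X, labels, groups, config = default_config()) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(labels), length(labels) == length(groups))
  gs <- unique(groups)
  if (length(gs) < 2) stop("need at least 2 groups for leave-one-group-out")
  conf <- matrix(0L, 5, 5, dimnames = list(TISSUE_CLASSES, TISSUE_CLASSES))
  records <- list()
  flagged <- 0L
  for (g in gs) {
    test <- groups == g
    model <- train_multiclass(X[!test, , drop = FALSE], labels[!test],
                              kernel = config$rvm$kernel,
                              max_outer = config$rvm$max_outer,
                              tol = config$rvm$tol,
                              prune_threshold = config$rvm$prune_threshold)
    pred <- rvm_classify(model, X[test, , drop = FALSE])$class
    truth <- labels[test]
    flagged <- flagged + sum(!(truth %in% model$classes))
    for (i in seq_along(truth)) conf[truth[i], pred[i]] <- conf[truth[i], pred[i]] + 1L
    records[[length(records) + 1L]] <- data.frame(
      group = g, n = sum(test), correct = sum(pred == truth))
  }
  per_fold <- do.call(rbind, records)
  list(confusion = conf, accuracy = sum(diag(conf)) / sum(conf),
       per_fold = per_fold, flagged = flagged)
}

#' Class-to-hue table for overlays
#'
#' Dense collagen gold, loose collagen yellow, normal myocardium red,
#' adipose blue, fibrotic myocardium magenta. Hues in \[0, 1\].
#'
#' @return Named numeric vector of hues.
#' @export
class_hues <- function() {
  c(normal_myocardium = 0, loose_collagen = 60 / 360, adipose = 240 / 360,
    fibrotic_myocardium = 300 / 360, dense_collagen = 45 / 360)
}

#' HSV overlay of classified layers on a B-scan
#'
#' Hue encodes each pixel's layer class; saturation and value encode the
#' normalized OCT intensity, so structure stays visible and a zero-intensity
#' pixel is black regardless of class. Pixels outside any labelled layer are
#' rendered grayscale.
#'
#' @param bs A [bscan] (typically the flattened image).
#' @param regions List of [layer_region].
#' @param labels A [label_map] (or character vector) of per-layer classes.
#' @return `depth x width x 3` RGB array in \[0, 1\].
#' @export
hsv_overlay <- function(bs, regions, labels) {
  classes <- if (inherits(labels, "label_map")) labels$classes else labels
  stopifnot(length(classes) == length(regions))
  m <- bs$intensity
  nz <- nrow(m); nx <- ncol(m)
  v <- (m - min(m)) / max(1e-12, diff(range(m)))
  hue <- matrix(NA_real_, nz, nx)
  hue_tab <- class_hues()
  zi <- matrix(seq_len(nz), nz, nx)
  for (k in seq_along(regions)) {
    rg <- regions[[k]]
    inr <- zi >= matrix(rg$upper, nz, nx, byrow = TRUE) &
           zi < matrix(rg$lower, nz, nx, byrow = TRUE)
    hue[inr] <- hue_tab[[classes[k]]]
  }
  out <- array(0, c(nz, nx, 3))
  lab <- !is.na(hue)
  cols_rgb <- grDevices::col2rgb(grDevices::hsv(ifelse(lab, hue, 0),
                                                ifelse(lab, v, 0), v)) / 255
  out[, , 1] <- matrix(cols_rgb[1, ], nz, nx)
  out[, , 2] <- matrix(cols_rgb[2, ], nz, nx)
  out[, , 3] <- matrix(cols_rgb[3, ], nz, nx)
  out
}

#' Build a labelled feature dataset from phantom volumes
#'
#' For each group: generate phantom B-scans, run the full segmentation and
#' feature extraction, and label every estimated layer with the true class
#' of the ground-truth layer containing the region's centre at the centre
#' column. The group id supports leave-one-group-out evaluation.
#'
#' @param layer_sets List of character vectors; group g uses
#'   `layer_sets[[((g - 1) %% length(layer_sets)) + 1]]` as its layer
#'   classes (presets via [tissue_presets()]).
#' @param n_groups Number of groups (one phantom seed each).
#' @param bscans_per_group B-scans generated per group.
#' @param config Pipeline configuration.
#' @param phantom_overrides Named list of [phantom_config()] arguments.
#' @param seed Base seed; group g uses `seed + g`.
#' @return List: `X` (matrix), `labels`, `groups`, `n_failed` (B-scans that
#'   errored out).
#' @export
build_phantom_dataset <- function(layer_sets, n_groups = 10L,
                                  bscans_per_group = 1L,
                                  config = default_config(),
                                  phantom_overrides = list(),
                                  seed = 1L) {
  Xs <- list(); labs <- character(0); grp <- integer(0); failed <- 0L
  for (g in seq_len(n_groups)) {
    classes <- layer_sets[[((g - 1L) %% length(layer_sets)) + 1L]]
    depth <- if (!is.null(phantom_overrides$depth_px)) phantom_overrides$depth_px else 512L
    sdepth <- if (!is.null(phantom_overrides$surface_depth_px)) phantom_overrides$surface_depth_px else 40L
    thick <- (depth - sdepth - 2L) %/% length(classes)
    presets <- tissue_presets(thickness_px = thick)
    args <- utils::modifyList(
      list(layers = unname(presets[classes]), n_bscans = bscans_per_group,
           seed = seed + g),
      phantom_overrides)
    vol <- generate_volume(do.call(phantom_config, args))
    for (b in seq_along(vol$bscans)) {
      res <- tryCatch(segment_bscan(vol$bscans[[b]], config),
                      error = function(e) NULL)
      if (is.null(res)) { failed <- failed + 1L; next }
      truth <- vol$truths[[b]]
      # truth boundaries in the flattened frame
      cx <- max(1L, ncol(vol$bscans[[b]]$intensity) %/% 2L)
      tb <- vapply(truth$boundaries$boundaries,
                   function(bnd) bnd[cx] + res$shifts[cx], numeric(1))
      tops <- c(tb, nrow(vol$bscans[[b]]$intensity) + 1)
      for (k in seq_along(res$regions)) {
        rg <- res$regions[[k]]
        center <- (rg$upper[cx] + rg$lower[cx]) / 2
        li <- findInterval(center, tops, all.inside = TRUE)
        fv <- tryCatch(extract_features(res$flattened, rg, res$surface_row,
                                        config$features),
                       error = function(e) NULL)
        if (is.null(fv)) next
        Xs[[length(Xs) + 1L]] <- fv
        labs <- c(labs, truth$labels[li])
        grp <- c(grp, g)
      }
    }
  }
  list(X = do.call(rbind, Xs), labels = labs, groups = grp, n_failed = failed)
}

#' Write a feature table as CSV
#'
#' One row per (B-scan, layer): ids, group, true label (if any) and the 16
#' feature columns.
#'
#' @param X Feature matrix.
#' @param path CSV path.
#' @param labels,groups,ids Optional per-row annotations.
#' @return The path, invisibly.
#' @export
write_features <- function(X, path, labels = NULL, groups = NULL, ids = NULL) {
  df <- as.data.frame(X)
  names(df) <- FEATURE_NAMES
  if (!is.null(ids)) df <- cbind(id = ids, df)
  if (!is.null(groups)) df <- cbind(group = groups, df)
  if (!is.null(labels)) df <- cbind(label = labels, df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path)
  X <- as.matrix(df[, FEATURE_NAMES])
  list(X = X,
       labels = if ("label" %in% names(df)) df$label else NULL,
       groups = if ("group" %in% names(df)) df$group else NULL,
       ids = if ("id" %in% names(df)) df$id else NULL)
}
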