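# End-to-end pipeline: per slice, preprocess -> initial contour -> hybrid
# curve evolution to the muscle wall -> SAT/VAT side split -> fuzzy
# clustering + region merging per side -> skin/wall stripping -> depot
# labels; then volume/mass quantification over the stack.

#' Pipeline configuration
#'
#' Nested list of every tunable constant of the pipeline, grouped by
#' stage.  `overrides` is a nested list merged over the defaults; unknown
#' keys are rejected so that config files cannot silently misspell a
#' parameter.
#'
#' @param overrides nested list of stage -> parameter overrides.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(overrides = list()) {
  defaults <- list(
    preprocess = list(clip_probs = c(0.005, 0.995), bg_threshold = 0.05,
                      diffusion_iters = 15L, diffusion_kappa = 0.1,
                      diffusion_step = 0.2,
                      conductance_form = "exponential",
                      edge_gain = 0.6, edge_sigma = 1.0),
    init = list(shrink_scale = 0.80, center_mode = "slice_center",
                band_width = 10),
    snake = list(local_radius = 8L, curvature_weight = 0.2,
                 balloon_weight = 0.5, edge_sigma = 1.5, area_tol = 10,
                 check_interval = 5L, max_iters = 500L, step_size = 0.25,
                 reinit_interval = 20L, reinit_iters = 30L,
                 region_epsilon = 1e-6, region_clamp = 1.5),
    fcm = list(sat_classes = 3L, vat_classes = 5L, fuzzifier_m = 2,
               tol = 1e-5, max_iter = 300L, intensity_gap = 0.15,
               pooled = FALSE),
    strip = list(skin_depth = 2, wall_depth = 2),
    quant = list(density = 0.9),
    seed = 1L)
  check_keys <- function(def, ov, path = "") {
    bad <- setdiff(names(ov), names(def))
    if (length(bad))
      stop("unknown config key(s): ",
           paste0(path, bad, collapse = ", "))
    for (nm in names(ov))
      if (is.list(def[[nm]]) && is.list(ov[[nm]]))
        check_keys(def[[nm]], ov[[nm]], paste0(path, nm, "$"))
  }
  check_keys(defaults, overrides)
  cfg <- modifyList(defaults, overrides)
  if (cfg$snake$area_tol <= 0) stop("snake$area_tol must be positive")
  structure(cfg, class = c("pipeline_config", "list"))
}

# memberships for fixed centroids (used in pooled-clustering mode)
fcm_classify <- function(x, centroids, fuzzifier_m = 2) {
  d2 <- outer(x, centroids, function(a, b) (a - b)^2)
  fcm_memberships(d2, 2 / (fuzzifier_m - 1))
}

segment_side <- function(pixels, side_mask, n_classes, cfg,
                         centroids = NULL) {
  vals <- pixels[side_mask]
  if (length(unique(vals)) < n_classes)
    return(list(mask = matrix(FALSE, nrow(pixels), ncol(pixels)),
                fit = NULL))
  if (is.null(centroids)) {
    fit <- fcm(vals, n_classes, fuzzifier_m = cfg$fcm$fuzzifier_m,
               tol = cfg$fcm$tol, max_iter = cfg$fcm$max_iter)
    hard <- harden(fit)
  } else {
    U <- fcm_classify(vals, centroids, cfg$fcm$fuzzifier_m)
    fit <- structure(list(memberships = U, centroids = centroids,
                          objective = numeric(0), n_iters = 0L,
                          fuzzifier_m = cfg$fcm$fuzzifier_m),
                     class = "fcm_fit")
    hard <- harden(fit)
  }
  class_map <- matrix(NA_integer_, nrow(pixels), ncol(pixels))
  class_map[side_mask] <- hard
  mask <- merge_regions(class_map, pixels,
                        intensity_gap = cfg$fcm$intensity_gap)
  list(mask = mask, fit = fit)
}

#' Segment one pre-processed-ready slice
#'
#' Runs the complete per-slice pipeline on raw intensities and returns the
#' depot label matrix together with the intermediate objects (body mask,
#' converged wall contour, evolution trace, FCM fits).
#'
#' @param pixels raw slice matrix.
#' @param config a [pipeline_config].
#' @param sat_centroids,vat_centroids optional fixed FCM centroids (pooled
#'   clustering mode).
#' @return list with `labels` (integer matrix in the depot coding),
#'   `body_mask`, `wall_ls`, `trace`, `sat_fit`, `vat_fit`, `image`.
#' @export
segment_slice <- function(pixels, config = pipeline_config(),
                          sat_centroids = NULL, vat_centroids = NULL) {
  cfg <- config
  pp <- preprocess_slice(pixels, cfg)
  contour <- edge_map(pp$body_mask)
  ip <- init_params(shrink_scale = cfg$init$shrink_scale,
                    center_mode = cfg$init$center_mode)
  phi0 <- shrink_and_place(contour, ip, dim(pixels), mask = pp$body_mask)
  phi0$band_width <- cfg$init$band_width
  sp <- do.call(snake_params,
                cfg$snake[setdiff(names(cfg$snake), character(0))])
  ev <- evolve(pp$image, phi0, sp)
  inside <- ev$ls$phi < 0
  vat_side <- EBImage::fillHull(matrix(as.integer(inside),
                                       nrow(pixels))) > 0
  vat_side <- vat_side & pp$body_mask
  sat_side <- pp$body_mask & !vat_side
  sat <- segment_side(pp$image, sat_side, cfg$fcm$sat_classes, cfg,
                      sat_centroids)
  vat <- segment_side(pp$image, vat_side, cfg$fcm$vat_classes, cfg,
                      vat_centroids)
  # wall-like intensity ceiling: midpoint between the brightest excluded
  # and the dimmest merged SAT-side class (the wall is iso-intense)
  fat_floor <- NULL
  if (!is.null(sat$fit)) {
    cents <- sort(sat$fit$centroids)
    merged_c <- cents[cents >= max(cents) - cfg$fcm$intensity_gap]
    excl_c <- cents[cents < max(cents) - cfg$fcm$intensity_gap]
    fat_floor <- if (length(excl_c)) (max(excl_c) + min(merged_c)) / 2
                 else min(merged_c) - cfg$fcm$intensity_gap
  }
  sat_mask <- tryCatch(
    strip_skin_wall(sat$mask, pp$body_mask, ev$ls,
                    skin_depth = cfg$strip$skin_depth,
                    wall_depth = cfg$strip$wall_depth,
                    pixels = pp$image, fat_floor = fat_floor),
    warning = function(w) sat$mask & FALSE)
  labels <- matrix(LABEL_CODES[["background"]], nrow(pixels), ncol(pixels))
  labels[pp$body_mask] <- LABEL_CODES[["organ"]]
  d_in <- as.matrix(EBImage::distmap(matrix(as.numeric(pp$body_mask),
                                            nrow(pixels))))
  skin_band <- pp$body_mask & d_in <= cfg$strip$skin_depth
  wall_band <- pp$body_mask & abs(ev$ls$phi) < cfg$strip$wall_depth
  if (!is.null(fat_floor))
    wall_band <- wall_band & pp$image < fat_floor
  labels[skin_band | wall_band] <- LABEL_CODES[["skin_wall"]]
  labels[sat_mask] <- LABEL_CODES[["SAT"]]
  labels[vat$mask] <- LABEL_CODES[["VAT"]]
  list(labels = labels, body_mask = pp$body_mask, wall_ls = ev$ls,
       trace = ev$trace, sat_fit = sat$fit, vat_fit = vat$fit,
       image = pp$image)
}

#' Segment a full MR volume into depot labels
#'
#' Applies [segment_slice()] to every selected slice.  In pooled mode the
#' SAT-side and VAT-side intensities of all slices are clustered jointly
#' and the shared centroids are then applied per slice.  Per-slice
#' unrecoverable errors ("contour collapsed", "containment lost") are
#' collected and reported with the slice index.
#'
#' @param volume an [image_volume].
#' @param config a [pipeline_config].
#' @param slices integer indices of the slices to process (default: all).
#' @return an object of class `fat_segmentation`: list with `labels` (a
#'   [depot_labels]), `report` (a [quantify()] report), `traces`,
#'   `sat_fits`, `vat_fits`, `failed_slices`.
#' @export
segment_volume <- function(volume, config = pipeline_config(),
                           slices = NULL) {
  stopifnot(inherits(volume, "image_volume"))
  n_sl <- dim(volume$voxels)[3]
  if (is.null(slices)) slices <- seq_len(n_sl)
  if (any(slices < 1 | slices > n_sl)) stop("slice index out of range")
  d <- dim(volume$voxels)
  lab <- array(LABEL_CODES[["background"]], c(d[1], d[2], length(slices)))
  traces <- vector("list", length(slices))
  sat_fits <- vector("list", length(slices))
  vat_fits <- vector("list", length(slices))
  failed <- character(0)
  sat_cent <- vat_cent <- NULL
  if (isTRUE(config$fcm$pooled)) {
    pooled <- pooled_centroids(volume, config, slices)
    sat_cent <- pooled$sat; vat_cent <- pooled$vat
  }
  for (i in seq_along(slices)) {
    s <- slices[i]
    res <- tryCatch(
      segment_slice(volume$voxels[, , s], config,
                    sat_centroids = sat_cent, vat_centroids = vat_cent),
      error = function(e)
        structure(list(msg = conditionMessage(e)), class = "slice_failure"))
    if (inherits(res, "slice_failure")) {
      failed <- c(failed, sprintf("slice %d: %s", s, res$msg))
      next
    }
    lab[, , i] <- res$labels
    traces[[i]] <- res$trace
    sat_fits[[i]] <- res$sat_fit
    vat_fits[[i]] <- res$vat_fit
  }
  labels <- depot_labels(lab, volume$in_plane_spacing,
                         volume$slice_thickness)
  structure(list(labels = labels,
                 report = quantify(labels, density = config$quant$density),
                 traces = traces, sat_fits = sat_fits, vat_fits = vat_fits,
                 failed_slices = failed, config = config),
            class = "fat_segmentation")
}

# run the geometric part of the pipeline on every slice, pool side voxels,
# and cluster once per side
pooled_centroids <- function(volume, config, slices) {
  sat_vals <- vat_vals <- numeric(0)
  for (s in slices) {
    px <- volume$voxels[, , s]
    pp <- preprocess_slice(px, config)
    contour <- edge_map(pp$body_mask)
    ip <- init_params(shrink_scale = config$init$shrink_scale,
                      center_mode = config$init$center_mode)
    phi0 <- shrink_and_place(contour, ip, dim(px), mask = pp$body_mask)
    sp <- do.call(snake_params, config$snake)
    ev <- evolve(pp$image, phi0, sp)
    vat_side <- EBImage::fillHull(matrix(as.integer(ev$ls$phi < 0),
                                         nrow(px))) > 0
    vat_side <- vat_side & pp$body_mask
    sat_vals <- c(sat_vals, pp$image[pp$body_mask & !vat_side])
    vat_vals <- c(vat_vals, pp$image[vat_side])
  }
  list(sat = fcm(sat_vals, config$fcm$sat_classes,
                 fuzzifier_m = config$fcm$fuzzifier_m,
                 tol = config$fcm$tol,
                 max_iter = config$fcm$max_iter)$centroids,
       vat = fcm(vat_vals, config$fcm$vat_classes,
                 fuzzifier_m = config$fcm$fuzzifier_m,
                 tol = config$fcm$tol,
                 max_iter = config$fcm$max_iter)$centroids)
}

#' @export
print.fat_segmentation <- function(x, ...) {
  cat("Abdominal fat segmentation\n")
  print(x$report)
  ok <- sum(!vapply(x$traces, is.null, logical(1)))
  cat(sprintf("  %d slice(s) segmented", ok))
  if (length(x$failed_slices))
    cat(sprintf(", %d failed:\n    %s", length(x$failed_slices),
                paste(x$failed_slices, collapse = "\n    ")))
  cat("\n")
  invisible(x)
}

#' @export
summary.fat_segmentation <- function(object, ...) {
  print(object)
  for (i in seq_along(object$traces))
    if (!is.null(object$traces[[i]])) {
      cat(sprintf("  slice %d: ", i)); print(object$traces[[i]])
    }
  invisible(object)
}
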