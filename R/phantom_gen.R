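# Synthetic abdominal MR phantom: per slice, an elliptical body with (from
# the outside in) a thin skin line, a hyper-intense SAT ring, an
# iso-intense muscle wall, and an interior of hypo-intense organ tissue
# with hyper-intense VAT blobs; multiplicative low-frequency bias field
# and Rician (or Gaussian) noise on top.  Ground-truth labels are the
# noise-free tissue assignments, so the full pipeline can be validated
# without animal data.

#' Phantom specification
#'
#' Defaults emulate a rodent abdominal FSE slice at coarse resolution:
#' both fat depots hyper-intense, the muscle wall iso-intense between
#' them, organs hypo/iso-intense, dark background.  Ring thicknesses are
#' measured as true pixel depth from the body edge, so they are uniform
#' along the boundary.
#'
#' @param n_slices number of slices.
#' @param image_size image side in px (square slices).
#' @param body_axes ellipse semi-axes (row, col) in px.
#' @param axis_taper per-slice shrink of both semi-axes in px (the body
#'   narrows along the stack).
#' @param skin_thickness,sat_thickness,wall_thickness ring depths in px.
#' @param n_vat_blobs number of circular VAT blobs (a blob column runs
#'   through all slices).
#' @param blob_radius_range min/max blob radius in px.
#' @param intensity_means named means in [0,1] for background, organ,
#'   wall, skin, SAT, VAT; fat must exceed wall, wall exceed organ, organ
#'   be at least background.
#' @param noise_sigma noise scale (Rician by default).
#' @param bias_amplitude amplitude of the multiplicative low-frequency
#'   intensity-inhomogeneity field.
#' @param noise_model `"rician"` or `"gaussian"`.
#' @param skin_fold if TRUE, locally thins the muscle wall to nothing over
#'   an angular sector, reproducing the skin-folding/compression failure
#'   mode in which SAT and VAT are no longer separated by intensity.
#' @param in_plane_spacing,slice_thickness voxel geometry in mm.
#' @param seed RNG seed controlling blob layout, bias phase and noise.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(n_slices = 3L, image_size = 192L,
                         body_axes = c(76, 64), axis_taper = 2,
                         skin_thickness = 2, sat_thickness = 6,
                         wall_thickness = 3, n_vat_blobs = 6L,
                         blob_radius_range = c(6, 10),
                         intensity_means = c(background = 0.05,
                                             organ = 0.35, wall = 0.45,
                                             skin = 0.8, SAT = 0.9,
                                             VAT = 0.85),
                         noise_sigma = 0.03, bias_amplitude = 0.1,
                         noise_model = c("rician", "gaussian"),
                         skin_fold = FALSE,
                         in_plane_spacing = c(0.2, 0.2),
                         slice_thickness = 1.6, seed = 1L) {
  noise_model <- match.arg(noise_model)
  im <- intensity_means
  req <- c("background", "organ", "wall", "skin", "SAT", "VAT")
  if (!all(req %in% names(im)))
    stop("intensity_means must name: ", paste(req, collapse = ", "))
  if (!(im[["SAT"]] > im[["wall"]] && im[["VAT"]] > im[["wall"]]))
    stop("fat means must exceed the wall mean (fat is hyper-intense)")
  if (!(im[["wall"]] > im[["organ"]] && im[["organ"]] >= im[["background"]]))
    stop("means must be ordered wall > organ >= background")
  ring <- skin_thickness + sat_thickness + wall_thickness
  min_ax <- min(body_axes) - axis_taper * (n_slices - 1)
  if (ring + max(blob_radius_range) + 4 >= min_ax)
    stop("rings and blobs do not fit inside the body ellipse")
  if (max(body_axes) + 4 >= image_size / 2)
    stop("body ellipse does not fit inside the image with margin")
  structure(list(n_slices = as.integer(n_slices),
                 image_size = as.integer(image_size),
                 body_axes = body_axes, axis_taper = axis_taper,
                 skin_thickness = skin_thickness,
                 sat_thickness = sat_thickness,
                 wall_thickness = wall_thickness,
                 n_vat_blobs = as.integer(n_vat_blobs),
                 blob_radius_range = blob_radius_range,
                 intensity_means = im, noise_sigma = noise_sigma,
                 bias_amplitude = bias_amplitude,
                 noise_model = noise_model, skin_fold = skin_fold,
                 in_plane_spacing = in_plane_spacing,
                 slice_thickness = slice_thickness,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# deterministic blob layout: centers + radii that fit inside the deepest
# interior of the *narrowest* slice, mutually separated
phantom_blobs <- function(spec) {
  set.seed(spec$seed)
  n <- spec$image_size
  ctr <- (n + 1) / 2
  ring <- spec$skin_thickness + spec$sat_thickness + spec$wall_thickness
  ax <- spec$body_axes - spec$axis_taper * (spec$n_slices - 1)
  blobs <- matrix(numeric(0), 0L, 3L)   # row, col, radius
  tries <- 0L
  while (nrow(blobs) < spec$n_vat_blobs) {
    tries <- tries + 1L
    if (tries > 5000L)
      stop("could not place ", spec$n_vat_blobs, " VAT blobs; relax geometry")
    r <- runif(1, spec$blob_radius_range[1], spec$blob_radius_range[2])
    # sample inside the interior ellipse shrunk by ring depth + radius + margin
    a <- ax[1] - ring - r - 3; b <- ax[2] - ring - r - 3
    if (a <= 0 || b <= 0) next
    u <- runif(1); th <- runif(1, 0, 2 * pi)
    cand <- c(ctr + a * sqrt(u) * sin(th), ctr + b * sqrt(u) * cos(th))
    if (nrow(blobs) > 0) {
      dd <- sqrt((blobs[, 1] - cand[1])^2 + (blobs[, 2] - cand[2])^2)
      if (any(dd < blobs[, 3] + r + 4)) next
    }
    blobs <- rbind(blobs, c(cand, r))
  }
  blobs
}

phantom_bias_field <- function(n, amplitude, phase) {
  if (amplitude == 0) return(matrix(1, n, n))
  xs <- seq_len(n) / n
  1 + amplitude * outer(sin(pi * xs + phase[1]), sin(pi * xs + phase[2]))
}

#' Generate a synthetic abdominal phantom
#'
#' Rasterizes the geometry of `spec` slice by slice, assigns tissue mean
#' intensities, multiplies a low-frequency bias field, adds noise, and
#' returns both the noisy volume and the noise-free ground-truth labels
#' (skin and wall share the `skin_wall` label).  Deterministic per seed.
#'
#' @param spec a [phantom_spec].
#' @param blobs optional fixed blob layout (n x 3 matrix row, col,
#'   radius), used by [make_paired_series()] to rescale a shared anatomy.
#' @return list with `volume` (an [image_volume]) and `labels`
#'   (a [depot_labels]), plus the `blobs` layout used.
#' @export
make_phantom <- function(spec = phantom_spec(), blobs = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(blobs)) blobs <- phantom_blobs(spec)
  set.seed(spec$seed + 1000003L)
  n <- spec$image_size
  ctr <- (n + 1) / 2
  im <- spec$intensity_means
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  vox <- array(0, c(n, n, spec$n_slices))
  lab <- array(LABEL_CODES[["background"]], c(n, n, spec$n_slices))
  bias <- phantom_bias_field(n, spec$bias_amplitude,
                             phase = runif(2, 0, pi))
  fold_angle <- runif(1, 0, 2 * pi)
  for (s in seq_len(spec$n_slices)) {
    ax <- spec$body_axes - spec$axis_taper * (s - 1)
    body <- ((rows - ctr) / ax[1])^2 + ((cols - ctr) / ax[2])^2 <= 1
    depth <- as.matrix(EBImage::distmap(matrix(as.numeric(body), n)))
    t1 <- spec$skin_thickness
    t2 <- t1 + spec$sat_thickness
    t3 <- t2 + spec$wall_thickness
    sl_lab <- matrix(LABEL_CODES[["background"]], n, n)
    sl_lab[body & depth <= t1] <- LABEL_CODES[["skin_wall"]]
    sl_lab[body & depth > t1 & depth <= t2] <- LABEL_CODES[["SAT"]]
    wall_px <- body & depth > t2 & depth <= t3
    if (spec$skin_fold) {
      # erase the wall over a 40-degree sector: SAT and VAT regions touch
      ang <- atan2(rows - ctr, cols - ctr)
      sector <- abs(((ang - fold_angle + pi) %% (2 * pi)) - pi) < (pi / 9)
      sl_lab[wall_px & sector] <- LABEL_CODES[["SAT"]]
      wall_px <- wall_px & !sector
    }
    sl_lab[wall_px] <- LABEL_CODES[["skin_wall"]]
    interior <- body & depth > t3
    sl_lab[interior] <- LABEL_CODES[["organ"]]
    for (bi in seq_len(nrow(blobs))) {
      inblob <- interior &
        (rows - blobs[bi, 1])^2 + (cols - blobs[bi, 2])^2 <= blobs[bi, 3]^2
      sl_lab[inblob] <- LABEL_CODES[["VAT"]]
    }
    means <- c(im[["background"]], im[["SAT"]], im[["VAT"]], 0, im[["organ"]])
    sl_img <- matrix(means[sl_lab + 1L], n, n)
    # skin and wall share a label but not an intensity
    sl_img[body & depth <= t1] <- im[["skin"]]
    sl_img[wall_px] <- im[["wall"]]
    sl_img <- sl_img * bias
    if (spec$noise_sigma > 0) {
      if (spec$noise_model == "rician") {
        n1 <- matrix(rnorm(n * n, 0, spec$noise_sigma), n)
        n2 <- matrix(rnorm(n * n, 0, spec$noise_sigma), n)
        sl_img <- sqrt((sl_img + n1)^2 + n2^2)
      } else {
        sl_img <- sl_img + matrix(rnorm(n * n, 0, spec$noise_sigma), n)
      }
    }
    vox[, , s] <- sl_img
    lab[, , s] <- sl_lab
  }
  list(volume = image_volume(vox, spec$in_plane_spacing,
                             spec$slice_thickness),
       labels = depot_labels(lab, spec$in_plane_spacing,
                             spec$slice_thickness),
       blobs = blobs)
}

# pooled body-edge depths of all in-body voxels across slices
phantom_depths <- function(spec) {
  n <- spec$image_size; ctr <- (n + 1) / 2
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  depths <- numeric(0)
  for (s in seq_len(spec$n_slices)) {
    ax <- spec$body_axes - spec$axis_taper * (s - 1)
    body <- ((rows - ctr) / ax[1])^2 + ((cols - ctr) / ax[2])^2 <= 1
    depth <- as.matrix(EBImage::distmap(matrix(as.numeric(body), n)))
    depths <- c(depths, depth[body])
  }
  depths
}

# SAT ring voxel count for a given sat thickness, from precomputed depths
count_sat_voxels <- function(depths, skin_thickness, sat_thickness) {
  sum(depths > skin_thickness & depths <= skin_thickness + sat_thickness)
}

#' Generate a paired pre/post phantom series with programmed depot change
#'
#' The post phantom shares the pre phantom's anatomy (same blob centers,
#' same body outline) but rescales the SAT ring thickness and the VAT blob
#' radii so the ground-truth depot volumes change by the requested
#' fractions.  The SAT thickness is solved against the actual rasterized
#' voxel counts; blob radii scale by `sqrt(1 + change)` since blob columns
#' contribute area quadratically in radius.
#'
#' @param spec a [phantom_spec] for the pre scan.
#' @param change named fractional changes, e.g. `c(sat = 0.18, vat =
#'   -0.15)`; magnitudes must be below 1.
#' @param post_seed seed for the post scan's noise (anatomy is shared).
#' @return list with `pre` and `post` (each a [make_phantom()] result) and
#'   `programmed` (the requested fractional changes).
#' @export
make_paired_series <- function(spec = phantom_spec(),
                               change = c(sat = 0.18, vat = -0.15),
                               post_seed = spec$seed + 500L) {
  if (any(abs(change) >= 1))
    stop("|change| must be below 1 (a depot cannot vanish or double safely)")
  pre <- make_phantom(spec)
  depths <- phantom_depths(spec)
  target <- (1 + change[["sat"]]) *
    count_sat_voxels(depths, spec$skin_thickness, spec$sat_thickness)
  ts <- seq(max(0.5, spec$sat_thickness * (1 + change[["sat"]]) * 0.5),
            spec$sat_thickness * (1 + abs(change[["sat"]])) + 1, by = 0.01)
  counts <- vapply(ts, function(t)
    count_sat_voxels(depths, spec$skin_thickness, t), numeric(1))
  t_post <- ts[which.min(abs(counts - target))]
  post_spec <- spec
  post_spec$sat_thickness <- t_post
  post_spec$seed <- as.integer(post_seed)
  post_spec$n_vat_blobs <- spec$n_vat_blobs
  post_blobs <- pre$blobs
  post_blobs[, 3] <- post_blobs[, 3] * sqrt(1 + change[["vat"]])
  post <- make_phantom(post_spec, blobs = post_blobs)
  if (sum(post$labels$labels == LABEL_CODES[["VAT"]]) == 0L ||
      sum(post$labels$labels == LABEL_CODES[["SAT"]]) == 0L)
    stop("programmed change removed a depot entirely")
  list(pre = pre, post = post, programmed = change)
}
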