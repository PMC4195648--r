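# Fuzzy C-means clustering of the SAT-side and VAT-side voxels (3 and 5
# classes respectively), merging of fat-like clusters by intensity and
# adjacency to the brightest cluster, and stripping of skin and abdominal
# muscle-wall voxels from the SAT depot.

#' Fuzzy C-means clustering of voxel intensities
#'
#' Standard FCM alternation on 1-D intensities: memberships from
#' inverse-distance ratios with exponent 2/(m-1), centroids as
#' membership^m-weighted means, iterated until the largest centroid
#' movement falls below `tol` or `max_iter` is reached.  Initialization is
#' deterministic: centroids start at evenly spaced quantiles of the
#' intensity distribution; `seed` optionally adds a small reproducible
#' perturbation.
#'
#' @param intensities numeric vector of voxel values.
#' @param n_classes number of classes (3 for SAT, 5 for VAT by the
#'   pipeline's defaults).
#' @param fuzzifier_m fuzziness exponent, > 1 (2 by default).
#' @param tol convergence tolerance on centroid movement.
#' @param max_iter iteration cap.
#' @param seed optional integer; when supplied, jitters the initial
#'   centroids reproducibly (the default initialization is already
#'   deterministic without it).
#' @return an object of class `fcm_fit` with `memberships` (N x C matrix,
#'   rows summing to 1), `centroids` (ascending), `objective` (per
#'   iteration), `n_iters`, `fuzzifier_m`.
#' @export
fcm <- function(intensities, n_classes, fuzzifier_m = 2, tol = 1e-5,
                max_iter = 300L, seed = NULL) {
  x <- as.numeric(intensities)
  if (fuzzifier_m <= 1) stop("'fuzzifier_m' must be > 1")
  if (length(unique(x)) < n_classes)
    stop("fewer distinct intensity values than classes")
  probs <- (seq_len(n_classes) - 0.5) / n_classes
  centers <- quantile(x, probs, names = FALSE)
  if (!is.null(seed)) {
    rs <- local({ set.seed(seed); runif(n_classes, -1, 1) })
    centers <- centers + rs * diff(range(x)) * 1e-3
  }
  # quantile init can duplicate centers on discrete data; spread them
  if (anyDuplicated(signif(centers, 12)))
    centers <- seq(min(x), max(x), length.out = n_classes)
  expo <- 2 / (fuzzifier_m - 1)
  objective <- numeric(0)
  U <- NULL
  for (it in seq_len(max_iter)) {
    d2 <- outer(x, centers, function(a, b) (a - b)^2)
    U <- fcm_memberships(d2, expo)
    Um <- U^fuzzifier_m
    objective <- c(objective, sum(Um * d2))
    new_centers <- colSums(Um * x) / colSums(Um)
    moved <- max(abs(new_centers - centers))
    centers <- new_centers
    if (moved < tol) break
  }
  ord <- order(centers)
  structure(list(memberships = U[, ord, drop = FALSE],
                 centroids = centers[ord],
                 objective = objective, n_iters = it,
                 fuzzifier_m = fuzzifier_m),
            class = "fcm_fit")
}

# memberships from squared distances; exact-hit voxels get membership 1
# in (split across) their zero-distance class(es)
fcm_memberships <- function(d2, expo) {
  n <- nrow(d2); C <- ncol(d2)
  U <- matrix(0, n, C)
  zero <- d2 <= 0
  hit <- rowSums(zero) > 0
  if (any(hit))
    U[hit, ] <- zero[hit, , drop = FALSE] / rowSums(zero[hit, , drop = FALSE])
  if (any(!hit)) {
    w <- (1 / d2[!hit, , drop = FALSE])^(expo / 2)
    U[!hit, ] <- w / rowSums(w)
  }
  U
}

#' @export
print.fcm_fit <- function(x, ...) {
  cat(sprintf("FCM fit: %d classes, m = %g, %d iteration(s)\n",
              length(x$centroids), x$fuzzifier_m, x$n_iters))
  cat("  centroids:", paste(signif(x$centroids, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Harden a fuzzy partition
#'
#' Maximum-membership defuzzification: each voxel is assigned the class of
#' its largest membership; exact ties break toward the class with the
#' higher centroid.
#'
#' @param fit an [fcm()] fit.
#' @return integer vector of class ids (1..C, classes ordered by
#'   ascending centroid).
#' @export
harden <- function(fit) {
  stopifnot(inherits(fit, "fcm_fit"))
  U <- fit$memberships
  # ties toward higher-centroid class: scan classes from brightest down
  apply(U, 1L, function(r) {
    mx <- max(r)
    max(which(r >= mx - 1e-15))
  })
}

#' Merge fat-like FCM classes by intensity and adjacency
#'
#' Starting from the brightest class (the fat anchor), every class whose
#' mean intensity lies within `intensity_gap` of the anchor's mean *and*
#' whose region touches the anchor's region (8-connectivity) is merged
#' into the fat mask; all other classes are excluded.
#'
#' @param class_map integer matrix of hardened class ids over the slice
#'   (NA outside the clustered region).
#' @param pixels slice intensities (for class means).
#' @param intensity_gap maximum mean-intensity distance from the brightest
#'   class, as a fraction of the normalized range.
#' @param require_adjacency if FALSE, merge on intensity alone.
#' @return logical matrix: the merged fat mask.
#' @export
merge_regions <- function(class_map, pixels, intensity_gap = 0.15,
                          require_adjacency = TRUE) {
  ids <- sort(unique(class_map[!is.na(class_map)]))
  if (!length(ids)) stop("empty partition: no classes to merge")
  means <- vapply(ids, function(k)
    mean(pixels[!is.na(class_map) & class_map == k]), numeric(1))
  anchor <- ids[which.max(means)]
  candidates <- ids[means >= max(means) - intensity_gap]
  merged <- setdiff(candidates, anchor)
  if (require_adjacency && length(merged)) {
    anchor_mask <- !is.na(class_map) & class_map == anchor
    grown <- EBImage::dilate(matrix(as.integer(anchor_mask), nrow(class_map)),
                             EBImage::makeBrush(3, "box")) > 0
    touching <- vapply(merged, function(k)
      any(grown & !is.na(class_map) & class_map == k), logical(1))
    merged <- merged[touching]
  }
  keep <- c(anchor, merged)
  out <- !is.na(class_map) & class_map %in% keep
  out
}

#' Strip skin and abdominal-wall voxels from the SAT mask
#'
#' Removes (a) a `skin_depth`-thick band just inside the body boundary and
#' (b) a `wall_depth`-thick band around the converged wall contour
#' (|phi| < wall_depth) from the SAT fat mask, yielding the final SAT
#' depot.  Because the converged contour may sit at either face of the
#' muscle wall, the wall band can optionally be restricted to voxels of
#' wall-like intensity (`pixels < fat_floor`): the wall is iso-intense by
#' the pipeline's contrast assumption, so fat-bright voxels inside the
#' band are subcutaneous fat and are retained.
#'
#' @param sat_mask logical matrix of fat-classified SAT-side voxels.
#' @param body_mask logical body foreground mask.
#' @param wall_ls converged [level_set] of the muscle wall.
#' @param skin_depth skin band thickness in px (0 disables).
#' @param wall_depth wall band half-width in px (0 disables).
#' @param pixels optional slice intensities for the intensity guard.
#' @param fat_floor optional intensity below which a band voxel counts as
#'   wall rather than fat; ignored unless `pixels` is given.
#' @return logical matrix, the stripped SAT mask.
#' @export
strip_skin_wall <- function(sat_mask, body_mask, wall_ls, skin_depth = 2,
                            wall_depth = 2, pixels = NULL,
                            fat_floor = NULL) {
  stopifnot(all(dim(sat_mask) == dim(body_mask)))
  if (!any(sat_mask)) {
    warning("SAT mask is empty before stripping")
    return(sat_mask)
  }
  out <- sat_mask
  if (skin_depth > 0) {
    d_in <- as.matrix(EBImage::distmap(matrix(as.numeric(body_mask),
                                              nrow(body_mask))))
    out <- out & !(body_mask & d_in <= skin_depth)
  }
  if (wall_depth > 0) {
    band <- abs(wall_ls$phi) < wall_depth
    if (!is.null(pixels) && !is.null(fat_floor))
      band <- band & pixels < fat_floor
    out <- out & !band
  }
  if (!any(out))
    stop("empty SAT after skin/wall stripping (depths exceed ring thickness?)")
  out
}
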