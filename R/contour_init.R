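# Automatic initialization of the level-set contour: trace the body edge,
# shrink it about its centroid into the abdominal cavity, and embed it as
# a signed distance field (negative inside).

#' Level-set field constructor
#'
#' Implicit contour representation: the evolving curve is the zero set of
#' `phi`, with `phi < 0` inside and `phi > 0` outside.
#'
#' @param phi numeric matrix, signed scalar field.
#' @param band_width width in pixels over which `phi` is maintained as a
#'   signed distance.
#' @return an object of class `level_set`.
#' @export
level_set <- function(phi, band_width = 10) {
  stopifnot(is.matrix(phi), all(is.finite(phi)))
  structure(list(phi = phi, band_width = band_width), class = "level_set")
}

#' @export
print.level_set <- function(x, ...) {
  cat(sprintf("Level-set field %d x %d, enclosed area %d px, band %g px\n",
              nrow(x$phi), ncol(x$phi), sum(x$phi < 0), x$band_width))
  invisible(x)
}

#' Initialization parameters
#'
#' @param shrink_scale similarity scale applied to the body edge about its
#'   centroid; the working range is \[0.75, 0.85\] (values outside it are
#'   accepted with a warning).
#' @param center_mode `"slice_center"` places the shrunken contour at the
#'   geometric center of the image grid; `"mask_centroid"` at the centroid
#'   of the body mask (robust to off-center animals).
#' @return an `init_params` list.
#' @export
init_params <- function(shrink_scale = 0.80,
                        center_mode = c("slice_center", "mask_centroid")) {
  center_mode <- match.arg(center_mode)
  if (shrink_scale <= 0) stop("'shrink_scale' must be positive")
  if (shrink_scale < 0.75 || shrink_scale > 0.85)
    warning("shrink_scale outside the working range [0.75, 0.85]")
  structure(list(shrink_scale = shrink_scale, center_mode = center_mode),
            class = "init_params")
}

# 8-connected Moore boundary tracing; returns n x 2 (row, col), each
# boundary pixel once, ordered along the closed boundary.
trace_boundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  at <- function(p) p[1] >= 1L && p[1] <= nr && p[2] >= 1L && p[2] <= nc &&
    mask[p[1], p[2]]
  # start: first foreground pixel in column-major scan, so its W and N
  # neighbours are background
  idx <- which(mask)
  start <- c(((idx[1] - 1L) %% nr) + 1L, ((idx[1] - 1L) %/% nr) + 1L)
  # neighbour offsets in a fixed rotational order starting West
  off <- rbind(c(0L, -1L), c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
               c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  dir_of <- function(delta) which(off[, 1] == delta[1] & off[, 2] == delta[2])
  chain <- matrix(start, 1L, 2L)
  cur <- start
  b_dir <- 1L  # direction of a known-background neighbour (West of start)
  repeat {
    nxt <- NULL
    # scan the 8 neighbours rotationally, starting just past the backtrack
    for (k in 1:8) {
      d <- ((b_dir - 1L + k) %% 8L) + 1L
      cand <- cur + off[d, ]
      if (at(cand)) {
        # new backtrack: the (background) neighbour checked just before,
        # expressed as a direction from the new pixel
        prev_checked <- cur + off[((b_dir - 1L + k - 1L) %% 8L) + 1L, ]
        b_dir <- dir_of(prev_checked - cand)
        nxt <- cand
        break
      }
    }
    if (is.null(nxt)) break                              # isolated pixel
    if (all(nxt == start)) break
    cur <- nxt
    chain <- rbind(chain, cur)
    if (nrow(chain) > 8L * (nr + nc)) break              # safety cap
  }
  dimnames(chain) <- NULL
  chain
}

#' Edge map of a binary mask as an ordered contour
#'
#' Returns the 8-connected boundary pixels of the (largest) foreground
#' component, ordered into a closed chain by Moore boundary tracing.  This
#' chain is the automatic initial contour of the pipeline.
#'
#' @param mask logical matrix with non-empty foreground.
#' @return n x 2 integer matrix of (row, col) boundary pixel coordinates,
#'   ordered along the closed boundary.
#' @export
edge_map <- function(mask) {
  if (!any(mask)) stop("empty mask: no foreground to trace")
  trace_boundary(mask)
}

# Scanline rasterization of a closed polygon given as n x 2 (row, col)
# vertices; returns a logical matrix with pixels whose centers fall inside.
rasterize_polygon <- function(poly, shape) {
  nr <- shape[1]; nc <- shape[2]
  out <- matrix(FALSE, nr, nc)
  y1 <- poly[, 1]; x1 <- poly[, 2]
  y2 <- c(poly[-1, 1], poly[1, 1]); x2 <- c(poly[-1, 2], poly[1, 2])
  keep <- y1 != y2
  y1 <- y1[keep]; x1 <- x1[keep]; y2 <- y2[keep]; x2 <- x2[keep]
  if (!length(y1)) return(out)
  rmin <- max(1L, floor(min(y1, y2))); rmax <- min(nr, ceiling(max(y1, y2)))
  for (r in rmin:rmax) {
    crosses <- (y1 <= r & y2 > r) | (y2 <= r & y1 > r)
    if (!any(crosses)) next
    xs <- x1[crosses] + (r - y1[crosses]) / (y2[crosses] - y1[crosses]) *
      (x2[crosses] - x1[crosses])
    xs <- sort(xs)
    for (i in seq(1L, length(xs) - 1L, by = 2L)) {
      a <- ceiling(xs[i]); b <- floor(xs[i + 1])
      if (b >= a) out[r, max(1L, a):min(nc, b)] <- TRUE
    }
  }
  # include the polygon's own boundary pixels: the traced chain runs
  # through pixel centers, so counting interior-only pixels would bias the
  # enclosed area low by about half the perimeter (Pick's theorem)
  br <- round(poly[, 1]); bc <- round(poly[, 2])
  ok <- br >= 1L & br <= nr & bc >= 1L & bc <= nc
  out[cbind(br[ok], bc[ok])] <- TRUE
  out
}

#' Signed distance field of a binary mask
#'
#' Euclidean distance transform based embedding: `phi = d_out - 0.5`
#' outside and `phi = -(d_in - 0.5)` inside, where d_in/d_out are distances
#' to the nearest opposite-region pixel.  The half-pixel shift puts the
#' zero crossing on the mask boundary and gives |grad phi| ~ 1 across it.
#'
#' @param mask logical matrix (TRUE = inside).
#' @param band_width band width stored on the result.
#' @param polish_iters iterations of the Godunov-upwind redistancing PDE
#'   run after the distance transform to smooth out the orientation-
#'   dependent ripple of pixel-center distances.
#' @return a [level_set].
#' @export
sdf_from_mask <- function(mask, band_width = 10, polish_iters = 10L) {
  m <- matrix(as.numeric(mask), nrow(mask))
  d_in <- as.matrix(EBImage::distmap(m))
  d_out <- as.matrix(EBImage::distmap(1 - m))
  phi <- ifelse(mask, -(d_in - 0.5), d_out - 0.5)
  phi <- sussman_polish(phi, n_iter = polish_iters)
  level_set(phi, band_width = band_width)
}

# redistancing PDE phi_t = sign(phi0) (1 - |grad phi|) with the Godunov
# upwind Hamiltonian and subcell interface anchoring: cells that straddle
# the zero crossing of the input field relax toward a fixed distance
# estimate d0 = phi0 / |grad phi0| instead of being advected, so the
# interface cannot move during redistancing (no curvature-proportional
# shrinkage)
sussman_polish <- function(phi, n_iter = 10L, dt = 0.5) {
  if (n_iter <= 0L) return(phi)
  nr <- nrow(phi); nc <- ncol(phi)
  ip <- c(2:nr, nr); im <- c(1, 1:(nr - 1))
  jp <- c(2:nc, nc); jm <- c(1, 1:(nc - 1))
  phi0 <- phi
  s <- phi0 / sqrt(phi0^2 + 1)
  pos <- phi0 > 0
  sgn0 <- sign(phi0)
  at_interface <- (phi0 * phi0[ip, ] < 0) | (phi0 * phi0[im, ] < 0) |
    (phi0 * phi0[, jp] < 0) | (phi0 * phi0[, jm] < 0)
  g0y <- (phi0[ip, ] - phi0[im, ]) / 2
  g0x <- (phi0[, jp] - phi0[, jm]) / 2
  d0 <- phi0 / pmax(sqrt(g0y^2 + g0x^2), 1e-6)
  for (it in seq_len(n_iter)) {
    a <- phi - phi[im, ]   # D-y
    b <- phi[ip, ] - phi   # D+y
    cc <- phi - phi[, jm]  # D-x
    d <- phi[, jp] - phi   # D+x
    gpos <- sqrt(pmax(pmax(a, 0)^2, pmin(b, 0)^2) +
                 pmax(pmax(cc, 0)^2, pmin(d, 0)^2))
    gneg <- sqrt(pmax(pmin(a, 0)^2, pmax(b, 0)^2) +
                 pmax(pmin(cc, 0)^2, pmax(d, 0)^2))
    g <- ifelse(pos, gpos, gneg)
    upd <- phi - dt * s * (g - 1)
    upd_if <- phi - dt * (sgn0 * abs(phi) - d0)
    phi <- ifelse(at_interface, upd_if, upd)
  }
  phi
}

#' Shrink the body contour and place it in the abdominal cavity
#'
#' Scales the closed contour about its centroid by `shrink_scale`,
#' translates its centroid to the chosen center (geometric slice center by
#' default), rasterizes the result and embeds it as a signed distance
#' field.  The shrink guarantees the initial zero level set starts inside
#' the abdominal area, away from the strong background/image boundary.
#'
#' @param contour n x 2 (row, col) closed contour from [edge_map()].
#' @param params an [init_params] object.
#' @param slice_shape integer length-2, image (rows, cols).
#' @param mask optional body mask, required for `center_mode =
#'   "mask_centroid"`.
#' @return a [level_set] whose zero set is the shrunken contour.
#' @export
shrink_and_place <- function(contour, params = init_params(), slice_shape,
                             mask = NULL) {
  stopifnot(inherits(params, "init_params"), ncol(contour) == 2L)
  ctr <- colMeans(contour)
  center <- switch(params$center_mode,
    slice_center = (slice_shape + 1) / 2,
    mask_centroid = {
      if (is.null(mask)) stop("mask required for center_mode='mask_centroid'")
      idx <- which(mask, arr.ind = TRUE)
      colMeans(idx)
    })
  scaled <- sweep(contour, 2L, ctr) * params$shrink_scale
  placed <- sweep(scaled, 2L, center, FUN = "+")
  raster <- rasterize_polygon(placed, slice_shape)
  if (!any(raster))
    stop("shrunken contour rasterizes to an empty region")
  sdf_from_mask(raster)
}

#' Reinitialize a level-set field to a signed distance function
#'
#' Relaxes `phi` back to a signed distance by iterating the redistancing
#' PDE `phi_t = sign(phi0) (1 - |grad phi|)` with a Godunov upwind
#' Hamiltonian.  The zero crossing is preserved to sub-pixel accuracy
#' (the PDE leaves the sign pattern untouched, so slow sub-pixel contour
#' motion accumulated between reinitializations survives) while
#' |grad phi| is restored to 1 in the band.
#'
#' @param ls a [level_set] with a non-empty zero crossing.
#' @param n_iter redistancing iterations; the corrected region grows by
#'   about half a pixel per iteration, so the default covers a band wider
#'   than `band_width`.
#' @return a reinitialized [level_set].
#' @export
reinitialize <- function(ls, n_iter = 30L) {
  stopifnot(inherits(ls, "level_set"))
  inside <- ls$phi < 0
  if (!any(inside) || all(inside))
    stop("level set has no zero crossing")
  level_set(sussman_polish(ls$phi, n_iter = n_iter),
            band_width = ls$band_width)
}
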