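#' @importFrom stats quantile sd rnorm runif median
#' @importFrom utils write.csv read.csv modifyList
NULL

# Integer coding used in NIfTI label files.  Fixed so that label volumes are
# bit-exact interchange objects: 0 background, 1 SAT, 2 VAT, 3 skin_wall,
# 4 organ.
LABEL_LEVELS <- c("background", "SAT", "VAT", "skin_wall", "organ")
LABEL_CODES <- c(background = 0L, SAT = 1L, VAT = 2L, skin_wall = 3L,
                 organ = 4L)

#' Construct an MR image volume
#'
#' The raw input container of the pipeline: a 3-D intensity stack
#' (rows x cols x slices, arbitrary scanner units) together with the voxel
#' geometry needed for quantification.  Indexing is row-major 0-based in
#' concept (first array margin = image row), with the slice axis last.
#'
#' @param voxels numeric 3-D array (rows x cols x slices) or a matrix
#'   (treated as a single slice).
#' @param in_plane_spacing numeric length-2, mm per pixel (row, col); a
#'   single value is recycled.
#' @param slice_thickness slice thickness in mm.
#' @param slice_labels optional character vector of per-slice names (e.g.
#'   anatomical levels such as "L1".."L5").
#' @return an object of class `image_volume`.
#' @export
image_volume <- function(voxels, in_plane_spacing, slice_thickness,
                         slice_labels = NULL) {
  if (is.matrix(voxels)) voxels <- array(voxels, c(dim(voxels), 1L))
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("'voxels' must be a 2-D matrix or 3-D array")
  if (!all(is.finite(voxels))) stop("all intensities must be finite")
  if (dim(voxels)[3] < 1L) stop("volume must contain at least one slice")
  in_plane_spacing <- rep(as.numeric(in_plane_spacing), length.out = 2L)
  slice_thickness <- as.numeric(slice_thickness)
  if (any(in_plane_spacing <= 0) || slice_thickness <= 0)
    stop("voxel spacing must be strictly positive")
  if (!is.null(slice_labels) && length(slice_labels) != dim(voxels)[3])
    stop("'slice_labels' must have one entry per slice")
  structure(list(voxels = voxels,
                 in_plane_spacing = in_plane_spacing,
                 slice_thickness = slice_thickness,
                 slice_labels = slice_labels),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("MR image volume: %d x %d pixels, %d slice(s)\n",
              d[1], d[2], d[3]))
  cat(sprintf("  in-plane spacing %.4g x %.4g mm, slice thickness %.4g mm\n",
              x$in_plane_spacing[1], x$in_plane_spacing[2],
              x$slice_thickness))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Construct a depot label volume
#'
#' Per-voxel categorical labels over \{background, SAT, VAT, skin_wall,
#' organ\}, carrying the same geometry as its source volume.  SAT and VAT
#' voxel sets are disjoint by construction (one label per voxel).
#'
#' @param labels integer 3-D array (or matrix for one slice) using the
#'   coding 0 background, 1 SAT, 2 VAT, 3 skin_wall, 4 organ; or a
#'   character array over those names.
#' @param in_plane_spacing,slice_thickness voxel geometry in mm.
#' @return an object of class `depot_labels`.
#' @export
depot_labels <- function(labels, in_plane_spacing, slice_thickness) {
  if (is.matrix(labels)) labels <- array(labels, c(dim(labels), 1L))
  if (is.character(labels)) {
    if (!all(labels %in% LABEL_LEVELS)) stop("unknown label name")
    labels <- array(LABEL_CODES[labels], dim(labels))
  }
  storage.mode(labels) <- "integer"
  if (!all(labels %in% LABEL_CODES))
    stop("labels must be integers in 0..4 (background/SAT/VAT/skin_wall/organ)")
  in_plane_spacing <- rep(as.numeric(in_plane_spacing), length.out = 2L)
  if (any(in_plane_spacing <= 0) || slice_thickness <= 0)
    stop("voxel spacing must be strictly positive")
  structure(list(labels = labels,
                 in_plane_spacing = in_plane_spacing,
                 slice_thickness = as.numeric(slice_thickness)),
            class = "depot_labels")
}

#' @export
print.depot_labels <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("Depot label volume: %d x %d x %d\n", d[1], d[2], d[3]))
  tab <- table(factor(LABEL_LEVELS[x$labels + 1L], levels = LABEL_LEVELS))
  print(tab)
  invisible(x)
}

#' Read an MR slice stack with geometry metadata
#'
#' Reads either a NIfTI file (`.nii`/`.nii.gz`; spacing from the header) or
#' the package's plain array + JSON-sidecar format: `<stem>.json` holding
#' `dim`, `in_plane_spacing_mm`, `slice_thickness_mm` and optional
#' `slice_labels`, next to `<stem>.csv` with the voxel values flattened in
#' column-major order, one slice after another.  Slices must all share the
#' same in-plane shape; sidecar metadata is validated against the data.
#'
#' @param source path to a `.nii`/`.nii.gz` file or to the JSON sidecar.
#' @return an [image_volume].
#' @export
read_volume <- function(source) {
  if (!file.exists(source)) stop("input not readable: ", source)
  if (grepl("\\.nii(\\.gz)?$", source)) {
    img <- RNifti::readNifti(source)
    pd <- RNifti::pixdim(img)
    a <- as.array(img)
    a <- array(as.vector(a), dim(a))       # drop RNifti attributes
    if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 1L))
    if (length(pd) < 3L) pd <- c(pd, 1)
    return(image_volume(a, in_plane_spacing = pd[1:2],
                        slice_thickness = pd[3]))
  }
  if (grepl("\\.json$", source)) {
    meta <- jsonlite::fromJSON(source)
    req <- c("dim", "in_plane_spacing_mm", "slice_thickness_mm")
    miss <- setdiff(req, names(meta))
    if (length(miss))
      stop("metadata sidecar missing field(s): ", paste(miss, collapse = ", "))
    stem <- sub("\\.json$", "", source)
    datafile <- paste0(stem, ".csv")
    if (!file.exists(datafile)) stop("voxel data file not found: ", datafile)
    vals <- scan(datafile, what = numeric(), sep = ",", quiet = TRUE)
    d <- as.integer(meta$dim)
    if (length(d) == 2L) d <- c(d, 1L)
    if (length(vals) != prod(d))
      stop(sprintf("voxel data length %d does not match dim %s",
                   length(vals), paste(d, collapse = "x")))
    return(image_volume(array(vals, d),
                        in_plane_spacing = meta$in_plane_spacing_mm,
                        slice_thickness = meta$slice_thickness_mm,
                        slice_labels = meta$slice_labels))
  }
  stop("unrecognized input format (expect .nii, .nii.gz or .json sidecar): ",
       source)
}

#' Write an image volume as array + JSON sidecar
#'
#' Inverse of the sidecar branch of [read_volume()]; plain-text, so suitable
#' for fixtures and archival diffing.
#'
#' @param volume an [image_volume].
#' @param stem output path without extension; writes `<stem>.json` and
#'   `<stem>.csv`.
#' @return the sidecar path, invisibly.
#' @export
write_volume_sidecar <- function(volume, stem) {
  stopifnot(inherits(volume, "image_volume"))
  meta <- list(dim = dim(volume$voxels),
               in_plane_spacing_mm = volume$in_plane_spacing,
               slice_thickness_mm = volume$slice_thickness)
  if (!is.null(volume$slice_labels)) meta$slice_labels <- volume$slice_labels
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = FALSE,
                       digits = NA)
  # column-major flatten; 15 significant digits round-trips doubles we use
  cat(sprintf("%.15g", as.vector(volume$voxels)),
      file = paste0(stem, ".csv"), sep = ",")
  invisible(paste0(stem, ".json"))
}

#' Write a depot label volume to NIfTI-1
#'
#' Integer coding: 0 background, 1 SAT, 2 VAT, 3 skin_wall, 4 organ.
#' Written uncompressed when `path` ends in `.nii`, so read-back (and file
#' bytes, for fixed input) reproduce the labels exactly; spacing
#' round-trips at the float32 precision of the NIfTI-1 header.
#'
#' @param labels a [depot_labels] volume.
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "depot_labels"))
  img <- RNifti::asNifti(labels$labels)
  RNifti::pixdim(img) <- c(labels$in_plane_spacing, labels$slice_thickness)
  tryCatch(
    RNifti::writeNifti(img, path, datatype = "uint8"),
    error = function(e)
      stop("cannot write label file '", path, "': ", conditionMessage(e)))
  if (dim(labels$labels)[3] == 1L && grepl("\\.nii$", path))
    patch_nifti_singleton(path, labels$in_plane_spacing,
                          labels$slice_thickness)
  invisible(path)
}

# A trailing singleton slice dimension is squeezed away when the image is
# created, which silently discards all three pixel dimensions.  Restore
# the 3-D geometry by rewriting the fixed-offset dim/pixdim header fields
# of the uncompressed NIfTI-1 file (int16 dim[8] at byte 40, float32
# pixdim[8] at byte 76; little-endian).
patch_nifti_singleton <- function(path, in_plane_spacing, slice_thickness) {
  con <- file(path, "r+b")
  on.exit(close(con))
  seek(con, 40L, rw = "read")
  d <- readBin(con, "integer", n = 8L, size = 2L, endian = "little")
  d[1] <- 3L
  d[4] <- 1L
  seek(con, 40L, rw = "write")
  writeBin(as.integer(d), con, size = 2L, endian = "little")
  seek(con, 76L, rw = "read")
  pd <- readBin(con, "double", n = 8L, size = 4L, endian = "little")
  pd[2:4] <- c(in_plane_spacing, slice_thickness)
  seek(con, 76L, rw = "write")
  writeBin(pd, con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a depot label volume from NIfTI-1
#'
#' @param path a file written by [write_labels()].
#' @return a [depot_labels] volume.
#' @export
read_labels <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  if (length(pd) < 3L) pd <- c(pd, 1)
  a <- as.array(img)
  a <- array(as.integer(a), dim(a))        # drop RNifti attributes
  if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 1L))
  depot_labels(a, in_plane_spacing = pd[1:2], slice_thickness = pd[3])
}
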