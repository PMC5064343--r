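#' Construct an ImageVolume
#'
#' @param data 3D numeric array.
#' @param spacing Voxel size in mm; a single value (isotropic) or one per
#'   axis. Ignored when `affine` is given (spacing is then derived from the
#'   affine column norms) unless both are supplied consistently.
#' @param affine Optional 4x4 voxel-to-world matrix; defaults to a diagonal
#'   scaling by `spacing` with the origin at voxel (0,0,0).
#' @return An [ImageVolume-class] object.
#' @examples
#' v <- ImageVolume(array(0, dim = c(4, 4, 4)), spacing = 2)
#' dim(v)
#' @export
ImageVolume <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  if (is.null(dim(data)) || length(dim(data)) != 3L)
    stop("data must be a 3D array; got dims [",
         paste(dim(data), collapse = " x "), "]")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  new("ImageVolume", data = data, spacing = as.numeric(spacing),
      affine = affine)
}

#' Construct a ProbabilityMap
#'
#' Values within `eps = 1e-6` outside \[0, 1\] are clamped; larger
#' excursions raise an error.
#'
#' @inheritParams ImageVolume
#' @param eps Clamping tolerance.
#' @return A [ProbabilityMap-class] object.
#' @export
ProbabilityMap <- function(data, spacing = c(1, 1, 1), affine = NULL,
                           eps = 1e-6) {
  v <- as.vector(data)
  ok <- !is.nan(v)
  if (any(v[ok] < -eps) || any(v[ok] > 1 + eps))
    stop("probability values outside [", -eps, ", ", 1 + eps, "]: range [",
         min(v[ok]), ", ", max(v[ok]), "]")
  data[!is.nan(data) & data < 0] <- 0
  data[!is.nan(data) & data > 1] <- 1
  iv <- ImageVolume(data, spacing, affine)
  new("ProbabilityMap", iv)
}

#' Construct a BinaryMask
#'
#' @inheritParams ImageVolume
#' @return A [BinaryMask-class] object.
#' @export
BinaryMask <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  storage.mode(data) <- "double"
  iv <- ImageVolume(data, spacing, affine)
  new("BinaryMask", iv)
}

#' Construct a LabelVolume
#'
#' @inheritParams ImageVolume
#' @param labelNames Named character vector mapping label integers (as
#'   names) to region names, e.g. `c("1" = "precuneus")`.
#' @param referenceLabel Integer label of the reference (cerebellar) region,
#'   or NA.
#' @return A [LabelVolume-class] object.
#' @export
LabelVolume <- function(data, spacing = c(1, 1, 1), affine = NULL,
                        labelNames = character(), referenceLabel = NA_integer_) {
  storage.mode(data) <- "double"
  iv <- ImageVolume(data, spacing, affine)
  new("LabelVolume", iv, labelNames = labelNames,
      referenceLabel = as.integer(referenceLabel))
}

#' Read a 3D volume from a NIfTI-1 file
#'
#' Spacing and affine are taken from the header (sform preferred); data are
#' returned in native units. 4D images are rejected: this pipeline operates
#' on static 3D volumes.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return An [ImageVolume-class] object.
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- img[, , , 1, drop = TRUE]
    d <- dim(img)
  }
  if (length(d) != 3L)
    stop("expected a 3D image, got shape [", paste(d, collapse = " x "),
         "] in ", path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  sp <- abs(RNifti::pixdim(img))[1:3]
  if (any(sp <= 0)) sp <- sqrt(colSums(aff[1:3, 1:3]^2))
  arr <- array(as.numeric(img), dim = d)
  ImageVolume(arr, spacing = sp, affine = aff)
}

#' Write a volume to a NIfTI-1 file
#'
#' Data are written as float (NaN marks excluded voxels); the affine is
#' stored as the sform and the spacing in pixdim, so that
#' `readVolume(writeVolume(v, p))` reproduces grid metadata exactly.
#'
#' @param vol An [ImageVolume-class] (or subclass).
#' @param path Output path (`.nii` or `.nii.gz`); parent directory must exist.
#' @param nanAsZero Replace NaN by 0 on output, for viewers that cannot
#'   render NaN. Default FALSE.
#' @return Invisibly, `path`.
#' @export
writeVolume <- function(vol, path, nanAsZero = FALSE) {
  stopifnot(is(vol, "ImageVolume"))
  if (!dir.exists(dirname(path)))
    stop("directory does not exist: ", dirname(path))
  arr <- vol@data
  if (nanAsZero) arr[is.nan(arr)] <- 0
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- vol@spacing
  RNifti::`sform<-`(img, structure(vol@affine, code = 2L)) -> img
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Check that volumes share one grid
#'
#' Every multi-volume operation in the pipeline calls this gate: shapes must
#' be identical and affines must agree elementwise within `tol`. No
#' resampling is ever performed — inputs must already be co-registered onto
#' one grid.
#'
#' @param volumes List of [ImageVolume-class] objects (>= 2).
#' @param tol Tolerance on affine entries (default 1e-4).
#' @return Invisibly TRUE; raises an error naming the first offending pair.
#' @export
assertSameGrid <- function(volumes, tol = 1e-4) {
  stopifnot(length(volumes) >= 2L)
  ref <- volumes[[1L]]
  for (i in seq_along(volumes)[-1L]) {
    v <- volumes[[i]]
    if (!identical(dim(ref@data), dim(v@data)))
      stop(sprintf("grid mismatch between volumes 1 and %d: shape [%s] vs [%s]",
                   i, paste(dim(ref@data), collapse = " x "),
                   paste(dim(v@data), collapse = " x ")))
    dev <- max(abs(ref@affine - v@affine))
    if (dev > tol)
      stop(sprintf(
        "grid mismatch between volumes 1 and %d: affines differ by %.3g (tol %.3g)",
        i, dev, tol))
  }
  invisible(TRUE)
}

#' Read a label-name table
#'
#' Two-column CSV `label,name` with an optional logical `is_reference`
#' column marking the reference region.
#'
#' @param path CSV path.
#' @return List with `labelNames` (named character) and `referenceLabel`
#'   (integer or NA).
#' @export
readLabelTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("label", "name") %in% names(tab)))
    stop("label table must have columns 'label' and 'name': ", path)
  nm <- as.character(tab$name)
  names(nm) <- as.character(as.integer(tab$label))
  ref <- NA_integer_
  if ("is_reference" %in% names(tab)) {
    hit <- which(as.logical(tab$is_reference))
    if (length(hit) > 1L) stop("more than one reference label in ", path)
    if (length(hit) == 1L) ref <- as.integer(tab$label[hit])
  }
  list(labelNames = nm, referenceLabel = ref)
}

# Internal: rebuild a volume with new data on the same grid, same class
# where that class's invariant still holds.
sameGrid <- function(template, data, class = "ImageVolume") {
  iv <- ImageVolume(data, spacing = template@spacing,
                    affine = template@affine)
  if (class == "ImageVolume") iv else new(class, iv)
}
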