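# Internal: shift a logical 3D array by an integer offset, filling with
# FALSE (outside the grid there is no mask).
shiftArray <- function(arr, off) {
  d <- dim(arr)
  out <- array(FALSE, dim = d)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    k <- off[ax]
    n <- d[ax]
    if (abs(k) >= n) return(out)
    if (k >= 0) { dst[[ax]] <- seq_len(n - k); src[[ax]] <- seq_len(n - k) + k }
    else        { dst[[ax]] <- seq_len(n + k) - k; src[[ax]] <- seq_len(n + k) }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

# Internal: structuring-element offsets for 6-, 18- or 26-connectivity
# (face, face+edge, full 3x3x3 neighborhoods; the center is implicit).
structOffsets <- function(connectivity) {
  g <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  nz <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6"  = nz == 1,
                 "18" = nz >= 1 & nz <= 2,
                 "26" = nz >= 1,
                 stop("connectivity must be 6, 18 or 26"))
  g[keep, , drop = FALSE]
}

# Internal: one binary erosion step. A voxel survives iff every voxel under
# the structuring element (centered on it) is inside the mask; outside the
# grid counts as background.
binaryErodeOnce <- function(arr, connectivity) {
  offs <- structOffsets(connectivity)
  out <- arr
  for (i in seq_len(nrow(offs))) {
    out <- out & shiftArray(arr, offs[i, ])
    if (!any(out)) break
  }
  out
}

#' Erode a binary mask to half its voxel count
#'
#' Repeatedly applies one binary-erosion step with the chosen structuring
#' element until the voxel count is at most half the original, restricting a
#' VOI to its central core (the periphery of atlas regions is unreliable).
#' If an erosion step would empty the mask before reaching half, the last
#' nonempty mask is returned with a warning. The result is always a subset
#' of the input.
#'
#' Erosion operates in voxel units; with anisotropic voxels the removed
#' rind is thinner in mm along the finer axes.
#'
#' @param mask A nonempty [BinaryMask-class].
#' @param connectivity Structuring element: 6 (faces), 18 (faces + edges) or
#'   26 (full 3x3x3 box, the default).
#' @return An eroded [BinaryMask-class].
#' @examples
#' cube <- array(0, dim = c(14, 14, 14)); cube[3:12, 3:12, 3:12] <- 1
#' m <- erodeToHalf(BinaryMask(cube))
#' sum(imgData(m))  # 216: counts go 1000 -> 512 -> 216
#' @export
erodeToHalf <- function(mask, connectivity = 26) {
  stopifnot(is(mask, "BinaryMask"))
  cur <- mask@data == 1
  n0 <- sum(cur)
  if (n0 == 0L) stop("cannot erode an empty mask")
  while (sum(cur) > n0 / 2) {
    nxt <- binaryErodeOnce(cur, connectivity)
    if (!any(nxt)) {
      warning("erosion would empty the mask before reaching half (",
              sum(cur), " of ", n0,
              " voxels remain); returning the last nonempty mask")
      break
    }
    cur <- nxt
  }
  sameGrid(mask, array(as.numeric(cur), dim = dim(cur)), "BinaryMask")
}

#' Binary mask of one atlas label
#'
#' @param labels A [LabelVolume-class].
#' @param label The label to select (must occur in the volume).
#' @param erode If TRUE, restrict to the central half via [erodeToHalf()].
#' @param connectivity Structuring element for erosion (default 26).
#' @return A [BinaryMask-class].
#' @export
voiMask <- function(labels, label, erode = FALSE, connectivity = 26) {
  stopifnot(is(labels, "LabelVolume"))
  m <- labels@data == label
  if (!any(m))
    stop("label ", label, " does not occur in the label volume")
  out <- sameGrid(labels, array(as.numeric(m), dim = dim(m)), "BinaryMask")
  if (erode) erodeToHalf(out, connectivity) else out
}

#' Compute an SUVR image with an eroded-VOI median reference
#'
#' The reference value is the median of the PVC-PET image over the
#' non-excluded voxels of the reference VOI eroded to half its size; the
#' SUVR image is the PVC-PET image divided voxelwise by that value.
#' Excluded (NaN) voxels stay excluded. By construction the median SUVR
#' over the eroded reference VOI is exactly 1, and the result is invariant
#' to a global rescaling of the input image.
#'
#' @param pvcPet PVC-PET [ImageVolume-class] (NaN outside the GM mask).
#' @param labels [LabelVolume-class] of VOIs on the same grid.
#' @param referenceLabel Reference (cerebellar cortex) label; defaults to
#'   the label volume's `referenceLabel`.
#' @param connectivity Erosion structuring element (default 26).
#' @return An [SUVRResult-class].
#' @export
computeSuvr <- function(pvcPet, labels,
                        referenceLabel = labels@referenceLabel,
                        connectivity = 26) {
  stopifnot(is(labels, "LabelVolume"))
  assertSameGrid(list(pvcPet, labels))
  if (is.na(referenceLabel)) stop("no reference label given")
  refMask <- voiMask(labels, referenceLabel, erode = TRUE,
                     connectivity = connectivity)
  sel <- refMask@data == 1 & !is.nan(pvcPet@data)
  if (!any(sel))
    stop("eroded reference VOI is entirely excluded from the PVC-PET image; ",
         "cannot form a reference value")
  refVal <- stats::median(pvcPet@data[sel])
  if (!is.finite(refVal) || refVal <= 0)
    stop("non-positive reference value (", signif(refVal, 4),
         "); check bias correction")
  new("SUVRResult",
      suvr = sameGrid(pvcPet, pvcPet@data / refVal),
      referenceValue = refVal,
      referenceLabel = as.integer(referenceLabel),
      erodedRefVoxels = sum(sel),
      alphaApplied = NA_real_)
}

#' Apply a cross-modality slope correction
#'
#' Multiplies every non-excluded SUVR voxel by `alpha`, the mean per-VOI
#' regression slope relating one modality's SUVR scale to the other's
#' (see [poolAlpha()]). Repeated application composes multiplicatively and
#' the accumulated factor is recorded.
#'
#' @param suvr An [SUVRResult-class].
#' @param alpha Positive scale factor.
#' @return An [SUVRResult-class] with `alphaApplied` updated.
#' @export
applyAlpha <- function(suvr, alpha) {
  stopifnot(is(suvr, "SUVRResult"))
  if (!is.finite(alpha) || alpha <= 0)
    stop("alpha must be a positive finite number")
  prev <- if (is.na(suvr@alphaApplied)) 1 else suvr@alphaApplied
  new("SUVRResult",
      suvr = sameGrid(suvr@suvr, suvr@suvr@data * alpha),
      referenceValue = suvr@referenceValue,
      referenceLabel = suvr@referenceLabel,
      erodedRefVoxels = suvr@erodedRefVoxels,
      alphaApplied = prev * alpha)
}
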