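#' Extract the voxel data array
#'
#' @param x An [ImageVolume] (or subclass).
#' @return The 3D numeric array of voxel values.
#' @export
setGeneric("imgData", function(x) standardGeneric("imgData"))

#' Voxel spacing in mm
#'
#' @param x An [ImageVolume] (or subclass).
#' @return Numeric length-3 voxel size in mm.
#' @export
setGeneric("imgSpacing", function(x) standardGeneric("imgSpacing"))

#' Voxel-to-world affine
#'
#' @param x An [ImageVolume] (or subclass).
#' @return The 4x4 affine matrix (NIfTI convention, 0-based voxel indices).
#' @export
setGeneric("imgAffine", function(x) standardGeneric("imgAffine"))

#' Apply a 3D Gaussian filter
#'
#' @param vol The volume to smooth.
#' @param sdMm Gaussian SD in mm: a single value (isotropic) or one per axis.
#' @return A volume of the same class on the same grid.
#' @export
setGeneric("gaussianSmooth", function(vol, sdMm) standardGeneric("gaussianSmooth"))

setMethod("imgData", "ImageVolume", function(x) x@data)
setMethod("imgSpacing", "ImageVolume", function(x) x@spacing)
setMethod("imgAffine", "ImageVolume", function(x) x@affine)

#' @describeIn imgData Grid dimensions of a volume.
#' @export
setMethod("dim", "ImageVolume", function(x) dim(x@data))

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("%s: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              class(object), d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  v <- object@data[!is.nan(object@data)]
  if (length(v))
    cat(sprintf("  values: [%.4g, %.4g], %d excluded (NaN) voxels\n",
                min(v), max(v), sum(is.nan(object@data))))
  else cat("  all voxels excluded (NaN)\n")
  invisible(NULL)
})

setMethod("show", "LabelVolume", function(object) {
  callNextMethod()
  labs <- sort(unique(as.vector(object@data)))
  labs <- labs[labs > 0]
  cat(sprintf("  %d labels%s\n", length(labs),
              if (!is.na(object@referenceLabel))
                sprintf(", reference label %d", object@referenceLabel)
              else ""))
  invisible(NULL)
})

setMethod("show", "SmoothingSpec", function(object) {
  cat(sprintf(paste0("SmoothingSpec: scanner %.3g mm + filter %.3g mm (%s)",
                     " -> PET %.4g mm; struct %.3g mm -> kernel %.4g mm\n"),
              object@petScannerSd, object@petFilterSd, object@rule,
              combinedPetSd(object), object@structSd,
              matchingKernelSd(object)))
  invisible(NULL)
})

setMethod("show", "SUVRResult", function(object) {
  cat(sprintf("SUVRResult: reference label %d, reference value %.6g (%d voxels)%s\n",
              object@referenceLabel, object@referenceValue,
              object@erodedRefVoxels,
              if (!is.na(object@alphaApplied))
                sprintf(", alpha %.4g applied", object@alphaApplied) else ""))
  show(object@suvr)
  invisible(NULL)
})
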