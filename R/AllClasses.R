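#' @import methods
NULL

#' ImageVolume: a 3D image on a fixed grid
#'
#' The common currency of every pipeline stage: a 3D array of real values
#' together with per-axis voxel spacing (mm) and a 4x4 voxel-to-world affine
#' following the NIfTI convention (0-based voxel indices). Voxels excluded
#' from analysis (e.g. outside the gray-matter mask after partial volume
#' correction) are stored as `NaN`; all other values must be finite.
#'
#' @slot data 3D numeric array.
#' @slot spacing Numeric length-3, positive voxel size in mm.
#' @slot affine 4x4 numeric voxel-to-world transform.
#'
#' @seealso [ImageVolume()], [readVolume()], [writeVolume()]
#' @export
setClass("ImageVolume",
  representation(data = "array", spacing = "numeric", affine = "matrix"))

setValidity("ImageVolume", function(object) {
  msg <- character()
  d <- object@data
  if (length(dim(d)) != 3L)
    msg <- c(msg, sprintf("data must be a 3D array (got %d dims)",
                          length(dim(d))))
  if (length(dim(d)) == 3L && any(dim(d) < 1L))
    msg <- c(msg, "grid must have at least one voxel per axis")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive finite values (mm)")
  if (!all(dim(object@affine) == c(4L, 4L)))
    msg <- c(msg, "affine must be a 4x4 matrix")
  else if (any(!is.finite(object@affine)))
    msg <- c(msg, "affine entries must be finite")
  # NaN marks excluded voxels; +/-Inf is never legal
  if (any(is.infinite(d)))
    msg <- c(msg, "data contains infinite values")
  if (length(msg)) msg else TRUE
})

#' ProbabilityMap: a tissue probability volume
#'
#' An [ImageVolume] whose values lie in \[0, 1\] — the gray- or white-matter
#' probability maps produced by an external segmentation tool, before or
#' after resolution-matching smoothing. Values within 1e-6 outside \[0, 1\]
#' are clamped on construction; larger excursions are an error.
#'
#' @seealso [ProbabilityMap()]
#' @export
setClass("ProbabilityMap", contains = "ImageVolume")

setValidity("ProbabilityMap", function(object) {
  v <- object@data
  v <- v[!is.nan(v)]
  if (length(v) && (min(v) < 0 || max(v) > 1))
    "probability values must lie in [0, 1]"
  else TRUE
})

#' BinaryMask: a 0/1 voxel set
#'
#' An [ImageVolume] holding exactly 0s and 1s, produced by thresholding a
#' probability map or by selecting an atlas label. Shares its grid with the
#' volume it was derived from.
#'
#' @seealso [BinaryMask()], [thresholdMask()], [voiMask()]
#' @export
setClass("BinaryMask", contains = "ImageVolume")

setValidity("BinaryMask", function(object) {
  v <- object@data
  if (!all(v == 0 | v == 1)) "mask values must be exactly 0 or 1" else TRUE
})

#' LabelVolume: an integer-labelled VOI atlas
#'
#' An [ImageVolume] with non-negative integer values: 0 is background, each
#' positive label one volume of interest (VOI). Carries an optional
#' label-to-name mapping and the label of the reference (cerebellar) region.
#'
#' @slot labelNames Named character vector; names are label integers.
#' @slot referenceLabel Integer label of the reference region (NA if unset).
#'
#' @seealso [LabelVolume()], [voiMask()]
#' @export
setClass("LabelVolume", contains = "ImageVolume",
  representation(labelNames = "character", referenceLabel = "integer"))

setValidity("LabelVolume", function(object) {
  v <- object@data
  msg <- character()
  if (any(v < 0) || any(v != round(v)))
    msg <- c(msg, "labels must be non-negative integers")
  rl <- object@referenceLabel
  if (length(rl) != 1L)
    msg <- c(msg, "referenceLabel must be a single integer (possibly NA)")
  else if (!is.na(rl) && !any(v == rl))
    msg <- c(msg, sprintf("reference label %d does not occur in the volume", rl))
  if (length(msg)) msg else TRUE
})

#' SmoothingSpec: PSF bookkeeping for resolution matching
#'
#' Records the Gaussian point-spread-function standard deviations (mm) of
#' the PET scanner, of the reconstruction filter applied when the PET image
#' was created, and of the structural (CT or MRI) image, together with the
#' rule used to combine them: `"additive"` adds SDs linearly, `"quadrature"`
#' combines them as the square root of the sum of squares (the composition
#' law of Gaussian convolution).
#'
#' @slot petScannerSd PET scanner PSF SD in mm (default 4.0).
#' @slot petFilterSd PET reconstruction filter SD in mm (default 5.0).
#' @slot structSd Structural image PSF SD in mm (default 1.0).
#' @slot rule `"additive"` or `"quadrature"`.
#'
#' @seealso [SmoothingSpec()], [combinedPetSd()], [matchingKernelSd()]
#' @export
setClass("SmoothingSpec",
  representation(petScannerSd = "numeric", petFilterSd = "numeric",
                 structSd = "numeric", rule = "character"))

setValidity("SmoothingSpec", function(object) {
  msg <- character()
  sds <- c(object@petScannerSd, object@petFilterSd, object@structSd)
  if (length(sds) != 3L || any(!is.finite(sds)) || any(sds < 0))
    msg <- c(msg, "all PSF SDs must be single finite values >= 0")
  if (length(object@rule) != 1L ||
      !object@rule %in% c("additive", "quadrature"))
    msg <- c(msg, "rule must be \"additive\" or \"quadrature\"")
  if (length(msg)) msg else TRUE
})

#' PVCConfig: parameters of the partial volume correction
#'
#' @slot wmThreshold Probability threshold defining the deep white-matter
#'   mask on the smoothed WM map (default 0.95).
#' @slot gmThreshold Probability threshold defining the evaluable gray-matter
#'   mask on the smoothed GM map (default 0.35).
#' @slot negativePolicy What to do with voxels that go negative after the WM
#'   bias subtraction: `"keep"` (default) or `"clip_to_zero"`.
#' @slot wmStatistic Representative value of the WM-masked PET used as the
#'   nonspecific-binding reference: `"median"` (default; robust to outliers)
#'   or `"max"`.
#'
#' @seealso [PVCConfig()], [runPvc()]
#' @export
setClass("PVCConfig",
  representation(wmThreshold = "numeric", gmThreshold = "numeric",
                 negativePolicy = "character", wmStatistic = "character"))

setValidity("PVCConfig", function(object) {
  msg <- character()
  for (thr in list(c("wmThreshold", object@wmThreshold),
                   c("gmThreshold", object@gmThreshold))) {
    v <- as.numeric(thr[2])
    if (!is.finite(v) || v <= 0 || v >= 1)
      msg <- c(msg, sprintf("%s must lie strictly in (0, 1)", thr[1]))
  }
  if (!object@negativePolicy %in% c("keep", "clip_to_zero"))
    msg <- c(msg, "negativePolicy must be \"keep\" or \"clip_to_zero\"")
  if (!object@wmStatistic %in% c("median", "max"))
    msg <- c(msg, "wmStatistic must be \"median\" or \"max\"")
  if (length(msg)) msg else TRUE
})

#' SUVRResult: an SUVR image with its provenance
#'
#' @slot suvr [ImageVolume] of SUVR values (NaN where excluded).
#' @slot referenceValue Median PVC-PET value over the eroded reference VOI.
#' @slot referenceLabel Label of the reference region.
#' @slot erodedRefVoxels Number of voxels in the eroded reference VOI that
#'   contributed to the reference value.
#' @slot alphaApplied Cross-modality slope applied to the image (NA if none).
#'
#' @seealso [computeSuvr()], [applyAlpha()]
#' @export
setClass("SUVRResult",
  representation(suvr = "ImageVolume", referenceValue = "numeric",
                 referenceLabel = "integer", erodedRefVoxels = "integer",
                 alphaApplied = "numeric"))

setValidity("SUVRResult", function(object) {
  msg <- character()
  if (!is.finite(object@referenceValue) || object@referenceValue <= 0)
    msg <- c(msg, "referenceValue must be a positive finite number")
  if (!is.na(object@alphaApplied) && object@alphaApplied <= 0)
    msg <- c(msg, "alphaApplied must be positive (or NA)")
  if (length(msg)) msg else TRUE
})

#' PhantomSpec: geometry and signal model of the digital head phantom
#'
#' Defines a nested-ellipsoid "cerebrum" (outer CSF envelope, gray-matter
#' shell, white-matter core) plus a separate cerebellar ellipsoid pair (GM
#' shell + WM core), the tracer uptake of each compartment, the PET point
#' spread function, additive Gaussian noise, and the softness of tissue
#' boundaries. All lengths in mm, uptakes in arbitrary activity units.
#'
#' @slot shape Grid dimensions (3 integers).
#' @slot spacing Voxel size in mm (3 positive reals).
#' @slot cerebrumCenter,cerebrumCsfSemi,cerebrumGmSemi,cerebrumWmSemi
#'   Center offset from the grid center and semi-axes (mm) of the nested
#'   cerebral ellipsoids (CSF envelope > GM envelope > WM core).
#' @slot cerebellumCenter,cerebellumGmSemi,cerebellumWmSemi Center offset and
#'   semi-axes of the cerebellar GM shell and WM core.
#' @slot aGm,aWm,aRef Specific cortical GM uptake, nonspecific WM uptake and
#'   cerebellar GM uptake (activity units).
#' @slot psfSd SD (mm) of the Gaussian PSF of the simulated PET image.
#' @slot noiseSd SD of additive Gaussian noise (activity units).
#' @slot boundarySoftness Width (mm) over which tissue probability ramps
#'   from 0 to 1 at compartment boundaries (0 gives binary maps).
#' @slot nVois Number of angular cortical VOI sectors carved from the GM
#'   shell (the cerebellar reference label is `nVois + 1`).
#' @slot seed Integer seed controlling the noise realization.
#'
#' @seealso [PhantomSpec()], [generateTissueMaps()], [simulatePet()]
#' @export
setClass("PhantomSpec",
  representation(shape = "integer", spacing = "numeric",
                 cerebrumCenter = "numeric", cerebrumCsfSemi = "numeric",
                 cerebrumGmSemi = "numeric", cerebrumWmSemi = "numeric",
                 cerebellumCenter = "numeric", cerebellumGmSemi = "numeric",
                 cerebellumWmSemi = "numeric",
                 aGm = "numeric", aWm = "numeric", aRef = "numeric",
                 psfSd = "numeric", noiseSd = "numeric",
                 boundarySoftness = "numeric", nVois = "integer",
                 seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@shape) != 3L || any(object@shape < 1L))
    msg <- c(msg, "shape must be 3 positive integers")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive reals (mm)")
  if (any(c(object@aGm, object@aWm, object@aRef) < 0))
    msg <- c(msg, "uptakes must be >= 0")
  if (object@psfSd < 0 || object@noiseSd < 0 || object@boundarySoftness < 0)
    msg <- c(msg, "psfSd, noiseSd and boundarySoftness must be >= 0")
  if (object@nVois < 1L)
    msg <- c(msg, "nVois must be >= 1")
  semis <- list(object@cerebrumCsfSemi, object@cerebrumGmSemi,
                object@cerebrumWmSemi, object@cerebellumGmSemi,
                object@cerebellumWmSemi)
  if (any(vapply(semis, function(s) length(s) != 3L || any(s <= 0), TRUE)))
    msg <- c(msg, "all semi-axes must be 3 positive reals (mm)")
  if (!all(object@cerebrumCsfSemi > object@cerebrumGmSemi) ||
      !all(object@cerebrumGmSemi > object@cerebrumWmSemi))
    msg <- c(msg, "cerebral ellipsoids must nest: CSF > GM > WM semi-axes")
  if (!all(object@cerebellumGmSemi > object@cerebellumWmSemi))
    msg <- c(msg, "cerebellar GM semi-axes must exceed the WM core")
  if (length(msg)) msg else TRUE
})
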