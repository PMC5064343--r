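#' Construct a PVCConfig
#'
#' Defaults are the operating parameters of the correction: deep white
#' matter defined by probability >= 0.95 on the smoothed WM map, evaluable
#' gray matter by >= 0.35 on the smoothed GM map, the median as the robust
#' WM reference statistic, and negative post-subtraction voxels kept (they
#' carry noise information into the SUVR stage).
#'
#' @param wmThreshold WM mask threshold in (0, 1). Default 0.95.
#' @param gmThreshold GM mask threshold in (0, 1). Default 0.35.
#' @param negativePolicy `"keep"` (default) or `"clip_to_zero"`.
#' @param wmStatistic `"median"` (default) or `"max"` (the older convention
#'   for the WM reference).
#' @return A [PVCConfig-class] object.
#' @export
PVCConfig <- function(wmThreshold = 0.95, gmThreshold = 0.35,
                      negativePolicy = c("keep", "clip_to_zero"),
                      wmStatistic = c("median", "max")) {
  new("PVCConfig", wmThreshold = wmThreshold, gmThreshold = gmThreshold,
      negativePolicy = match.arg(negativePolicy),
      wmStatistic = match.arg(wmStatistic))
}

#' Threshold a probability map into a binary mask
#'
#' Mask is 1 where probability >= `thr` (inclusive, so an all-ones map
#' satisfies any threshold below 1), 0 elsewhere. An empty mask is permitted
#' here; downstream operations decide whether emptiness is fatal.
#'
#' @param prob A [ProbabilityMap-class].
#' @param thr Threshold in (0, 1).
#' @return A [BinaryMask-class] on the same grid.
#' @export
thresholdMask <- function(prob, thr) {
  stopifnot(is(prob, "ProbabilityMap"))
  if (!is.finite(thr) || thr <= 0 || thr >= 1)
    stop("threshold must lie strictly in (0, 1)")
  m <- (!is.nan(prob@data)) & prob@data >= thr
  sameGrid(prob, array(as.numeric(m), dim = dim(prob@data)), "BinaryMask")
}

#' Median (or max) of a volume under a mask
#'
#' @param vol An [ImageVolume-class].
#' @param mask A [BinaryMask-class] on the same grid.
#' @param statistic `"median"` (default; even counts give the midpoint of
#'   the two central order statistics) or `"max"`.
#' @return A single number.
#' @export
maskedStatistic <- function(vol, mask, statistic = c("median", "max")) {
  statistic <- match.arg(statistic)
  stopifnot(is(mask, "BinaryMask"))
  assertSameGrid(list(vol, mask))
  vals <- vol@data[mask@data == 1]
  if (!length(vals))
    stop("WM mask empty: no voxels with probability >= threshold ",
         "(check segmentation and smoothing)")
  if (statistic == "median") stats::median(vals) else max(vals)
}

#' @rdname maskedStatistic
#' @export
maskedMedian <- function(vol, mask) maskedStatistic(vol, mask, "median")

#' Subtract the white-matter nonspecific-binding bias
#'
#' The bias signal at each voxel is the WM reference value times the voxel's
#' smoothed WM probability; it is subtracted voxelwise from the PET image.
#' A phantom synthesized as `pet = aGm * GMs + aWm * WMs` with deep-WM
#' voxels (WMs >= 0.95, GMs = 0) yields `wmRef = aWm`, and the output is
#' exactly `aGm * GMs`.
#'
#' @param pet PET [ImageVolume-class].
#' @param wmSmooth Smoothed WM [ProbabilityMap-class] on the same grid.
#' @param wmRef The WM reference value (from [maskedMedian()]).
#' @param negativePolicy `"keep"` (default) or `"clip_to_zero"`.
#' @return Bias-corrected PET [ImageVolume-class].
#' @export
subtractWmBias <- function(pet, wmSmooth, wmRef,
                           negativePolicy = c("keep", "clip_to_zero")) {
  negativePolicy <- match.arg(negativePolicy)
  stopifnot(is(wmSmooth, "ProbabilityMap"), is.finite(wmRef))
  assertSameGrid(list(pet, wmSmooth))
  out <- pet@data - wmRef * wmSmooth@data
  if (negativePolicy == "clip_to_zero") out[!is.nan(out) & out < 0] <- 0
  sameGrid(pet, out)
}

#' Divide by the smoothed gray-matter probability map
#'
#' The tissue-fraction step: each bias-corrected voxel is divided by its
#' smoothed GM probability, restricted to the GM mask so every divisor is
#' bounded below by the GM threshold. Voxels outside the mask are excluded
#' (NaN).
#'
#' @param petCorr Bias-corrected PET [ImageVolume-class].
#' @param gmSmooth Smoothed GM [ProbabilityMap-class].
#' @param gmMask GM [BinaryMask-class] derived from `gmSmooth` by
#'   [thresholdMask()].
#' @return PVC-PET [ImageVolume-class], NaN outside the GM mask.
#' @export
divideByGm <- function(petCorr, gmSmooth, gmMask) {
  stopifnot(is(gmSmooth, "ProbabilityMap"), is(gmMask, "BinaryMask"))
  assertSameGrid(list(petCorr, gmSmooth, gmMask))
  if (!any(gmMask@data == 1))
    stop("GM mask empty: no evaluable gray matter ",
         "(no voxels with probability >= threshold)")
  out <- array(NaN, dim = dim(petCorr@data))
  inm <- gmMask@data == 1
  out[inm] <- petCorr@data[inm] / gmSmooth@data[inm]
  sameGrid(petCorr, out)
}

#' Run the full partial volume correction
#'
#' Executes, in order: smooth the GM and WM probability maps with the
#' resolution-matching kernel ([matchingKernelSd()]); build the WM mask at
#' `cfg@wmThreshold`; take the WM reference statistic of the masked PET;
#' subtract the WM bias voxelwise; build the GM mask at `cfg@gmThreshold`;
#' divide by the smoothed GM map inside that mask. Returns the masked
#' PVC-PET image plus a provenance record.
#'
#' The correction is homogeneous of degree 1: scaling the PET image by c
#' scales the PVC-PET image by c (the WM reference scales along).
#'
#' @param pet PET [ImageVolume-class].
#' @param gmProb,wmProb GM and WM [ProbabilityMap-class] on the PET grid
#'   (raw, unsmoothed — smoothing happens here).
#' @param cfg A [PVCConfig-class].
#' @param smoothing A [SmoothingSpec-class].
#' @param smoothingSdMm Optional explicit kernel SD override in mm (scalar
#'   or per-axis); 0 disables smoothing (for maps already at PET
#'   resolution). Default `matchingKernelSd(smoothing)`.
#' @return List with `pvcPet` ([ImageVolume-class], NaN outside the GM
#'   mask), `gmMask`, `wmMask`, and `report` (wmRef, mask voxel counts,
#'   kernel SD, rule, thresholds).
#' @export
runPvc <- function(pet, gmProb, wmProb, cfg = PVCConfig(),
                   smoothing = SmoothingSpec(),
                   smoothingSdMm = matchingKernelSd(smoothing)) {
  stopifnot(is(gmProb, "ProbabilityMap"), is(wmProb, "ProbabilityMap"),
            is(cfg, "PVCConfig"))
  assertSameGrid(list(pet, gmProb, wmProb))
  gmS <- gaussianSmooth(gmProb, smoothingSdMm)
  wmS <- gaussianSmooth(wmProb, smoothingSdMm)
  wmMask <- thresholdMask(wmS, cfg@wmThreshold)
  wmRef <- maskedStatistic(pet, wmMask, cfg@wmStatistic)
  corr <- subtractWmBias(pet, wmS, wmRef, cfg@negativePolicy)
  gmMask <- thresholdMask(gmS, cfg@gmThreshold)
  pvcPet <- divideByGm(corr, gmS, gmMask)
  list(pvcPet = pvcPet, gmMask = gmMask, wmMask = wmMask,
       report = list(wmRef = wmRef,
                     wmStatistic = cfg@wmStatistic,
                     wmMaskVoxels = sum(wmMask@data == 1),
                     gmMaskVoxels = sum(gmMask@data == 1),
                     kernelSdMm = smoothingSdMm,
                     rule = smoothing@rule,
                     wmThreshold = cfg@wmThreshold,
                     gmThreshold = cfg@gmThreshold,
                     negativePolicy = cfg@negativePolicy))
}
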