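#' Construct a SmoothingSpec
#'
#' The defaults are the operating assumptions of a PET/CT amyloid protocol:
#' scanner PSF SD 4.0 mm, 5.0 mm Gaussian reconstruction filter, structural
#' (CT) PSF SD 1.0 mm, combined by the additive rule. The additive rule adds
#' SDs linearly; the physically standard composition of Gaussian
#' convolutions combines them in quadrature (`sqrt(a^2 + b^2)`) and is
#' available as `rule = "quadrature"`. The two are never silently
#' substituted for one another.
#'
#' @param petScannerSd PET scanner PSF SD (mm).
#' @param petFilterSd SD of the Gaussian filter applied when creating the
#'   PET image (mm).
#' @param structSd Structural image PSF SD (mm).
#' @param rule `"additive"` (default) or `"quadrature"`.
#' @return A [SmoothingSpec-class] object.
#' @examples
#' spec <- SmoothingSpec()
#' combinedPetSd(spec)    # 9
#' matchingKernelSd(spec) # 8
#' @export
SmoothingSpec <- function(petScannerSd = 4.0, petFilterSd = 5.0,
                          structSd = 1.0, rule = c("additive", "quadrature")) {
  rule <- match.arg(rule)
  spec <- new("SmoothingSpec", petScannerSd = as.numeric(petScannerSd),
              petFilterSd = as.numeric(petFilterSd),
              structSd = as.numeric(structSd), rule = rule)
  # construction fails outright if no non-negative matching kernel exists
  matchingKernelSd(spec)
  spec
}

#' Effective PSF SD of the reconstructed, filtered PET image
#'
#' Combines the scanner PSF SD with the reconstruction filter SD under the
#' spec's rule: `additive` returns their sum, `quadrature` the root sum of
#' squares.
#'
#' @param spec A [SmoothingSpec-class].
#' @return SD in mm.
#' @export
combinedPetSd <- function(spec) {
  stopifnot(is(spec, "SmoothingSpec"))
  switch(spec@rule,
         additive = spec@petScannerSd + spec@petFilterSd,
         quadrature = sqrt(spec@petScannerSd^2 + spec@petFilterSd^2))
}

#' Kernel SD matching probability-map resolution to the PET image
#'
#' The SD of the 3D Gaussian filter to apply to the tissue probability maps
#' so that their spatial resolution matches the PET image: the combined PET
#' PSF SD minus the structural PSF SD (additive rule), or the quadrature
#' difference `sqrt(pet^2 - struct^2)`.
#'
#' @param spec A [SmoothingSpec-class].
#' @return SD in mm (>= 0).
#' @export
matchingKernelSd <- function(spec) {
  stopifnot(is(spec, "SmoothingSpec"))
  pet <- combinedPetSd(spec)
  out <- switch(spec@rule,
                additive = pet - spec@structSd,
                quadrature = {
                  d <- pet^2 - spec@structSd^2
                  if (d < 0) -1 else sqrt(d)
                })
  if (out < 0)
    stop("structural image is blurrier than the PET image (combined PET SD ",
         signif(pet, 4), " mm < structural SD ", spec@structSd,
         " mm); check inputs or the combination rule")
  out
}

# Internal: 1D discrete Gaussian kernel, truncated at 4 SD, normalized to
# sum 1 over its support.
gaussKernel1d <- function(sdVox) {
  r <- ceiling(4 * sdVox)
  w <- stats::dnorm(seq(-r, r), sd = sdVox)
  w / sum(w)
}

# Internal: convolve a 3D array along one axis with a normalized kernel,
# constant-0 extension outside the grid (outside the head there is no
# tissue). Implemented as a banded-matrix product along the permuted axis.
convolveAxis <- function(arr, axis, sdVox) {
  if (sdVox == 0) return(arr)
  d <- dim(arr)
  n <- d[axis]
  w <- gaussKernel1d(sdVox)
  r <- (length(w) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (k in seq(-r, r)) {
    i <- seq_len(n)
    j <- i + k
    ok <- j >= 1L & j <= n
    K[cbind(i[ok], j[ok])] <- w[k + r + 1L]
  }
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- K %*% matrix(a, nrow = n)
  out <- array(m, dim = d[perm])
  aperm(out, order(perm))
}

#' @describeIn gaussianSmooth Separable 3D Gaussian smoothing of an
#'   [ImageVolume-class]. The SD is given in mm and converted to voxels per
#'   axis (`sdMm / spacing`); an SD of 0 on an axis is the identity on that
#'   axis. The kernel is truncated at 4 SD and normalized; outside the grid
#'   the volume is extended with zeros, so values near the border shrink
#'   toward 0 — consistent with the tissue-fraction reading of the maps
#'   (no tissue outside the field of view).
#' @export
setMethod("gaussianSmooth", "ImageVolume", function(vol, sdMm) {
  if (length(sdMm) == 1L) sdMm <- rep(sdMm, 3L)
  stopifnot(length(sdMm) == 3L)
  if (any(!is.finite(sdMm)) || any(sdMm < 0))
    stop("smoothing SD must be finite and >= 0 per axis")
  if (any(!is.finite(vol@data)))
    stop("cannot smooth a volume containing non-finite values")
  arr <- vol@data
  sdVox <- sdMm / vol@spacing
  for (ax in 1:3) arr <- convolveAxis(arr, ax, sdVox[ax])
  sameGrid(vol, arr)
})

#' @describeIn gaussianSmooth Smoothing a [ProbabilityMap-class] returns a
#'   ProbabilityMap; convex averaging keeps values in \[0, 1\] up to
#'   rounding, which is clamped.
#' @export
setMethod("gaussianSmooth", "ProbabilityMap", function(vol, sdMm) {
  out <- callNextMethod(vol, sdMm)
  ProbabilityMap(out@data, spacing = out@spacing, affine = out@affine)
})
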