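#' Construct a PhantomSpec
#'
#' Digital head phantom: a nested-ellipsoid cerebrum (CSF envelope,
#' gray-matter shell, white-matter core) and a smaller cerebellar ellipsoid
#' pair below and behind it, on a 96^3 grid of 2 mm voxels by default. The
#' default signal model mirrors an amyloid study: cerebellar cortex uptake
#' 1 (the reference tissue, no specific binding), nonspecific white-matter
#' uptake 1.5 (in controls WM is the brightest tissue), cortical gray-matter
#' uptake 2 (an amyloid-positive cortical-to-cerebellar ratio of 2), a
#' Gaussian PET point spread function of SD 9 mm (scanner PSF 4 mm plus a
#' 5 mm reconstruction filter, combined additively), and additive Gaussian
#' noise of SD 0.05 activity units.
#'
#' @param shape Grid dimensions. Default `c(96, 96, 96)`.
#' @param spacing Voxel size in mm. Default 2 mm isotropic.
#' @param cerebrumCenter Offset (mm) of the cerebrum from the grid center.
#' @param cerebrumCsfSemi,cerebrumGmSemi,cerebrumWmSemi Semi-axes (mm) of
#'   the nested cerebral ellipsoids.
#' @param cerebellumCenter,cerebellumGmSemi,cerebellumWmSemi Cerebellar
#'   geometry (mm).
#' @param aGm,aWm,aRef Uptake of cortical GM, WM and cerebellar GM.
#' @param psfSd PET PSF SD in mm. Default 9.
#' @param noiseSd Additive Gaussian noise SD. Default 0.05.
#' @param boundarySoftness Tissue boundary ramp width in mm (emulates
#'   segmentation softness). Default 1.
#' @param nVois Number of cortical VOI sectors. Default 8.
#' @param seed Noise seed. Default 1.
#' @return A [PhantomSpec-class].
#' @export
PhantomSpec <- function(shape = c(96, 96, 96), spacing = c(2, 2, 2),
                        cerebrumCenter = c(0, 6, 12),
                        cerebrumCsfSemi = c(46, 52, 40),
                        cerebrumGmSemi = c(42, 48, 36),
                        cerebrumWmSemi = c(28, 34, 22),
                        cerebellumCenter = c(0, -32, -40),
                        cerebellumGmSemi = c(24, 20, 18),
                        cerebellumWmSemi = c(8, 6, 5),
                        aGm = 2, aWm = 1.5, aRef = 1,
                        psfSd = 9, noiseSd = 0.05,
                        boundarySoftness = 1, nVois = 8, seed = 1) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("PhantomSpec", shape = as.integer(shape), spacing = as.numeric(spacing),
      cerebrumCenter = cerebrumCenter, cerebrumCsfSemi = cerebrumCsfSemi,
      cerebrumGmSemi = cerebrumGmSemi, cerebrumWmSemi = cerebrumWmSemi,
      cerebellumCenter = cerebellumCenter, cerebellumGmSemi = cerebellumGmSemi,
      cerebellumWmSemi = cerebellumWmSemi,
      aGm = aGm, aWm = aWm, aRef = aRef, psfSd = psfSd, noiseSd = noiseSd,
      boundarySoftness = boundarySoftness, nVois = as.integer(nVois),
      seed = as.integer(seed))
}

# Internal: world-coordinate grids (mm) relative to the grid center, as
# three arrays matching the phantom shape.
phantomCoords <- function(spec) {
  ctr <- (spec@shape - 1) * spec@spacing / 2
  ax <- lapply(1:3, function(i)
    seq(0, spec@shape[i] - 1) * spec@spacing[i] - ctr[i])
  d <- spec@shape
  list(x = array(rep(ax[[1]], times = d[2] * d[3]), dim = d),
       y = array(rep(rep(ax[[2]], each = d[1]), times = d[3]), dim = d),
       z = array(rep(ax[[3]], each = d[1] * d[2]), dim = d))
}

# Internal: smooth ellipsoid indicator. r is the normalized ellipsoidal
# radius; the mm distance to the surface is approximated as (1 - r) times
# the geometric-mean semi-axis, and the indicator ramps linearly from 0 to
# 1 over boundarySoftness mm centered on the surface. Softness 0 gives the
# exact binary indicator r <= 1.
ellipsoidIndicator <- function(co, center, semi, softness) {
  r <- sqrt(((co$x - center[1]) / semi[1])^2 +
            ((co$y - center[2]) / semi[2])^2 +
            ((co$z - center[3]) / semi[3])^2)
  if (softness == 0) return(array(as.numeric(r <= 1), dim = dim(r)))
  scale <- prod(semi)^(1 / 3)
  d <- (1 - r) * scale
  pmin(pmax(d / softness + 0.5, 0), 1)  # array first: pmax keeps dim
}

#' Generate phantom tissue probability maps and VOI labels
#'
#' Deterministic given the spec. GM, WM and CSF probabilities are built
#' from nested smooth ellipsoid indicators so that GM + WM + CSF <= 1 at
#' every voxel. Labels carve the cerebral GM shell (probability >= 0.5)
#' into `nVois` angular sectors around the cerebrum axis; the cerebellar
#' GM shell is the reference label `nVois + 1`. Generation validates that a
#' deep-WM region (WM probability >= 0.95 with GM probability 0) exists and
#' that the geometry fits the grid with a margin of 4 PSF SDs.
#'
#' @param spec A [PhantomSpec-class].
#' @return List with `gm`, `wm`, `csf` ([ProbabilityMap-class]) and
#'   `labels` ([LabelVolume-class]).
#' @export
generateTissueMaps <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  halfExtent <- (spec@shape - 1) * spec@spacing / 2
  margin <- 4 * spec@psfSd
  reach <- pmax(abs(spec@cerebrumCenter) + spec@cerebrumCsfSemi,
                abs(spec@cerebellumCenter) + spec@cerebellumGmSemi)
  if (any(reach + margin > halfExtent))
    stop("phantom geometry does not fit the grid with a 4-SD PSF margin: ",
         "needs half-extent [", paste(round(reach + margin, 1), collapse = ", "),
         "] mm, grid offers [", paste(round(halfExtent, 1), collapse = ", "), "]")
  co <- phantomCoords(spec)
  s <- spec@boundarySoftness
  csfEnv <- ellipsoidIndicator(co, spec@cerebrumCenter, spec@cerebrumCsfSemi, s)
  gmEnv  <- ellipsoidIndicator(co, spec@cerebrumCenter, spec@cerebrumGmSemi, s)
  wmCore <- ellipsoidIndicator(co, spec@cerebrumCenter, spec@cerebrumWmSemi, s)
  cbGmEnv <- ellipsoidIndicator(co, spec@cerebellumCenter, spec@cerebellumGmSemi, s)
  cbWmCore <- ellipsoidIndicator(co, spec@cerebellumCenter, spec@cerebellumWmSemi, s)
  gmArr <- pmax(gmEnv - wmCore, 0) + pmax(cbGmEnv - cbWmCore, 0)
  wmArr <- wmCore + cbWmCore
  csfArr <- pmax(csfEnv - gmEnv, 0)
  total <- gmArr + wmArr + csfArr
  if (max(total) > 1 + 1e-6)
    stop("tissue probabilities exceed 1 (overlapping compartments); ",
         "max sum = ", max(total))
  gmArr <- pmin(gmArr, 1); wmArr <- pmin(wmArr, 1)
  if (!any(wmArr >= 0.95 & gmArr == 0))
    stop("no deep-WM voxels (WM >= 0.95 with GM = 0): geometry too thin")
  lab <- array(0, dim = spec@shape)
  ctx <- pmax(gmEnv - wmCore, 0) >= 0.5
  ang <- atan2(co$y - spec@cerebrumCenter[2], co$x - spec@cerebrumCenter[1])
  sector <- floor((ang + pi) / (2 * pi) * spec@nVois) + 1
  sector[sector > spec@nVois] <- spec@nVois
  lab[ctx] <- sector[ctx]
  refLab <- spec@nVois + 1L
  lab[pmax(cbGmEnv - cbWmCore, 0) >= 0.5] <- refLab
  nm <- c(sprintf("cortical_sector_%d", seq_len(spec@nVois)),
          "cerebellar_cortex")
  names(nm) <- as.character(c(seq_len(spec@nVois), refLab))
  sp <- spec@spacing
  list(gm = ProbabilityMap(gmArr, spacing = sp),
       wm = ProbabilityMap(wmArr, spacing = sp),
       csf = ProbabilityMap(csfArr, spacing = sp),
       labels = LabelVolume(lab, spacing = sp, labelNames = nm,
                            referenceLabel = refLab))
}

#' Simulate a PET acquisition of the phantom
#'
#' The true activity is `aGm * gm + aWm * wm`, with the cerebellar GM
#' uptake `aRef` substituted inside the reference label; the observed image
#' is the true activity blurred by the Gaussian PSF plus additive Gaussian
#' noise. Bit-identical for a fixed seed.
#'
#' @param spec A [PhantomSpec-class].
#' @param gm,wm [ProbabilityMap-class]s from [generateTissueMaps()].
#' @param labels [LabelVolume-class] from the same call (locates the
#'   cerebellar reference region).
#' @return List with `petTrue` and `petObserved` ([ImageVolume-class]).
#' @export
simulatePet <- function(spec, gm, wm, labels) {
  stopifnot(is(spec, "PhantomSpec"))
  assertSameGrid(list(gm, wm, labels))
  a <- spec@aGm * gm@data + spec@aWm * wm@data
  inRef <- labels@data == labels@referenceLabel
  a[inRef] <- spec@aRef * gm@data[inRef] + spec@aWm * wm@data[inRef]
  petTrue <- sameGrid(gm, a)
  obs <- gaussianSmooth(petTrue, spec@psfSd)
  if (spec@noiseSd > 0) {
    set.seed(spec@seed)
    obs@data <- obs@data + stats::rnorm(length(obs@data), sd = spec@noiseSd)
  }
  list(petTrue = petTrue, petObserved = obs)
}

#' Generate a complete phantom case
#'
#' `profile = "AD"` sets the cortical GM uptake to twice the cerebellar
#' uptake (true cortical SUVR 2); `profile = "NL"` sets it equal (true
#' SUVR 1, leaving only the nonspecific WM signal as contrast).
#'
#' @param spec A [PhantomSpec-class] (its `aGm` is overridden by the
#'   profile).
#' @param profile `"AD"` or `"NL"`.
#' @return List with `petObserved`, `petTrue`, `gm`, `wm`, `csf`, `labels`
#'   and `groundTruth` (uptakes and the true SUVR of every VOI).
#' @export
generateCase <- function(spec = PhantomSpec(), profile = c("AD", "NL")) {
  profile <- match.arg(profile)
  spec@aGm <- if (profile == "AD") 2 * spec@aRef else spec@aRef
  maps <- generateTissueMaps(spec)
  pet <- simulatePet(spec, maps$gm, maps$wm, maps$labels)
  trueSuvr <- c(rep(spec@aGm / spec@aRef, spec@nVois), 1)
  names(trueSuvr) <- names(maps$labels@labelNames)
  c(pet, maps,
    list(groundTruth = list(profile = profile, aGm = spec@aGm,
                            aWm = spec@aWm, aRef = spec@aRef,
                            trueSuvr = trueSuvr, seed = spec@seed)))
}

#' Degrade probability maps into a coarser modality variant
#'
#' Emulates a second structural modality (e.g. CT next to MRI) by blurring
#' the maps further and adding clamped Gaussian jitter, for rehearsing the
#' cross-modality alpha workflow with known inputs.
#'
#' @param prob A [ProbabilityMap-class].
#' @param extraBlurMm Additional Gaussian SD in mm. Default 2.
#' @param jitterSd SD of additive probability jitter. Default 0.02.
#' @param seed Jitter seed.
#' @return A degraded [ProbabilityMap-class].
#' @export
degradeMaps <- function(prob, extraBlurMm = 2, jitterSd = 0.02, seed = 1) {
  stopifnot(is(prob, "ProbabilityMap"))
  out <- gaussianSmooth(prob, extraBlurMm)
  if (jitterSd > 0) {
    set.seed(seed)
    arr <- out@data + stats::rnorm(length(out@data), sd = jitterSd)
    out <- ProbabilityMap(pmin(pmax(arr, 0), 1), spacing = out@spacing,
                          affine = out@affine)
  }
  out
}

#' Simulate paired cross-modality SUVR voxel samples
#'
#' Draws per-VOI paired voxel values with a known inter-modality slope:
#' `x` uniform on a plausible SUVR range per VOI, `y = slope * x +`
#' Gaussian noise. Used to rehearse and validate the alpha-estimation
#' workflow ([voiRegression()] + [poolAlpha()]) against ground truth.
#'
#' @param nVois Number of VOIs. Default 8.
#' @param nPerVoi Voxels per VOI. Default 5000.
#' @param slope True inter-modality slope. Default 1.2.
#' @param noiseSd SD of the y-noise. Default 0.05.
#' @param xRange Range of x values. Default `c(0.8, 2.5)`.
#' @param seed Seed.
#' @return data.frame with columns `voi`, `x`, `y`.
#' @export
simulateSuvrPairs <- function(nVois = 8, nPerVoi = 5000, slope = 1.2,
                              noiseSd = 0.05, xRange = c(0.8, 2.5),
                              seed = 1) {
  set.seed(seed)
  voi <- rep(seq_len(nVois), each = nPerVoi)
  x <- stats::runif(nVois * nPerVoi, xRange[1], xRange[2])
  y <- slope * x + stats::rnorm(nVois * nPerVoi, sd = noiseSd)
  data.frame(voi = voi, x = x, y = y)
}
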