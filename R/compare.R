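#' Per-VOI regression between two SUVR modalities
#'
#' Ordinary least squares of the y-modality SUVR on the x-modality SUVR
#' over paired voxel values inside one VOI, pooled across subjects when the
#' inputs are concatenated pairs. Includes an intercept by default (set
#' `throughOrigin = TRUE` for a proportional fit as a sensitivity check).
#' Voxels excluded (NaN) in either image are dropped.
#'
#' @param suvrX,suvrY [SUVRResult-class] objects (or [ImageVolume-class]s)
#'   on one grid.
#' @param voi [BinaryMask-class] of the VOI.
#' @param voiLabel Integer label recorded in the result.
#' @param throughOrigin Fit without intercept. Default FALSE.
#' @return List (class `voiRegression`) with `voiLabel`, `slope`,
#'   `intercept`, `pearsonR`, `nVoxels`.
#' @export
voiRegression <- function(suvrX, suvrY, voi, voiLabel = NA_integer_,
                          throughOrigin = FALSE) {
  vx <- if (is(suvrX, "SUVRResult")) suvrX@suvr else suvrX
  vy <- if (is(suvrY, "SUVRResult")) suvrY@suvr else suvrY
  stopifnot(is(voi, "BinaryMask"))
  assertSameGrid(list(vx, vy, voi))
  sel <- voi@data == 1 & !is.nan(vx@data) & !is.nan(vy@data)
  x <- vx@data[sel]; y <- vy@data[sel]
  if (length(x) < 3L)
    stop("need at least 3 paired non-excluded voxels in the VOI; got ",
         length(x))
  if (stats::var(x) == 0)
    stop("degenerate regressor: x-modality SUVR has zero variance in the VOI")
  fit <- if (throughOrigin) stats::lm(y ~ x + 0) else stats::lm(y ~ x)
  cf <- stats::coef(fit)
  structure(list(voiLabel = as.integer(voiLabel),
                 slope = unname(cf[["x"]]),
                 intercept = if (throughOrigin) 0 else unname(cf[[1L]]),
                 pearsonR = stats::cor(x, y),
                 nVoxels = length(x)),
            class = "voiRegression")
}

#' Pool per-VOI slopes into a single cross-modality factor
#'
#' The correction factor alpha is the arithmetic mean of the per-VOI
#' regression slopes, on the assumption that a slope estimated in the
#' assessment VOIs applies throughout gray matter; its spread is reported
#' as the sample SD of the slopes (0 for a single VOI).
#'
#' @param regs List of [voiRegression()] results (>= 1).
#' @return List (class `alphaResult`) with `alpha`, `alphaSd`, `perVoi`.
#' @export
poolAlpha <- function(regs) {
  if (!length(regs)) stop("need at least one per-VOI regression")
  slopes <- vapply(regs, function(r) r$slope, numeric(1))
  structure(list(alpha = mean(slopes),
                 alphaSd = if (length(slopes) > 1L) stats::sd(slopes) else 0,
                 perVoi = regs),
            class = "alphaResult")
}

#' Mann-Whitney U test (two-sided)
#'
#' U statistic with midrank tie handling. The p-value is exact (from the
#' full permutation distribution) when both samples have at most
#' `exactMaxN` observations and there are no ties; otherwise the normal
#' approximation with tie-corrected variance and continuity correction is
#' used.
#'
#' @param a,b Numeric vectors (both nonempty).
#' @param exactMaxN Largest per-group size for the exact p-value. Default 8.
#' @return List with `U` (for sample `a`) and `p` (two-sided).
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
mannWhitneyU <- function(a, b, exactMaxN = 8) {
  if (!length(a) || !length(b)) stop("both groups must be nonempty")
  n <- length(a); m <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- any(duplicated(c(a, b)))
  useExact <- !ties && n <= exactMaxN && m <= exactMaxN
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = useExact, correct = TRUE))
  list(U = unname(U), p = wt$p.value)
}

#' Voxelwise t-test between two groups of images
#'
#' Per-voxel two-sample (pooled-variance) or paired t statistic with a
#' two-sided p-value from the t distribution, thresholded at `pThreshold`
#' without multiple-testing correction. A voxel is evaluated only where it
#' is non-excluded in every image; voxels with zero within-group variance
#' are marked non-evaluable (NaN in the t map, 0 in the mask), never
#' "infinitely significant".
#'
#' @param imagesA,imagesB Lists of [ImageVolume-class]s (>= 2 per group;
#'   paired mode requires equal counts in the same subject order).
#' @param paired Paired design. Default FALSE.
#' @param pThreshold Uncorrected two-sided significance level. Default 0.001.
#' @return List with `tMap` ([ImageVolume-class]), `significanceMask`
#'   ([BinaryMask-class]), `df`, `nEvaluable`.
#' @export
voxelwiseTTest <- function(imagesA, imagesB, paired = FALSE,
                           pThreshold = 0.001) {
  nA <- length(imagesA); nB <- length(imagesB)
  if (nA < 2L || nB < 2L) stop("need at least 2 images per group")
  if (paired && nA != nB) stop("paired design requires equal group sizes")
  assertSameGrid(c(imagesA, imagesB))
  ref <- imagesA[[1L]]
  d <- dim(ref@data)
  stack <- function(lst) vapply(lst, function(v) as.vector(v@data),
                                numeric(prod(d)))
  A <- stack(imagesA); B <- stack(imagesB)
  ok <- rowSums(is.nan(A)) == 0 & rowSums(is.nan(B)) == 0
  tv <- rep(NaN, prod(d))
  if (paired) {
    D <- B - A
    mD <- rowMeans(D); vD <- apply(D, 1L, stats::var)
    df <- nA - 1L
    good <- ok & vD > 0
    tv[good] <- -mD[good] / sqrt(vD[good] / nA)  # sign: A relative to B
  } else {
    mA <- rowMeans(A); mB <- rowMeans(B)
    vA <- apply(A, 1L, stats::var); vB <- apply(B, 1L, stats::var)
    df <- nA + nB - 2L
    sp2 <- ((nA - 1L) * vA + (nB - 1L) * vB) / df
    good <- ok & sp2 > 0
    tv[good] <- (mA[good] - mB[good]) /
      sqrt(sp2[good] * (1 / nA + 1 / nB))
  }
  pv <- 2 * stats::pt(-abs(tv), df)
  sig <- !is.nan(pv) & pv < pThreshold
  list(tMap = sameGrid(ref, array(tv, dim = d)),
       significanceMask = sameGrid(ref, array(as.numeric(sig), dim = d),
                                   "BinaryMask"),
       df = df, nEvaluable = sum(good))
}

#' Quartile summary of SUVR values in a VOI
#'
#' First quartile, median and third quartile of the non-excluded voxel
#' values inside a VOI, using the linear-interpolation quantile convention
#' (R type 7) so boxplot numbers are reproducible.
#'
#' @param suvr An [SUVRResult-class] or [ImageVolume-class].
#' @param voi [BinaryMask-class].
#' @param voiLabel,group Identifiers carried into the result.
#' @return List (class `voiDistribution`) with `voiLabel`, `group`, `q1`,
#'   `median`, `q3`, `n`.
#' @export
voiDistribution <- function(suvr, voi, voiLabel = NA_integer_,
                            group = NA_character_) {
  vol <- if (is(suvr, "SUVRResult")) suvr@suvr else suvr
  stopifnot(is(voi, "BinaryMask"))
  assertSameGrid(list(vol, voi))
  vals <- vol@data[voi@data == 1 & !is.nan(vol@data)]
  if (!length(vals))
    stop("no non-excluded voxels in the VOI")
  q <- unname(stats::quantile(vals, c(0.25, 0.5, 0.75), type = 7))
  structure(list(voiLabel = as.integer(voiLabel), group = group,
                 q1 = q[1], median = q[2], q3 = q[3], n = length(vals)),
            class = "voiDistribution")
}
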