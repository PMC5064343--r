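# Scaled-down phantom for fast tests: 48^3 grid of 3 mm voxels, geometry
# and PSF reduced proportionally (PSF SD 6 mm) so every tissue class
# survives the resolution-matching blur, as in the full-size default.
smallPhantomSpec <- function(psfSd = 6, noiseSd = 0, seed = 1, ...) {
  PhantomSpec(shape = c(48, 48, 48), spacing = c(3, 3, 3),
              cerebrumCenter = c(0, 4, 8),
              cerebrumCsfSemi = c(34, 38, 30),
              cerebrumGmSemi = c(30, 34, 26),
              cerebrumWmSemi = c(20, 24, 15),
              cerebellumCenter = c(0, -24, -30),
              cerebellumGmSemi = c(17, 14, 12),
              cerebellumWmSemi = c(6, 4, 3),
              psfSd = psfSd, noiseSd = noiseSd, seed = seed, ...)
}

# Wrap a numeric vector as an n x 1 x 1 ImageVolume (for feeding vector
# data through the image-based statistics API).
vecVolume <- function(x) ImageVolume(array(x, dim = c(length(x), 1, 1)))

fullMask <- function(vol) {
  BinaryMask(array(1, dim = dim(imgData(vol))),
             spacing = imgSpacing(vol), affine = imgAffine(vol))
}

# Independent brute-force binary erosion: a voxel survives iff every
# structuring-element neighbour (by explicit index arithmetic, outside the
# grid = background) is inside the mask. Deliberately loop-based and
# separate from the package implementation.
bruteErodeOnce <- function(arr, connectivity = 26) {
  d <- dim(arr)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nz <- rowSums(abs(offs))
  offs <- switch(as.character(connectivity),
                 "6" = offs[nz == 1, , drop = FALSE],
                 "18" = offs[nz >= 1 & nz <= 2, , drop = FALSE],
                 "26" = offs[nz >= 1, , drop = FALSE])
  out <- array(FALSE, dim = d)
  idx <- which(arr == 1, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    ok <- TRUE
    for (k in seq_len(nrow(offs))) {
      p <- idx[r, ] + offs[k, ]
      if (any(p < 1) || any(p > d) || arr[p[1], p[2], p[3]] != 1) {
        ok <- FALSE; break
      }
    }
    out[idx[r, 1], idx[r, 2], idx[r, 3]] <- ok
  }
  out
}

# Closed-form ordinary least squares (with intercept) from raw sums.
olsOracle <- function(x, y) {
  n <- length(x)
  slope <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

# Exact two-sided Mann-Whitney p by full enumeration of all C(n+m, n)
# group assignments (no ties assumed): doubled one-sided tail, capped at 1.
mwEnumOracle <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a); m <- length(b)
  combos <- utils::combn(n + m, n)
  us <- apply(combos, 2, function(ix) {
    r <- rank(pooled)
    sum(r[ix]) - n * (n + 1) / 2
  })
  uObs <- sum(rank(pooled)[seq_len(n)]) - n * (n + 1) / 2
  pl <- mean(us <= uObs); pu <- mean(us >= uObs)
  list(U = uObs, p = min(1, 2 * min(pl, pu)))
}
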