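test_that("voiRegression recovers exact linear relations", {
  set.seed(3)
  x <- runif(200, 0.8, 2.5)
  mask <- fullMask(vecVolume(x))
  r1 <- voiRegression(vecVolume(x), vecVolume(x), mask)
  expect_equal(r1$slope, 1, tolerance = 1e-12)
  expect_equal(r1$intercept, 0, tolerance = 1e-12)
  expect_equal(r1$pearsonR, 1, tolerance = 1e-12)

  r2 <- voiRegression(vecVolume(x), vecVolume(1.2 * x), mask)
  expect_equal(r2$slope, 1.2, tolerance = 1e-12)
  expect_equal(r2$pearsonR, 1, tolerance = 1e-12)

  expect_error(voiRegression(vecVolume(rep(1, 10)), vecVolume(runif(10)),
                             fullMask(vecVolume(rep(1, 10)))), "zero variance")
  # excluded voxels are dropped from the pairs
  xn <- x; xn[1:50] <- NaN
  r3 <- voiRegression(vecVolume(xn), vecVolume(1.2 * x), mask)
  expect_identical(r3$nVoxels, 150L)
})

test_that("noisy regression matches the closed-form OLS oracle", {
  set.seed(101)
  x <- runif(5000, 0.8, 2.5)
  y <- 1.2 * x + rnorm(5000, sd = 0.05)
  r <- voiRegression(vecVolume(x), vecVolume(y), fullMask(vecVolume(x)))
  o <- olsOracle(x, y)
  expect_equal(r$slope, o$slope, tolerance = 1e-10)
  expect_equal(r$intercept, o$intercept, tolerance = 1e-10)
  expect_gt(r$slope, 1.18); expect_lt(r$slope, 1.22)
  expect_gt(r$pearsonR, 0.73)  # far above the reported floor
})

test_that("poolAlpha averages slopes with their spread", {
  reg <- function(s) structure(list(voiLabel = 1L, slope = s, intercept = 0,
                                    pearsonR = 1, nVoxels = 10L),
                               class = "voiRegression")
  expect_identical(poolAlpha(list(reg(1)))$alpha, 1)
  expect_identical(poolAlpha(list(reg(1)))$alphaSd, 0)
  pa <- poolAlpha(list(reg(1.1), reg(1.3)))
  expect_equal(pa$alpha, 1.2, tolerance = 1e-15)
  expect_equal(pa$alphaSd, sd(c(1.1, 1.3)))
  # k copies of one regression pool to that slope
  expect_equal(poolAlpha(rep(list(reg(1.192)), 5))$alpha, 1.192,
               tolerance = 1e-12)
  expect_error(poolAlpha(list()), "at least one")
})

test_that("Mann-Whitney: exact enumeration oracle and tie handling", {
  r <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
  expect_identical(r$U, 0)
  expect_equal(r$p, 0.1, tolerance = 1e-12)
  o <- mwEnumOracle(c(1, 2, 3), c(4, 5, 6))
  expect_identical(o$U, 0)
  expect_equal(r$p, o$p, tolerance = 1e-12)

  # identical multisets: U = n^2/2, p near 1
  a <- c(1.2, 3.4, 5.6, 7.8)
  r2 <- mannWhitneyU(a, a)
  expect_identical(r2$U, length(a)^2 / 2)
  expect_gte(r2$p, 0.99)

  # invariance under a common strictly monotone transform
  set.seed(5)
  x <- rnorm(12); y <- rnorm(15, mean = 0.5)
  r3 <- mannWhitneyU(x, y)
  r4 <- mannWhitneyU(exp(x), exp(y))
  expect_identical(r3$U, r4$U)
  expect_equal(r3$p, r4$p, tolerance = 1e-12)
  expect_error(mannWhitneyU(numeric(0), 1), "nonempty")
})

test_that("normal approximation tracks exact enumeration at n = m = 7", {
  # exhaustive and deterministic: the p-value depends only on U, so every
  # achievable U is compared. The continuity-corrected approximation is
  # within 0.0125 everywhere (its worst deviation, 0.0124, sits at the
  # distribution center, U = 18, exact p 0.456) and within 0.005 in the
  # decision-relevant tail where the exact p is below 0.1.
  datasets <- lapply(0:49, function(u) {
    # tie-free dataset with U(a over b) exactly u = 7k + r: k elements of
    # a above all of b, one element above exactly r of b, the rest below
    b <- (1:7) * 10
    k <- u %/% 7; r <- u %% 7
    a <- numeric(0)
    if (k > 0) a <- c(a, 100 + seq_len(k))
    if (r > 0) a <- c(a, b[r] + 0.5)
    a <- c(a, seq_len(7 - length(a)) * 0.1)
    list(a = a, b = b)
  })
  worstAll <- worstTail <- 0
  for (d in datasets) {
    ex <- mwEnumOracle(d$a, d$b)
    ap <- mannWhitneyU(d$a, d$b, exactMaxN = 0)  # force the approximation
    expect_identical(ap$U, ex$U)
    worstAll <- max(worstAll, abs(ap$p - ex$p))
    if (ex$p <= 0.1) worstTail <- max(worstTail, abs(ap$p - ex$p))
  }
  expect_lte(worstAll, 0.0125)
  expect_lte(worstTail, 0.005)
})

test_that("voxelwise t-test: nulls, swaps and degenerate voxels", {
  set.seed(9)
  d <- c(8, 8, 8)
  mk <- function() ImageVolume(array(rnorm(prod(d)), dim = d))
  a <- replicate(4, mk(), simplify = FALSE)
  b <- replicate(4, mk(), simplify = FALSE)

  same <- voxelwiseTTest(a, a)
  expect_true(all(imgData(same$tMap)[!is.nan(imgData(same$tMap))] == 0))
  expect_identical(sum(imgData(same$significanceMask)), 0)

  # swapping groups negates t, keeps the two-sided mask
  r1 <- voxelwiseTTest(a, b, pThreshold = 0.05)
  r2 <- voxelwiseTTest(b, a, pThreshold = 0.05)
  expect_equal(imgData(r1$tMap), -imgData(r2$tMap), tolerance = 1e-12)
  expect_identical(imgData(r1$significanceMask),
                   imgData(r2$significanceMask))
  expect_identical(r1$df, 6L)

  # cross-check a single voxel against stats::t.test
  va <- sapply(a, function(v) imgData(v)[2, 3, 4])
  vb <- sapply(b, function(v) imgData(v)[2, 3, 4])
  tt <- t.test(va, vb, var.equal = TRUE)
  expect_equal(imgData(r1$tMap)[2, 3, 4], unname(tt$statistic),
               tolerance = 1e-12)

  # constant shift with zero within-group variance: non-evaluable
  c1 <- replicate(3, ImageVolume(array(1, dim = d)), simplify = FALSE)
  c2 <- replicate(3, ImageVolume(array(2, dim = d)), simplify = FALSE)
  rc <- voxelwiseTTest(c1, c2)
  expect_true(all(is.nan(imgData(rc$tMap))))
  expect_identical(sum(imgData(rc$significanceMask)), 0)
  expect_identical(rc$nEvaluable, 0L)

  # NaN-excluded voxels are not evaluated
  an <- a; dat <- imgData(an[[1]]); dat[1, 1, 1] <- NaN
  an[[1]] <- ImageVolume(dat)
  rn <- voxelwiseTTest(an, b)
  expect_true(is.nan(imgData(rn$tMap)[1, 1, 1]))
  expect_error(voxelwiseTTest(a[1], b), "at least 2")
})

test_that("paired t-test matches stats::t.test and requires equal sizes", {
  set.seed(21)
  d <- c(6, 6, 6)
  a <- replicate(5, ImageVolume(array(rnorm(prod(d)), dim = d)), simplify = FALSE)
  b <- lapply(a, function(v)
    ImageVolume(imgData(v) + 0.3 + array(rnorm(prod(d), sd = 0.2), dim = d)))
  r <- voxelwiseTTest(a, b, paired = TRUE, pThreshold = 0.05)
  va <- sapply(a, function(v) imgData(v)[3, 3, 3])
  vb <- sapply(b, function(v) imgData(v)[3, 3, 3])
  tt <- t.test(va, vb, paired = TRUE)
  expect_equal(imgData(r$tMap)[3, 3, 3], unname(tt$statistic),
               tolerance = 1e-12)
  expect_identical(r$df, 4L)
  expect_error(voxelwiseTTest(a, b[1:4], paired = TRUE), "equal group sizes")
})

test_that("voiDistribution uses the linear-interpolation quantile convention", {
  v5 <- vecVolume(c(1, 2, 3, 4, 5))
  d <- voiDistribution(v5, fullMask(v5))
  expect_identical(c(d$q1, d$median, d$q3), c(2, 3, 4))

  const <- vecVolume(rep(3.3, 10))
  dc <- voiDistribution(const, fullMask(const))
  expect_identical(c(dc$q1, dc$median, dc$q3), rep(3.3, 3))

  set.seed(31)
  x <- rnorm(1000)
  dx <- voiDistribution(vecVolume(x), fullMask(vecVolume(x)))
  # sort-based oracle for type-7 quantiles
  xs <- sort(x)
  q7 <- function(p) {
    h <- (length(xs) - 1) * p + 1
    lo <- floor(h)
    xs[lo] + (h - lo) * (xs[lo + 1] - xs[lo])
  }
  expect_equal(dx$q1, q7(0.25), tolerance = 1e-12)
  expect_equal(dx$median, q7(0.5), tolerance = 1e-12)
  expect_equal(dx$q3, q7(0.75), tolerance = 1e-12)
  expect_identical(dx$n, 1000L)
  expect_error(voiDistribution(vecVolume(NaN * 1:3),
                               fullMask(vecVolume(1:3))), "no non-excluded")
})
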