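test_that("erodeToHalf matches the brute-force oracle on a cube", {
  arr <- array(0, dim = c(16, 16, 16))
  arr[4:13, 4:13, 4:13] <- 1  # 10^3 = 1000 voxels
  m <- BinaryMask(arr)
  out <- erodeToHalf(m, connectivity = 26)
  # closed form: (10 - 2k)^3 -> 1000, 512, 216; 512 > 500 so iterate again
  expect_identical(sum(imgData(out)), 216)
  # brute-force oracle: two erosion steps
  e1 <- bruteErodeOnce(arr, 26)
  e2 <- bruteErodeOnce(e1 * 1, 26)
  expect_identical(imgData(out), array(as.numeric(e2), dim = dim(arr)))
})

test_that("erodeToHalf: subset property, half rule and degenerate floor", {
  set.seed(11)
  for (conn in c(6, 18, 26)) {
    for (rep in 1:3) {
      arr <- array(0, dim = c(12, 12, 12))
      blob <- array(runif(12^3) < 0.4, dim = c(12, 12, 12))
      arr[blob] <- 1
      m <- BinaryMask(arr)
      out <- suppressWarnings(erodeToHalf(m, conn))
      o <- imgData(out)
      expect_true(all(o <= arr))             # anti-extensive
      expect_gt(sum(o), 0)                   # never empty
    }
  }
  # solid block halves properly
  arr <- array(0, dim = c(12, 12, 12)); arr[3:10, 3:10, 3:10] <- 1
  out <- erodeToHalf(BinaryMask(arr), 26)
  expect_lte(sum(imgData(out)), ceiling(sum(arr) / 2))
  # single voxel: warning, returns the voxel itself
  single <- array(0, dim = c(5, 5, 5)); single[3, 3, 3] <- 1
  expect_warning(out1 <- erodeToHalf(BinaryMask(single)), "empty")
  expect_identical(imgData(out1), single)
  expect_error(erodeToHalf(BinaryMask(array(0, dim = c(3, 3, 3)))), "empty")
})

test_that("voiMask selects, optionally erodes, and checks label presence", {
  lab <- array(0, dim = c(16, 16, 16))
  lab[3:10, 3:10, 3:10] <- 2                       # one 8^3 block
  lv <- LabelVolume(lab, referenceLabel = 2L)
  expect_identical(sum(imgData(voiMask(lv, 2))), 512)
  expect_lte(sum(imgData(voiMask(lv, 2, erode = TRUE))), 256)
  expect_error(voiMask(lv, 7), "does not occur")

  # two disjoint blocks under one label: the half rule acts on the union
  lab2 <- array(0, dim = c(20, 20, 10))
  lab2[2:7, 2:7, 3:8] <- 3; lab2[12:17, 12:17, 3:8] <- 3
  lv2 <- LabelVolume(lab2, referenceLabel = 3L)
  out <- voiMask(lv2, 3, erode = TRUE)
  n0 <- sum(lab2 == 3)
  expect_lte(sum(imgData(out)), n0 / 2)
  # brute force: each 6^3 block erodes to 4^3, union 128 <= 216
  e1 <- bruteErodeOnce(array(as.numeric(lab2 == 3), dim = dim(lab2)), 26)
  expect_identical(imgData(out), array(as.numeric(e1), dim = dim(lab2)))
})

test_that("computeSuvr self-normalizes on the eroded reference VOI", {
  lab <- array(0, dim = c(12, 12, 12))
  lab[3:8, 3:8, 3:8] <- 1; lab[9:11, 9:11, 9:11] <- 5
  lv <- LabelVolume(lab, referenceLabel = 5L)
  pet <- ImageVolume(array(2, dim = c(12, 12, 12)))
  s <- suppressWarnings(computeSuvr(pet, lv))
  expect_equal(imgData(s@suvr)[1, 1, 1], 1)
  expect_identical(s@referenceValue, 2)

  # 3-voxel reference line {1,2,3}: erosion hits the degenerate floor and
  # keeps all 3, so the reference median is 2 and a voxel of 6 has SUVR 3
  lab3 <- array(0, dim = c(8, 8, 8)); lab3[3:5, 2, 2] <- 7
  lv3 <- LabelVolume(lab3, referenceLabel = 7L)
  vals <- array(6, dim = c(8, 8, 8)); vals[3:5, 2, 2] <- c(1, 2, 3)
  expect_warning(s2 <- computeSuvr(ImageVolume(vals), lv3), "empty")
  expect_identical(s2@referenceValue, 2)
  expect_identical(imgData(s2@suvr)[1, 1, 1], 3)
  expect_identical(s2@erodedRefVoxels, 3L)
})

test_that("SUVR on the phantom: ratio recovery, exact reference median, scale invariance", {
  ph <- smallPhantomSpec()
  maps <- generateTissueMaps(ph)
  pet <- simulatePet(ph, maps$gm, maps$wm, maps$labels)$petObserved
  res <- runPvc(pet, maps$gm, maps$wm, smoothingSdMm = ph@psfSd)
  s <- computeSuvr(res$pvcPet, maps$labels)

  # median over the eroded reference VOI is 1 by construction
  refMask <- erodeToHalf(voiMask(maps$labels, 9))
  sel <- imgData(refMask) == 1 & !is.nan(imgData(s@suvr))
  expect_equal(stats::median(imgData(s@suvr)[sel]), 1, tolerance = 1e-9)

  # cortical SUVR approximates aGm / aRef = 2
  med <- voiDistribution(s, voiMask(maps$labels, 3, erode = TRUE))$median
  expect_lt(abs(med - ph@aGm / ph@aRef) / (ph@aGm / ph@aRef), 0.05)

  # global rescaling of the PVC-PET image leaves the SUVR image unchanged
  scaled <- ImageVolume(2 * imgData(res$pvcPet),
                        spacing = imgSpacing(res$pvcPet),
                        affine = imgAffine(res$pvcPet))
  s2 <- computeSuvr(scaled, maps$labels)
  expect_identical(imgData(s2@suvr), imgData(s@suvr))
  expect_identical(s2@referenceValue, 2 * s@referenceValue)
})

test_that("noiseless closed-form SUVR: cortical value aGm / aRef exactly", {
  # constructed-maps condition: raw soft maps treated as pre-smoothed,
  # smoothing disabled, no noise, no PSF
  ph <- smallPhantomSpec(psfSd = 0, noiseSd = 0)
  maps <- generateTissueMaps(ph)
  pet <- simulatePet(ph, maps$gm, maps$wm, maps$labels)$petObserved
  res <- runPvc(pet, maps$gm, maps$wm, smoothingSdMm = 0)
  s <- computeSuvr(res$pvcPet, maps$labels)
  for (l in c(1, 5, 8)) {
    med <- voiDistribution(s, voiMask(maps$labels, l, erode = TRUE))$median
    expect_equal(med, ph@aGm / ph@aRef, tolerance = 1e-6)
  }
})

test_that("applyAlpha scales non-excluded voxels and composes", {
  ph <- smallPhantomSpec(psfSd = 0, noiseSd = 0)
  maps <- generateTissueMaps(ph)
  pet <- simulatePet(ph, maps$gm, maps$wm, maps$labels)$petObserved
  res <- runPvc(pet, maps$gm, maps$wm, smoothingSdMm = 0)
  s <- computeSuvr(res$pvcPet, maps$labels)

  expect_identical(imgData(applyAlpha(s, 1)@suvr), imgData(s@suvr))
  a <- applyAlpha(s, 1.192)
  i <- which(!is.nan(imgData(s@suvr)))[1]
  expect_equal(imgData(a@suvr)[i], 1.192 * imgData(s@suvr)[i])
  expect_identical(a@alphaApplied, 1.192)

  ab <- applyAlpha(applyAlpha(s, 1.25), 0.5)
  once <- applyAlpha(s, 1.25 * 0.5)
  expect_equal(imgData(ab@suvr), imgData(once@suvr), tolerance = 1e-15)
  expect_equal(ab@alphaApplied, 0.625)
  expect_error(applyAlpha(s, -2), "positive")
  expect_error(applyAlpha(s, 0), "positive")
})
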