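test_that("phantom construction honors tumor count, determinism and
           containment", {
  ph0 <- makePhantom(testPhantomSpec(nTumors = 0, seed = 3))
  expect_false(any(voxelData(ph0) == labelTable(ph0)[["tumor"]]))
  expect_length(tumorMasks(ph0), 0)

  ph2 <- makePhantom(testPhantomSpec(nTumors = 2, seed = 5))
  tms <- tumorMasks(ph2)
  expect_length(tms, 2)
  # tumors lie inside the organ region by construction
  organ <- voxelData(pancreasRegion(ph2))
  for (tm in tms) expect_true(all(organ[tm] == 1))
  # all the advertised structure classes are present
  present <- unique(as.vector(voxelData(ph2)))
  tab <- labelTable(ph2)
  expect_true(all(tab[c("pancreas", "duct", "veins", "arteries",
                        "tumor")] %in% present))

  again <- makePhantom(testPhantomSpec(nTumors = 2, seed = 5))
  expect_identical(voxelData(again), voxelData(ph2))
  other <- makePhantom(testPhantomSpec(nTumors = 2, seed = 6))
  expect_false(identical(voxelData(other), voxelData(ph2)))
})

test_that("impossible phantom geometry is rejected", {
  expect_error(phantomSpec(tumorRadiiMm = 20, pancreasRadiusMm = 10),
               "exceeds pancreas radius")
  expect_error(
    makePhantom(phantomSpec(shape = c(10L, 10L, 10L),
                            spacing = c(1, 1, 1))),
    "fit")
})

test_that("tumor size is the maximum axial diameter in cm", {
  # single voxel: degenerate diameter 0
  m <- array(0L, c(9, 9, 9)); m[5, 5, 5] <- 1L
  expect_equal(tumorSize(ctVolume(m)), 0)

  # axial disc of radius 10 mm at 1 mm spacing: diameter 2 cm
  disc <- array(0L, c(31, 31, 5))
  idx <- which(array(TRUE, dim(disc)), arr.ind = TRUE)
  d2 <- (idx[, 1] - 16)^2 + (idx[, 2] - 16)^2
  disc[idx[d2 <= 10^2 & idx[, 3] == 3, ]] <- 1L
  sz <- tumorSize(ctVolume(disc))
  # brute-force pairwise oracle on the same disc
  pts <- which(disc != 0, arr.ind = TRUE)[, 1:2]
  oracle <- max(dist(pts)) / 10
  expect_equal(sz, oracle)
  expect_equal(sz, 2.0, tolerance = 0.1 / 2)     # within one voxel pitch

  # a sphere measures the same as its equatorial disc
  ball <- makeBall(31, 10)
  expect_equal(tumorSize(ctVolume(ball)), oracle)
  expect_error(tumorSize(ctVolume(array(0L, c(4, 4, 4)))), "empty")
})

test_that("mock detector respects its operating contract", {
  ph <- makePhantom(testPhantomSpec(nTumors = 1, seed = 9))
  tm <- tumorMasks(ph)[[1]]

  zero <- mockDetect(ph, mockDetectorSpec(pDet = 0, fpRate = 0, seed = 1))
  expect_true(all(voxelData(zero) == 0))
  expect_equal(patientLikelihood(zero), 0)

  sure <- mockDetect(ph, mockDetectorSpec(pDet = 1, fpRate = 0, seed = 2))
  cands <- extractCandidates(sure)
  expect_length(cands, 1)
  expect_gte(diceCoefficient(cands[[1]]$voxels, tm), 0.5)

  # determinism under a fixed seed
  sure2 <- mockDetect(ph, mockDetectorSpec(pDet = 1, fpRate = 0, seed = 2))
  expect_identical(voxelData(sure2), voxelData(sure))
})

test_that("empirical detection and false-positive rates match the spec
           within sampling bounds", {
  ph <- makePhantom(testPhantomSpec(nTumors = 1, seed = 13))
  tm <- tumorMasks(ph)[[1]]
  n <- 500
  pDet <- 0.8; lam <- 1.0
  spec <- mockDetectorSpec(pDet = pDet, fpRate = lam,
                           fpOutsideFraction = 0.3)
  streams <- pdacdetect:::patientStreams(99L, n)
  detected <- logical(n); nFp <- integer(n)
  for (i in seq_len(n)) {
    lik <- pdacdetect:::withStream(streams[[i]],
                                   pdacdetect:::.mockDetect(ph, spec))
    cd <- extractCandidates(lik, maxCandidates = 20L)
    hits <- vapply(cd, function(x)
      diceCoefficient(x$voxels, tm) >= 0.1, logical(1))
    detected[i] <- any(hits)
    nFp[i] <- sum(!hits)
  }
  expect_lt(abs(mean(detected) - pDet), 3 * sqrt(pDet * (1 - pDet) / n))
  expect_lt(abs(mean(nFp) - lam), 3 * sqrt(lam / n))
})

test_that("cohorts are reproducible and structured as requested", {
  co <- makeCohort(2, 3, testPhantomSpec(), mockDetectorSpec(), seed = 21)
  expect_length(co, 5)
  expect_equal(vapply(co, `[[`, character(1), "class"),
               rep(c("PDAC", "non-PDAC"), c(2, 3)))
  expect_true(all(vapply(co[1:2], `[[`, numeric(1), "nTumors") >= 1))
  expect_true(all(vapply(co[3:5], `[[`, numeric(1), "nTumors") == 0))
  co2 <- makeCohort(2, 3, testPhantomSpec(), mockDetectorSpec(), seed = 21)
  for (i in seq_along(co)) {
    expect_identical(voxelData(co[[i]]$labels), voxelData(co2[[i]]$labels))
    expect_identical(voxelData(co[[i]]$likelihood),
                     voxelData(co2[[i]]$likelihood))
  }
})

test_that("score-level sampler matches the volumetric patient-score
           distribution", {
  # detection branch: fraction of positives with any signal ~ pDet
  ph <- makePhantom(testPhantomSpec(nTumors = 1, seed = 31))
  spec <- mockDetectorSpec(pDet = 0.7, fpRate = 0)
  n <- 300
  streams <- pdacdetect:::patientStreams(7L, n)
  volFrac <- mean(vapply(seq_len(n), function(i)
    patientLikelihood(pdacdetect:::withStream(
      streams[[i]], pdacdetect:::.mockDetect(ph, spec))) > 0, logical(1)))
  sc <- sampleCohortScores(n, 0, spec, seed = 8)
  smpFrac <- mean(sc$score > 0)
  bound <- 3 * sqrt(0.7 * 0.3 / n)
  expect_lt(abs(volFrac - 0.7), bound)
  expect_lt(abs(smpFrac - 0.7), bound)

  # false-positive branch: P(score > 0) = 1 - exp(-lambda_inside)
  spec2 <- mockDetectorSpec(pDet = 0, fpRate = 1.2, fpOutsideFraction = 0)
  volFrac2 <- mean(vapply(seq_len(n), function(i)
    patientLikelihood(pdacdetect:::withStream(
      streams[[i]], pdacdetect:::.mockDetect(ph, spec2))) > 0, logical(1)))
  sc2 <- sampleCohortScores(0, n, spec2, seed = 9)
  p0 <- 1 - exp(-1.2)
  bound2 <- 3 * sqrt(p0 * (1 - p0) / n)
  expect_lt(abs(volFrac2 - p0), bound2)
  expect_lt(abs(mean(sc2$score > 0) - p0), bound2)
})
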