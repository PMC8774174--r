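likeMap <- function(arr, spacing = c(1, 1, 1))
  asLikelihoodVolume(array(arr, dim(arr)), spacing = spacing)

test_that("pancreas masking zeroes exactly the outside and is monotone", {
  m <- array(0, c(10, 10, 6))
  m[2:3, 2:3, 2:3] <- 0.8          # inside blob
  m[8:9, 8:9, 4:5] <- 0.6          # outside blob
  lik <- likeMap(m)
  panc <- array(0L, dim(m)); panc[1:5, 1:5, ] <- 1L

  expect_identical(voxelData(maskToPancreas(lik, array(1L, dim(m)))),
                   voxelData(lik))
  allZero <- maskToPancreas(lik, array(0L, dim(m)))
  expect_true(all(voxelData(allZero) == 0))
  expect_equal(patientLikelihood(allZero), 0)

  masked <- maskToPancreas(lik, panc)
  before <- extractCandidates(lik)
  after <- extractCandidates(masked)
  expect_length(before, 2)
  expect_length(after, 1)          # the outside blob is removed
  expect_equal(after[[1]]$confidence, 0.8)
  expect_lte(patientLikelihood(masked), patientLikelihood(lik))
  expect_error(maskToPancreas(lik, array(1L, c(4, 4, 4))),
               "different grids")
})

test_that("candidate extraction follows the iterative peak/40%-growth rule", {
  expect_length(extractCandidates(likeMap(array(0, c(5, 5, 5)))), 0)

  # adjacent line (0.9, 0.5, 0.3): threshold 0.36 splits off the 0.3 voxel
  m <- array(0, c(8, 8, 8))
  m[3, 4, 4] <- 0.9; m[4, 4, 4] <- 0.5; m[5, 4, 4] <- 0.3
  cands <- extractCandidates(likeMap(m))
  expect_length(cands, 2)
  expect_equal(cands[[1]]$confidence, 0.9)
  expect_equal(cands[[1]]$nVoxels, 2)
  expect_equal(cands[[2]]$confidence, 0.3)
  expect_equal(cands[[2]]$nVoxels, 1)

  # seven well-separated blobs: the five-lesion cap applies
  m7 <- array(0, c(30, 8, 8))
  for (i in 1:7) m7[4 * i, 4, 4] <- 0.3 + i / 10
  expect_length(extractCandidates(likeMap(m7)), 5)

  expect_error(extractCandidates(likeMap(m7), relThreshold = 1.5),
               "\\(0, 1\\]")
  expect_error(extractCandidates(likeMap(m7), relThreshold = 0),
               "\\(0, 1\\]")
})

test_that("extraction matches the brute-force oracle on random maps", {
  set.seed(123)
  for (rep in 1:30) {
    d <- sample(4:10, 3, replace = TRUE)
    m <- array(0, d)
    k <- sample.int(prod(d), sample(3:12, 1))
    m[k] <- round(runif(length(k)), 2)   # ties likely
    conn <- sample(c(6L, 26L), 1)
    got <- extractCandidates(likeMap(m), connectivity = conn)
    want <- bruteExtractCandidates(m, connectivity = conn)
    expect_equal(length(got), length(want))
    for (i in seq_along(got)) {
      expect_identical(got[[i]]$voxels, as.integer(want[[i]]$indices))
      expect_equal(got[[i]]$confidence, want[[i]]$peak)
    }
  }
})

test_that("candidate invariants hold on randomized maps", {
  set.seed(7)
  for (rep in 1:10) {
    m <- array(0, c(12, 12, 12))
    k <- sample.int(12^3, 40)
    m[k] <- runif(40)
    cands <- extractCandidates(likeMap(m))
    expect_lte(length(cands), 5)
    conf <- vapply(cands, `[[`, numeric(1), "confidence")
    expect_true(all(diff(conf) <= 0))          # non-increasing order
    vox <- unlist(lapply(cands, `[[`, "voxels"))
    expect_equal(anyDuplicated(vox), 0)        # pairwise disjoint
    for (cd in cands) {                        # 3D-connected
      sub <- array(0L, c(12, 12, 12)); sub[cd$voxels] <- 1L
      lab <- pdacdetect:::cpp_label_components(as.integer(sub),
                                               dim(sub), 26L)
      expect_equal(attr(lab, "nComponents"), 1L)
      expect_equal(cd$confidence, max(m[cd$voxels]))  # confidence = peak
    }
    # patient likelihood equals rank-1 confidence when candidates exist
    expect_equal(patientLikelihood(likeMap(m)), conf[1])
  }
})

test_that("ensembling averages voxelwise and validates inputs", {
  m1 <- array(0, c(6, 6, 6)); m1[2, 2, 2] <- 1
  m2 <- array(0, c(6, 6, 6)); m2[5, 5, 5] <- 1
  e1 <- ensembleMaps(list(likeMap(m1)))
  expect_identical(voxelData(e1), m1)
  eTen <- ensembleMaps(rep(list(likeMap(m1)), 10))
  expect_equal(voxelData(eTen), m1)
  e2 <- ensembleMaps(list(likeMap(m1), likeMap(m2)))
  expect_equal(voxelData(e2)[2, 2, 2], 0.5)
  expect_equal(voxelData(e2)[5, 5, 5], 0.5)
  expect_error(ensembleMaps(list()), "at least one")
  expect_error(ensembleMaps(list(likeMap(m1),
                                 likeMap(array(0, c(3, 3, 3))))),
               "different grids")
})

test_that("candidate serialization produces a rank label map and JSON", {
  m <- array(0, c(8, 8, 8)); m[2, 2, 2] <- 0.9; m[6, 6, 6] <- 0.4
  cands <- extractCandidates(likeMap(m))
  labMap <- candidateLabelMap(cands, c(8, 8, 8))
  expect_equal(voxelData(labMap)[2, 2, 2], 1L)
  expect_equal(voxelData(labMap)[6, 6, 6], 2L)
  tmp <- withr::local_tempfile(fileext = ".json")
  writeCandidateJson(cands, c(8, 8, 8), tmp, patientId = "P001",
                     patientScore = 0.9)
  j <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_equal(j$nCandidates, 2)
  expect_equal(j$patientLikelihood, 0.9)
  expect_equal(j$candidates$confidence, c(0.9, 0.4))
})
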