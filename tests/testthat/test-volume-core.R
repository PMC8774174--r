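test_that("NIfTI round trip preserves labels, likelihoods and geometry", {
  tmp <- withr::local_tempdir()
  lab <- asLabelVolume(array(sample(0:2, 8^3, TRUE), c(8, 8, 8)),
                       spacing = c(0.7, 0.7, 3.0), origin = c(-5, 2, 10))
  f <- file.path(tmp, "lab.nii.gz")
  writeVolume(lab, f)
  back <- readVolume(f, type = "label")
  expect_identical(voxelData(back), voxelData(lab))
  expect_equal(voxelSpacing(back), voxelSpacing(lab), tolerance = 1e-5)
  expect_equal(labelTable(back), labelTable(lab))

  lik <- asLikelihoodVolume(array(runif(6^3), c(6, 6, 6)),
                            spacing = c(1, 1, 2))
  g <- file.path(tmp, "lik.nii.gz")
  writeVolume(lik, g)
  back2 <- readVolume(g, type = "likelihood")
  expect_equal(voxelData(back2), voxelData(lik), tolerance = 1e-6)
})

test_that("malformed volumes are rejected", {
  tmp <- withr::local_tempdir()
  f4 <- file.path(tmp, "vol4d.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(4, 4, 4, 2))), f4)
  expect_error(readVolume(f4), "3D")
  expect_error(asLikelihoodVolume(array(1 + 1e-9, c(2, 2, 2))), "\\[0, 1\\]")
  expect_error(asLikelihoodVolume(array(-1e-9, c(2, 2, 2))), "\\[0, 1\\]")
  expect_error(ctVolume(array(0, c(3, 3, 3)), spacing = c(1, 0, 1)),
               "positive")
  expect_error(readVolume(file.path(tmp, "missing.nii")), "not found")
})

test_that("resampling preserves world extent and scales spacing", {
  v <- ctVolume(array(rnorm(512), c(8, 8, 8)), spacing = c(0.5, 0.5, 3))
  expect_identical(voxelData(resampleVolume(v, c(8, 8, 8), "nearest")),
                   voxelData(v))
  down <- resampleVolume(v, c(4, 4, 8), "nearest")
  expect_equal(voxelSpacing(down), c(1, 1, 3))  # in-plane halving doubles it
  # world extent: shape * spacing invariant
  for (shape in list(c(3, 5, 7), c(16, 4, 2), c(5, 5, 5))) {
    r <- resampleVolume(v, shape, "linear")
    expect_equal(dim(r) * voxelSpacing(r), dim(v) * voxelSpacing(v))
  }
})

test_that("nearest resampling of labels emits only input labels", {
  lab <- asLabelVolume(array(sample(c(0L, 2L, 5L), 1000, TRUE),
                             c(10, 10, 10)),
                       labels = c(background = 0L, pancreas = 2L,
                                  veins = 5L))
  up <- resampleVolume(lab, c(17, 13, 9))
  expect_true(all(unique(as.vector(voxelData(up))) %in% c(0L, 2L, 5L)))
  expect_s4_class(up, "LabelVolume")
  expect_error(resampleVolume(lab, c(5, 5, 5), mode = "linear"), "nearest")
})

test_that("down-then-upsampled ball mask keeps high overlap", {
  ball <- makeBall(32, 9)
  v <- ctVolume(ball)
  down <- resampleVolume(v, c(16, 16, 16), "nearest")
  up <- resampleVolume(down, c(32, 32, 32), "nearest")
  expect_gte(diceArrays(voxelData(up), ball), 0.9)
})

test_that("spherical dilation matches its definition", {
  m <- array(0L, c(9, 9, 9)); m[5, 5, 5] <- 1L
  v <- ctVolume(m, spacing = c(1, 1, 1))
  expect_identical(voxelData(sphericalDilate(v, 0)), m)  # radius 0 identity
  # lattice points with Euclidean norm <= 2: 33 of them
  d2 <- sphericalDilate(v, 2)
  expect_equal(sum(voxelData(d2)), 33)
  expect_error(sphericalDilate(v, -1), ">= 0")

  # two voxels 3 mm apart bridged by radius 2 mm
  m2 <- array(0L, c(9, 9, 9)); m2[3, 5, 5] <- 1L; m2[6, 5, 5] <- 1L
  d3 <- sphericalDilate(ctVolume(m2), 2)
  lab <- pdacdetect:::cpp_label_components(as.integer(voxelData(d3) != 0),
                                           dim(voxelData(d3)), 6L)
  expect_equal(attr(lab, "nComponents"), 1L)
})

test_that("dilation agrees with the brute-force distance oracle and is
           monotone and extensive", {
  set.seed(42)
  for (rep in 1:5) {
    sp <- sample(list(c(1, 1, 1), c(1, 1, 2.5), c(0.8, 1.2, 2)), 1)[[1]]
    d <- c(10, 12, 8)
    a <- array(as.integer(runif(prod(d)) < 0.03), d)
    if (!any(a)) a[5, 5, 5] <- 1L
    r <- runif(1, 0.5, 4)
    got <- sphericalDilate(a, r, spacing = sp)
    want <- bruteDilate(a, sp, r)
    expect_identical(got != 0, want)
    expect_true(all(got[a != 0] != 0))            # extensive
    b <- a; b[2, 2, 2] <- 1L                      # superset mask
    gotB <- sphericalDilate(b, r, spacing = sp)
    expect_true(all(gotB[got != 0] != 0))         # monotone
  }
})

test_that("bounding boxes are tight, margined, clamped, and reject empty
           masks", {
  m <- array(0L, c(12, 12, 12)); m[6, 6, 6] <- 1L
  v <- ctVolume(m, spacing = c(1, 1, 1))
  b0 <- boundingBox3D(v, 0)
  expect_equal(b0@lo, rep(6L, 3)); expect_equal(b0@hi, rep(6L, 3))
  b10 <- boundingBox3D(v, 10)   # 10 mm margin clamps to the full volume
  expect_equal(b10@lo, rep(1L, 3)); expect_equal(b10@hi, rep(12L, 3))
  expect_error(boundingBox3D(ctVolume(array(0L, c(4, 4, 4)))), "empty")
  # margin is ceil(mm / spacing) voxels per axis
  v2 <- ctVolume(m, spacing = c(2, 3, 5))
  b <- boundingBox3D(v2, 6)
  expect_equal(b@lo, c(3L, 4L, 4L)); expect_equal(b@hi, c(9L, 8L, 8L))
})

test_that("crop and uncrop round trip and map indices to original space", {
  set.seed(1)
  v <- ctVolume(array(rnorm(16^3), c(16, 16, 16)), spacing = c(1, 2, 3),
                origin = c(5, 5, 5))
  full <- new("BoundingBox3D", lo = c(1L, 1L, 1L), hi = c(16L, 16L, 16L),
              refShape = c(16L, 16L, 16L))
  expect_identical(voxelData(cropVolume(v, full)), voxelData(v))
  box <- new("BoundingBox3D", lo = c(11L, 11L, 11L), hi = c(14L, 14L, 14L),
             refShape = c(16L, 16L, 16L))
  cr <- cropVolume(v, box)
  expect_equal(worldOrigin(cr), c(5, 5, 5) + c(10, 10, 10) * c(1, 2, 3))
  back <- uncropVolume(cr, box)
  expect_identical(voxelData(cropVolume(back, box)), voxelData(cr))
  expect_equal(worldOrigin(back), worldOrigin(v))
  expect_true(all(voxelData(back)[1:10, , ] == 0))
  # ROI voxel (3, 4, 5) with box lo (11, 11, 11) -> original (13, 14, 15)
  expect_equal(mapToOriginal(matrix(c(3L, 4L, 5L), 1), box),
               matrix(c(13L, 14L, 15L), 1))
  lin <- 3L + (4L - 1L) * 4L + (2L - 1L) * 16L
  sub <- arrayInd(mapToOriginal(lin, box, c(4L, 4L, 4L)), c(16L, 16L, 16L))
  expect_equal(as.integer(sub), c(13L, 14L, 12L))
  badBox <- new("BoundingBox3D", lo = c(1L, 1L, 1L), hi = c(4L, 4L, 4L),
                refShape = c(8L, 8L, 8L))
  expect_error(cropVolume(v, badBox), "does not match")
})
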