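#' Specification of a mock tumor detector
#'
#' Describes a stochastic stand-in for a trained voxel-level tumor
#' detection network with controllable operating characteristics. Each
#' true tumor is independently "detected" with probability `pDet`; a
#' detected tumor receives a Gaussian likelihood blob centered on it,
#' with peak value drawn from a Beta distribution and half-maximum
#' surface at the tumor's equivalent-sphere radius (so the extracted
#' candidate overlaps the lesion well). False-positive blobs arrive as a
#' Poisson process per patient, each placed inside the pancreas region
#' with probability `1 - fpOutsideFraction` and otherwise well outside it
#' (so pancreas masking has a measurable, predictable effect); FP blobs
#' have fixed width `fpSigmaMm` and peaks from their own Beta
#' distribution.
#'
#' Defaults make true-positive peaks (Beta(5, 2), mean 0.71)
#' stochastically dominate false-positive peaks (Beta(2, 5), mean 0.29),
#' giving non-degenerate ROC and FROC curves.
#'
#' @param pDet per-lesion detection probability in \[0, 1\].
#' @param tpBeta numeric(2), Beta shape parameters of TP peak likelihoods.
#' @param fpRate Poisson mean of false-positive blobs per patient.
#' @param fpBeta numeric(2), Beta shapes of FP peak likelihoods.
#' @param fpOutsideFraction fraction of FP blobs placed outside the
#'   pancreas region.
#' @param fpSigmaMm Gaussian falloff sigma of FP blobs (mm).
#' @param truncate blobs are cut at this fraction of their peak (support
#'   radius `sigma * sqrt(2 * log(1 / truncate))`). The default 0.45
#'   sits just above the pipeline's 40\% relative extraction threshold,
#'   so every simulated blob is extracted as exactly one candidate
#'   (no low-likelihood halo is left behind to form spurious annular
#'   candidates), which is what makes `pDet` and `fpRate` exactly
#'   recoverable from FROC analysis.
#' @param seed RNG seed used by [mockDetect()].
#' @return an object of class `"mockDetectorSpec"`.
#' @seealso [mockDetect()], [makeCohort()], [sampleCohortScores()]
#' @export
mockDetectorSpec <- function(pDet = 0.8, tpBeta = c(5, 2), fpRate = 1.0,
                             fpBeta = c(2, 5), fpOutsideFraction = 0.3,
                             fpSigmaMm = 3, truncate = 0.45, seed = 1L) {
  stopifnot(pDet >= 0, pDet <= 1, fpRate >= 0,
            fpOutsideFraction >= 0, fpOutsideFraction <= 1,
            fpSigmaMm > 0, truncate > 0, truncate < 1,
            length(tpBeta) == 2L, all(tpBeta > 0),
            length(fpBeta) == 2L, all(fpBeta > 0))
  structure(list(pDet = pDet, tpBeta = tpBeta, fpRate = fpRate,
                 fpBeta = fpBeta, fpOutsideFraction = fpOutsideFraction,
                 fpSigmaMm = fpSigmaMm, truncate = truncate,
                 seed = as.integer(seed)),
            class = "mockDetectorSpec")
}

# add a truncated Gaussian blob (max-combined) into `map`
addBlob <- function(map, coords, spacing, centerWorld, sigmaMm, peak,
                    truncate) {
  rt <- sigmaMm * sqrt(2 * log(1 / truncate))
  d <- dim(map)
  lims <- lapply(1:3, function(a) {
    w <- coords[[a]]
    which(w >= centerWorld[a] - rt & w <= centerWorld[a] + rt)
  })
  if (any(lengths(lims) == 0L)) return(map)
  dx <- coords[[1]][lims[[1]]] - centerWorld[1]
  dy <- coords[[2]][lims[[2]]] - centerWorld[2]
  dz <- coords[[3]][lims[[3]]] - centerWorld[3]
  d2 <- outer(outer(dx^2, dy^2, `+`), dz^2, `+`)
  v <- peak * exp(-d2 / (2 * sigmaMm^2))
  v[v < truncate * peak] <- 0
  cur <- map[lims[[1]], lims[[2]], lims[[3]]]
  map[lims[[1]], lims[[2]], lims[[3]]] <- pmax(cur, v)
  map
}

#' Simulate a detector likelihood map for a phantom
#'
#' Applies the stochastic mock detector described by a
#' [mockDetectorSpec()] to a phantom label map, producing a voxel-level
#' tumor likelihood map in \[0, 1\]. With `pDet = 1` and `fpRate = 0`
#' every tumor receives exactly one blob (DICE with the tumor well above
#' 0.5 at the default extraction threshold) and no other suprathreshold
#' voxels exist; blob centers are kept mutually separated so that each
#' planted blob yields its own candidate at extraction time, which is
#' what makes the generator's `pDet` and `fpRate` recoverable from FROC
#' analysis.
#'
#' @param phantom a [LabelVolume-class] from [makePhantom()].
#' @param spec a [mockDetectorSpec()].
#' @return a [LikelihoodVolume-class] on the phantom grid.
#' @export
mockDetect <- function(phantom, spec) {
  stopifnot(is(phantom, "LabelVolume"), inherits(spec, "mockDetectorSpec"))
  withSeed(spec$seed, .mockDetect(phantom, spec))
}

.mockDetect <- function(phantom, spec) {
  shape <- dim(phantom@values)
  spacing <- phantom@spacing
  coords <- axisCoords(shape, spacing, phantom@origin)
  map <- array(0, shape)
  vox <- prod(spacing)

  organ <- pancreasRegion(phantom)@values != 0
  tumors <- tumorMasks(phantom)

  # blob centers already placed, with their extraction-time radius
  # (voxels above 40% of peak), used to keep candidates resolvable
  placed <- matrix(numeric(0), 0, 4)  # x, y, z, radius40
  r40 <- function(sigma) sigma * sqrt(2 * log(1 / 0.4))

  for (tm in tumors) {
    sub <- arrayInd(tm, shape)
    centerWorld <- sapply(1:3, function(a) mean(coords[[a]][sub[, a]]))
    rEq <- (3 * length(tm) * vox / (4 * pi))^(1 / 3)
    sigma <- rEq / sqrt(2 * log(2))  # half-maximum at the tumor surface
    detected <- stats::runif(1) < spec$pDet
    if (detected) {
      peak <- stats::rbeta(1, spec$tpBeta[1], spec$tpBeta[2])
      map <- addBlob(map, coords, spacing, centerWorld, sigma, peak,
                     spec$truncate)
    }
    # reserve the site either way so FP blobs never sit on a lesion
    placed <- rbind(placed, c(centerWorld, max(r40(sigma), rEq)))
  }

  nFp <- stats::rpois(1, spec$fpRate)
  if (nFp > 0) {
    guard <- spec$fpSigmaMm * sqrt(2 * log(1 / spec$truncate))
    organIdx <- which(organ)
    # FP blobs outside the pancreas go beyond the organ's bounding box
    # expanded by the blob support, so masking removes them entirely
    obox <- boundingBox3D(array(as.integer(organ), shape), marginMm = guard,
                          spacing = spacing)
    outsideOk <- array(TRUE, shape)
    outsideOk[obox@lo[1]:obox@hi[1], obox@lo[2]:obox@hi[2],
              obox@lo[3]:obox@hi[3]] <- FALSE
    outsideIdx <- which(outsideOk)
    for (f in seq_len(nFp)) {
      outside <- stats::runif(1) < spec$fpOutsideFraction
      pool <- if (outside && length(outsideIdx)) outsideIdx else organIdx
      centerWorld <- NULL
      for (try in 1:200) {
        i <- pool[sample.int(length(pool), 1)]
        sub <- arrayInd(i, shape)
        cand <- sapply(1:3, function(a) coords[[a]][sub[, a]])
        sep <- TRUE
        if (nrow(placed)) {
          dd <- sqrt(rowSums(sweep(placed[, 1:3, drop = FALSE], 2, cand)^2))
          sep <- all(dd > placed[, 4] + r40(spec$fpSigmaMm) + 2 * max(spacing))
        }
        if (sep) { centerWorld <- cand; break }
      }
      if (is.null(centerWorld)) next  # no resolvable site left (rare)
      peak <- stats::rbeta(1, spec$fpBeta[1], spec$fpBeta[2])
      map <- addBlob(map, coords, spacing, centerWorld, spec$fpSigmaMm,
                     peak, spec$truncate)
      placed <- rbind(placed, c(centerWorld, r40(spec$fpSigmaMm)))
    }
  }
  asLikelihoodVolume(ctVolume(pmin(map, 1), spacing, phantom@origin))
}

#' Simulate a cohort of phantom patients with mock detections
#'
#' Generates `nPos` patients with at least one tumor and `nNeg`
#' tumor-free patients, each with a ground-truth label map and a mock
#' detector likelihood map. One seeded L'Ecuyer-CMRG stream drives the
#' cohort; each patient gets its own substream (indexed by patient
#' counter), so cohorts are reproducible and patients are independent.
#'
#' @param nPos,nNeg numbers of tumor-bearing / tumor-free patients.
#' @param phantomSpec a [phantomSpec()] (its `nTumors` applies to
#'   positive patients; negatives are generated tumor-free).
#' @param detectorSpec a [mockDetectorSpec()].
#' @param seed cohort seed.
#' @return list of per-patient lists with elements `id`, `class`
#'   ("PDAC"/"non-PDAC"), `labels` ([LabelVolume-class]), `likelihood`
#'   ([LikelihoodVolume-class]), `nTumors`, `tumorSizesCm`.
#' @export
makeCohort <- function(nPos, nNeg, phantomSpec = pdacdetect::phantomSpec(),
                       detectorSpec = mockDetectorSpec(), seed = 1L) {
  stopifnot(nPos >= 0, nNeg >= 0)
  n <- nPos + nNeg
  ids <- sprintf("P%03d", seq_len(n))
  classes <- rep(c("PDAC", "non-PDAC"), c(nPos, nNeg))
  streams <- patientStreams(seed, n)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    spec <- phantomSpec
    if (classes[i] == "non-PDAC") spec$nTumors <- 0L
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", streams[[i]], envir = globalenv())
    labels <- .makePhantom(spec)
    lik <- .mockDetect(labels, detectorSpec)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    tms <- tumorMasks(labels)
    sizes <- vapply(tms, tumorSize, numeric(1), shape = dim(labels@values),
                    spacing = labels@spacing)
    out[[i]] <- list(id = ids[i], class = classes[i], labels = labels,
                     likelihood = lik, nTumors = length(tms),
                     tumorSizesCm = sizes)
  }
  out
}

# per-patient L'Ecuyer-CMRG substreams derived from one cohort seed
patientStreams <- function(seed, n) {
  old <- RNGkind()
  oldSeed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    RNGkind(old[1], old[2], old[3])
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv())
  })
  set.seed(seed, kind = "L'Ecuyer-CMRG")
  s <- get(".Random.seed", globalenv())
  streams <- vector("list", n)
  for (i in seq_len(n)) {
    streams[[i]] <- s
    s <- parallel::nextRNGStream(s)
  }
  streams
}

#' Sample patient-level scores directly from the mock-detector model
#'
#' Draws the patient likelihood (the maximum of the tumor likelihood
#' map) from its analytic distribution under the mock detector: the max
#' over `Bernoulli(pDet) x Beta` true-positive peaks for each tumor and
#' `Poisson(fpRate)` false-positive Beta peaks (thinned to the
#' inside-pancreas fraction when `applyMasking` is `TRUE`), with 0 when
#' no blob is present. This is the marginal the volumetric pipeline
#' produces for the patient score, useful for large replicate studies of
#' score-level statistics (e.g. permutation-test calibration) where the
#' spatial maps themselves are not needed.
#'
#' @inheritParams makeCohort
#' @param nTumors tumors per positive patient.
#' @param applyMasking thin FP peaks to the inside-pancreas fraction, as
#'   pancreas masking does to the spatial maps.
#' @return data.frame with columns `id`, `class`, `score`.
#' @export
sampleCohortScores <- function(nPos, nNeg, detectorSpec = mockDetectorSpec(),
                               nTumors = 1L, applyMasking = TRUE,
                               seed = 1L) {
  withSeed(seed, {
    n <- nPos + nNeg
    lam <- detectorSpec$fpRate *
      (if (applyMasking) 1 - detectorSpec$fpOutsideFraction else 1)
    score <- numeric(n)
    kT <- rep(c(nTumors, 0L), c(nPos, nNeg))
    for (i in seq_len(n)) {
      peaks <- numeric(0)
      if (kT[i] > 0) {
        det <- stats::runif(kT[i]) < detectorSpec$pDet
        if (any(det))
          peaks <- stats::rbeta(sum(det), detectorSpec$tpBeta[1],
                                detectorSpec$tpBeta[2])
      }
      nFp <- stats::rpois(1, lam)
      if (nFp > 0)
        peaks <- c(peaks, stats::rbeta(nFp, detectorSpec$fpBeta[1],
                                       detectorSpec$fpBeta[2]))
      score[i] <- if (length(peaks)) max(peaks) else 0
    }
    data.frame(id = sprintf("P%03d", seq_len(n)),
               class = rep(c("PDAC", "non-PDAC"), c(nPos, nNeg)),
               score = score, stringsAsFactors = FALSE)
  })
}
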