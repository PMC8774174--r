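#' Specification of a synthetic abdominal phantom
#'
#' Describes one synthetic "patient": a 3D label map containing a curved
#' tubular pancreas, an internal pancreatic duct, a short common bile
#' duct, two vessel tubes (veins, arteries), and 0 or more spherical
#' tumors placed on the pancreas centerline. The phantom stands in for an
#' annotated abdominal CE-CT scan; it reproduces the annotation classes
#' and cohort structure of a PDAC study, not CT intensities.
#'
#' Default geometry: a 64 x 64 x 40 grid at 2 x 2 x 2.5 mm spacing
#' (128 x 128 x 100 mm field of view centered on the pancreatic region),
#' pancreas tube radius 14 mm (a ~28 mm-thick organ), and tumor radii
#' drawn uniformly from 8-14 mm (axial diameters 1.6-2.8 cm, the size
#' range typical of resectable PDAC).
#'
#' @param shape integer(3) grid shape (voxels).
#' @param spacing numeric(3) voxel spacing (mm).
#' @param nTumors number of tumors (0 for a non-PDAC patient).
#' @param tumorRadiiMm tumor radii in mm, recycled to `nTumors`; `NULL`
#'   draws them uniformly from `tumorRadiusRange`.
#' @param tumorRadiusRange range to draw radii from when unspecified.
#' @param pancreasRadiusMm pancreas tube radius (mm); tumor radii may not
#'   exceed it (tumors are placed inside the pancreas).
#' @param ductRadiusMm pancreatic duct radius (mm).
#' @param vesselRadiusMm vessel tube radius (mm).
#' @param controlPoints optional n x 3 matrix of world-mm centerline
#'   control points; `NULL` uses a curved default spanning the volume,
#'   jittered per phantom by `jitterSdMm`.
#' @param jitterSdMm per-phantom Gaussian jitter of the default control
#'   points (mm), giving anatomical variation across a cohort.
#' @param seed RNG seed used by [makePhantom()].
#' @return an object of class `"phantomSpec"` (a validated list).
#' @seealso [makePhantom()], [mockDetectorSpec()], [makeCohort()]
#' @export
phantomSpec <- function(shape = c(64L, 64L, 40L), spacing = c(2, 2, 2.5),
                        nTumors = 1L, tumorRadiiMm = NULL,
                        tumorRadiusRange = c(8, 14),
                        pancreasRadiusMm = 14, ductRadiusMm = 1.5,
                        vesselRadiusMm = 4, controlPoints = NULL,
                        jitterSdMm = 2, seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape > 0L),
            length(spacing) == 3L, all(spacing > 0),
            nTumors >= 0, pancreasRadiusMm > 0, ductRadiusMm > 0)
  if (!is.null(tumorRadiiMm)) {
    tumorRadiiMm <- rep_len(tumorRadiiMm, nTumors)
    if (any(tumorRadiiMm > pancreasRadiusMm))
      stop("tumor radius exceeds pancreas radius: tumors must fit inside ",
           "the pancreas")
  } else if (tumorRadiusRange[2] > pancreasRadiusMm + 1e-9) {
    stop("tumorRadiusRange exceeds pancreas radius")
  }
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 nTumors = as.integer(nTumors), tumorRadiiMm = tumorRadiiMm,
                 tumorRadiusRange = tumorRadiusRange,
                 pancreasRadiusMm = pancreasRadiusMm,
                 ductRadiusMm = ductRadiusMm,
                 vesselRadiusMm = vesselRadiusMm,
                 controlPoints = controlPoints, jitterSdMm = jitterSdMm,
                 seed = as.integer(seed)),
            class = "phantomSpec")
}

# evaluate expr under a temporary seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# voxel-center world coordinate vectors for each axis
axisCoords <- function(shape, spacing, origin = c(0, 0, 0)) {
  lapply(1:3, function(a) origin[a] + (seq_len(shape[a]) - 0.5) * spacing[a])
}

# sample a smooth centerline (world mm) through control points at ~1 mm
# arc steps
sampleCenterline <- function(cp, stepMm = 1) {
  seg <- sqrt(rowSums(diff(cp)^2))
  tKnot <- c(0, cumsum(seg))
  n <- max(16L, ceiling(tKnot[length(tKnot)] / stepMm))
  tt <- seq(0, tKnot[length(tKnot)], length.out = n)
  sapply(1:3, function(a)
    stats::spline(tKnot, cp[, a], xout = tt, method = "natural")$y)
}

# paint voxels within radiusMm of a polyline into `arr` (logical)
paintTube <- function(arr, coords, line, radiusMm) {
  d <- dim(arr)
  lims <- lapply(1:3, function(a) {
    r <- range(line[, a]) + c(-1, 1) * (radiusMm + 1)
    which(coords[[a]] >= r[1] & coords[[a]] <= r[2])
  })
  if (any(lengths(lims) == 0L)) return(arr)
  sub <- expand.grid(x = coords[[1]][lims[[1]]], y = coords[[2]][lims[[2]]],
                     z = coords[[3]][lims[[3]]])
  dmin <- rep(Inf, nrow(sub))
  for (k in seq_len(nrow(line))) {
    d2 <- (sub$x - line[k, 1])^2 + (sub$y - line[k, 2])^2 +
          (sub$z - line[k, 3])^2
    dmin <- pmin(dmin, d2)
  }
  inside <- array(FALSE, lengths(lims))
  inside[dmin <= radiusMm^2] <- TRUE
  arr[lims[[1]], lims[[2]], lims[[3]]] <-
    arr[lims[[1]], lims[[2]], lims[[3]]] | inside
  arr
}

paintSphere <- function(arr, coords, center, radiusMm) {
  paintTube(arr, coords, matrix(center, nrow = 1), radiusMm)
}

defaultControlPoints <- function(extent) {
  rel <- rbind(c(0.18, 0.32, 0.56),
               c(0.38, 0.46, 0.53),
               c(0.60, 0.56, 0.50),
               c(0.80, 0.42, 0.46))
  sweep(rel, 2, extent, `*`)
}

#' Generate a synthetic anatomy label map
#'
#' Builds the phantom described by a [phantomSpec()]: pancreas, duct,
#' common bile duct, veins and arteries are painted as tubes; tumors as
#' spheres centered on the pancreas centerline (so each tumor lies fully
#' inside the pancreas region, replacing parenchyma/duct voxels).
#' Identical spec and seed give bit-identical output.
#'
#' @param spec a [phantomSpec()].
#' @return a [LabelVolume-class] using the [pancreasLabels()] encoding;
#'   ground-truth per-tumor masks are recoverable with [tumorMasks()].
#' @examples
#' ph <- makePhantom(phantomSpec(nTumors = 2, seed = 7))
#' length(tumorMasks(ph))
#' @export
makePhantom <- function(spec) {
  stopifnot(inherits(spec, "phantomSpec"))
  withSeed(spec$seed, .makePhantom(spec))
}

# uses the current RNG stream (cohort generation supplies substreams)
.makePhantom <- function(spec) {
  shape <- spec$shape; spacing <- spec$spacing
  extent <- shape * spacing
  coords <- axisCoords(shape, spacing)
  labels <- pancreasLabels()

  cp <- spec$controlPoints
  if (is.null(cp)) {
    cp <- defaultControlPoints(extent)
    cp <- cp + matrix(stats::rnorm(length(cp), 0, spec$jitterSdMm),
                      nrow(cp), 3)
  }
  line <- sampleCenterline(cp)
  rp <- spec$pancreasRadiusMm
  if (any(apply(line, 2, min) - rp < 0) ||
      any(apply(line, 2, max) + rp > extent))
    stop("pancreas geometry does not fit inside the volume")

  lab <- array(0L, shape)
  paint <- function(lab, mask, id) { lab[mask & lab == 0L] <- id; lab }
  empty <- array(FALSE, shape)

  # vessels first (pancreas wins any accidental overlap)
  veinLine <- cbind(seq(0.12, 0.88, length.out = 40) * extent[1],
                    0.72 * extent[2], 0.40 * extent[3])
  artLine <- cbind(seq(0.15, 0.85, length.out = 40) * extent[1],
                   0.14 * extent[2], 0.62 * extent[3])
  lab <- paint(lab, paintTube(empty, coords, veinLine, spec$vesselRadiusMm),
               labels[["veins"]])
  lab <- paint(lab, paintTube(empty, coords, artLine, spec$vesselRadiusMm),
               labels[["arteries"]])
  # common bile duct: short vertical tube meeting the pancreatic head
  cbdLine <- cbind(line[1, 1], line[1, 2],
                   seq(min(line[1, 3] + rp + 2, extent[3] - 2),
                       min(extent[3] - 2, line[1, 3] + rp + 22),
                       length.out = 15))
  lab <- paint(lab, paintTube(empty, coords, cbdLine, 2),
               labels[["common_bile_duct"]])

  pancreasMask <- paintTube(empty, coords, line, rp)
  lab[pancreasMask] <- labels[["pancreas"]]
  ductMask <- paintTube(empty, coords, line, spec$ductRadiusMm)
  lab[ductMask & pancreasMask] <- labels[["duct"]]

  # tumors: spheres on the centerline, pairwise separated so that each
  # remains its own connected component
  nT <- spec$nTumors
  if (nT > 0) {
    radii <- spec$tumorRadiiMm
    if (is.null(radii))
      radii <- stats::runif(nT, spec$tumorRadiusRange[1],
                            spec$tumorRadiusRange[2])
    if (any(radii > rp))
      stop("tumor radius exceeds pancreas radius")
    nLine <- nrow(line)
    centers <- matrix(NA_real_, nT, 3)
    for (t in seq_len(nT)) {
      ok <- FALSE
      for (try in 1:400) {
        k <- sample(seq(ceiling(0.1 * nLine), floor(0.9 * nLine)), 1)
        cand <- line[k, ]
        sep <- TRUE
        if (t > 1) {
          dd <- sqrt(rowSums(sweep(centers[seq_len(t - 1), , drop = FALSE],
                                   2, cand)^2))
          sep <- all(dd > radii[seq_len(t - 1)] + radii[t] +
                       2 * max(spacing))
        }
        if (sep) { centers[t, ] <- cand; ok <- TRUE; break }
      }
      if (!ok) stop("could not place ", nT, " separated tumors on the ",
                    "pancreas centerline; reduce nTumors or radii")
    }
    for (t in seq_len(nT)) {
      sph <- paintSphere(empty, coords, centers[t, ], radii[t])
      lab[sph] <- labels[["tumor"]]
    }
  }

  asLabelVolume(lab, labels = labels, spacing = spacing)
}

#' Ground-truth tumor masks of a label map
#'
#' Returns one binary mask per connected tumor component (26-connectivity)
#' as lists of linear voxel indices, ordered by first occurrence.
#'
#' @param labelVolume a [LabelVolume-class].
#' @return list of integer vectors (linear voxel indices); empty list for
#'   a tumor-free patient.
#' @export
tumorMasks <- function(labelVolume) {
  stopifnot(is(labelVolume, "LabelVolume"))
  id <- labelVolume@labelTable[["tumor"]]
  m <- array(as.integer(labelVolume@values == id), dim(labelVolume@values))
  lab <- cpp_label_components(as.integer(m), dim(m), 26L)
  k <- attr(lab, "nComponents")
  if (k == 0L) return(list())
  lapply(seq_len(k), function(i) which(lab == i))
}

#' Binary organ-region mask (pancreas parenchyma + duct + tumor)
#'
#' The anatomical pancreas region used for likelihood-map masking and for
#' oracle coarse segmentation: parenchyma, pancreatic duct, and tumor
#' voxels (a tumor replaces parenchyma in the label map but is part of
#' the organ).
#'
#' @param labelVolume a [LabelVolume-class].
#' @return a binary [LabelVolume-class] (1 = pancreas region).
#' @export
pancreasRegion <- function(labelVolume) {
  stopifnot(is(labelVolume, "LabelVolume"))
  tab <- labelVolume@labelTable
  ids <- tab[c("pancreas", "duct", "tumor")]
  m <- array(as.integer(labelVolume@values %in% ids),
             dim(labelVolume@values))
  asLabelVolume(ctVolume(m, labelVolume@spacing, labelVolume@origin),
                labels = c(background = 0L, pancreas = 1L))
}

#' Tumor size as maximum axial diameter
#'
#' Measures a tumor mask the way radiologists size PDAC lesions: the
#' maximum, over axial (fixed z) slices, of the largest pairwise in-plane
#' distance between tumor voxel centers. Reported in cm.
#'
#' @param mask binary [CTVolume-class], or linear voxel indices with
#'   `shape` and `spacing` given.
#' @param shape,spacing grid geometry when `mask` is an index vector.
#' @return numeric(1), maximum axial diameter in cm (0 for a single
#'   voxel).
#' @export
tumorSize <- function(mask, shape = NULL, spacing = NULL) {
  if (is(mask, "CTVolume")) {
    idx <- which(mask@values != 0)
    shape <- dim(mask@values)
    spacing <- mask@spacing
  } else {
    idx <- as.integer(mask)
    if (is.null(shape) || is.null(spacing))
      stop("shape and spacing required for index input")
  }
  if (length(idx) == 0L) stop("empty tumor mask")
  sub <- arrayInd(idx, shape)
  xy <- cbind(sub[, 1] * spacing[1], sub[, 2] * spacing[2])
  dmax <- 0
  for (z in unique(sub[, 3])) {
    p <- xy[sub[, 3] == z, , drop = FALSE]
    if (nrow(p) < 2) next
    # convex hull keeps the pairwise search small on large discs
    h <- grDevices::chull(p)
    p <- p[h, , drop = FALSE]
    dmax <- max(dmax, max(stats::dist(p)))
  }
  dmax / 10
}
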