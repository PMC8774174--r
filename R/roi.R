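#' Construct a segmentation adapter
#'
#' Wraps a callable as a [SegmentationAdapter-class]. The callable
#' receives one volume (plus the patient id, for adapters that look up
#' stored outputs) and must return its output on exactly the same grid.
#'
#' @param fun `function(volume, patientId = NULL)`.
#' @param name adapter name recorded in provenance.
#' @param configId configuration identifier.
#' @return a [SegmentationAdapter-class].
#' @export
segmentationAdapter <- function(fun, name = "adapter", configId = "default") {
  new("SegmentationAdapter", fun = fun, name = name, configId = configId)
}

#' Oracle coarse pancreas segmenter
#'
#' An adapter that "segments" the pancreas by resampling a stored
#' ground-truth label map onto whatever grid it is queried on — the
#' idealized stand-in for a low-resolution pancreas segmentation
#' network. `erodeVoxels` optionally erodes the mask first (on its
#' native grid, with a ball of that many voxel pitches) to emulate an
#' imperfect coarse segmentation.
#'
#' @param labelVolume the ground-truth [LabelVolume-class] (full
#'   resolution), or a `function(patientId)` returning one.
#' @param erodeVoxels non-negative integer, erosion in voxel pitches.
#' @return a [SegmentationAdapter-class] returning a binary pancreas
#'   mask on the query grid.
#' @export
oracleCoarseAdapter <- function(labelVolume, erodeVoxels = 0L) {
  getLv <- if (is.function(labelVolume)) labelVolume else function(id) labelVolume
  fun <- function(volume, patientId = NULL) {
    lv <- getLv(patientId)
    organ <- pancreasRegion(lv)
    if (erodeVoxels > 0) {
      r <- erodeVoxels * max(organ@spacing)
      if (r >= max(dim(organ@values) * organ@spacing)) {
        organ@values[] <- 0L        # erosion wipes out the whole grid
      } else {
        inv <- array(as.integer(organ@values == 0), dim(organ@values))
        grown <- dilateBinary(inv != 0, organ@spacing, r)
        organ@values <- array(as.integer(organ@values != 0 & !grown),
                              dim(organ@values))
      }
    }
    resampleVolume(organ, dim(volume@values), mode = "nearest")
  }
  segmentationAdapter(fun, name = "oracle-coarse",
                      configId = sprintf("erode%d", erodeVoxels))
}

#' Mock tumor-detector adapter
#'
#' Wraps [mockDetect()] as a detection adapter: applied to a (cropped)
#' phantom label map it returns the mock likelihood map, and — like a
#' network trained to segment tumor plus pancreas — the binary pancreas
#' region, enabling pancreas masking downstream. Randomness follows the
#' ambient RNG stream, so cohort drivers control per-patient substreams.
#'
#' @param spec a [mockDetectorSpec()].
#' @param withPancreas also return the pancreas segmentation (set
#'   `FALSE` to emulate a tumor-only model, disabling masking).
#' @return a [SegmentationAdapter-class].
#' @export
mockDetectorAdapter <- function(spec, withPancreas = TRUE) {
  fun <- function(volume, patientId = NULL) {
    stopifnot(is(volume, "LabelVolume"))
    lik <- .mockDetect(volume, spec)
    if (!withPancreas) return(lik)
    list(likelihood = lik, pancreas = pancreasRegion(volume))
  }
  segmentationAdapter(fun, name = if (withPancreas) "mock-TP" else "mock-T",
                      configId = sprintf("pDet%.2f_fp%.2f", spec$pDet,
                                         spec$fpRate))
}

#' Precomputed-output adapter
#'
#' Reads per-patient likelihood maps written by an external model
#' (`<dir>/<patientId>_likelihood.nii.gz`), cropping them to the query
#' grid via world coordinates when the query is a region of interest.
#'
#' @param dir directory of per-patient NIfTI likelihood maps.
#' @return a [SegmentationAdapter-class].
#' @export
precomputedAdapter <- function(dir) {
  fun <- function(volume, patientId = NULL) {
    if (is.null(patientId)) stop("precomputed adapter needs a patient id")
    path <- file.path(dir, paste0(patientId, "_likelihood.nii.gz"))
    full <- readVolume(path, type = "likelihood")
    if (identical(dim(full@values), dim(volume@values))) return(full)
    lo <- round((volume@origin - full@origin) / full@spacing) + 1L
    hi <- lo + dim(volume@values) - 1L
    box <- new("BoundingBox3D", lo = as.integer(lo), hi = as.integer(hi),
               refShape = as.integer(dim(full@values)))
    cropVolume(full, box)
  }
  segmentationAdapter(fun, name = "precomputed", configId = dir)
}

applyAdapter <- function(adapter, volume, patientId = NULL) {
  out <- adapter@fun(volume, patientId)
  check <- function(v)
    if (!identical(dim(if (is(v, "CTVolume")) v@values else v),
                   dim(volume@values)))
      stop("adapter '", adapter@name, "' returned output on a different grid")
  if (is.list(out) && !is(out, "CTVolume")) lapply(out, check) else check(out)
  out
}

#' Pancreas-not-found condition
#'
#' Raised when the coarse segmenter returns an empty mask; cohort
#' drivers catch it, log the patient, and continue.
#' @param patientId offending patient.
#' @keywords internal
pancreasNotFound <- function(patientId = NULL) {
  stop(structure(class = c("pancreasNotFound", "error", "condition"),
                 list(message = paste0("pancreas not found",
                        if (!is.null(patientId)) paste0(" for patient ",
                                                        patientId)),
                      call = sys.call(-1))))
}

#' Automatic pancreas region-of-interest extraction
#'
#' The inference-time ROI chain: the scan is downsampled to
#' `coarseShape` (by default half resolution in-plane, mirroring a
#' 512 x 512 to 256 x 256 coarse grid, with the z axis kept); the coarse
#' segmenter produces a low-resolution pancreas mask (probabilities are
#' binarized at 0.5); the mask is upsampled back to the original grid
#' (nearest neighbor), dilated with a spherical kernel of
#' `dilationMm` to close gaps, and expanded by a fixed `marginMm`; the
#' resulting bounding box is cropped out of the scan.
#'
#' The dilation radius (default 5 mm) and margin (default 10 mm) are
#' package defaults — chosen so that an imperfect coarse mask still
#' yields an ROI containing the whole organ — and are configurable.
#'
#' @param scan the full [CTVolume-class] (any subclass).
#' @param coarseSegmenter a [SegmentationAdapter-class] returning a
#'   pancreas mask on the coarse grid.
#' @param coarseShape integer(3) coarse grid shape; default halves the
#'   in-plane axes.
#' @param dilationMm spherical dilation radius (mm).
#' @param marginMm fixed ROI margin (mm).
#' @param patientId passed to the adapter / error messages.
#' @return a [RoiResult-class].
#' @export
extractROI <- function(scan, coarseSegmenter,
                       coarseShape = NULL, dilationMm = 5, marginMm = 10,
                       patientId = NULL) {
  stopifnot(is(scan, "CTVolume"), is(coarseSegmenter, "SegmentationAdapter"))
  d <- dim(scan@values)
  if (is.null(coarseShape))
    coarseShape <- c(pmax(d[1:2] %/% 2L, 1L), d[3])
  low <- resampleVolume(scan, coarseShape, mode = "nearest")
  coarse <- applyAdapter(coarseSegmenter, low, patientId)
  if (is.list(coarse) && !is(coarse, "CTVolume")) coarse <- coarse$pancreas
  carr <- if (is(coarse, "CTVolume")) coarse@values else coarse
  if (!is.integer(carr)) carr <- (carr >= 0.5) * 1L
  if (!any(carr != 0)) pancreasNotFound(patientId)
  coarseVol <- ctVolume(array(as.integer(carr != 0), coarseShape),
                        spacing = low@spacing, origin = low@origin)
  up <- resampleVolume(coarseVol, d, mode = "nearest")
  dil <- sphericalDilate(up, dilationMm)
  box <- boundingBox3D(dil, marginMm = marginMm)
  new("RoiResult", box = box, cropped = cropVolume(scan, box),
      coarseMask = dil@values,
      params = list(coarseShape = coarseShape, dilationMm = dilationMm,
                    marginMm = marginMm))
}

#' Run the detection pipeline on one patient
#'
#' Full inference chain for a single scan: extract the pancreas ROI,
#' apply the tumor detector to the cropped ROI only, and place its
#' outputs back into original-image space (zero outside the ROI) for
#' downstream scoring and evaluation.
#'
#' @inheritParams extractROI
#' @param detector a [SegmentationAdapter-class] returning a likelihood
#'   map (optionally a list with a pancreas segmentation).
#' @param applyMasking mask the likelihood map to the detector's
#'   pancreas segmentation when one is returned.
#' @return list with `likelihood` ([LikelihoodVolume-class], original
#'   space), `pancreas` (binary [LabelVolume-class] in original space or
#'   `NULL`), `roi` ([RoiResult-class]), `patientLikelihood`.
#' @export
runPatient <- function(scan, coarseSegmenter, detector,
                       coarseShape = NULL, dilationMm = 5, marginMm = 10,
                       applyMasking = TRUE, patientId = NULL) {
  roi <- extractROI(scan, coarseSegmenter, coarseShape, dilationMm,
                    marginMm, patientId)
  out <- applyAdapter(detector, roi@cropped, patientId)
  pancreas <- NULL
  if (is.list(out) && !is(out, "CTVolume")) {
    lik <- out$likelihood
    pancreas <- out$pancreas
  } else lik <- out
  lik <- asLikelihoodVolume(lik)
  if (!is.null(pancreas) && applyMasking)
    lik <- maskToPancreas(lik, pancreas)
  likFull <- uncropVolume(lik, roi@box)
  pancreasFull <- if (!is.null(pancreas)) {
    pv <- if (is(pancreas, "CTVolume")) pancreas else
      ctVolume(pancreas, lik@spacing, lik@origin)
    uncropVolume(pv, roi@box)
  }
  list(likelihood = asLikelihoodVolume(likFull), pancreas = pancreasFull,
       roi = roi, patientLikelihood = patientLikelihood(likFull))
}
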