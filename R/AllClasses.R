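#' @import methods
#' @importFrom Rcpp sourceCpp
#' @importFrom parallel nextRNGStream
#' @importFrom stats setNames
#' @useDynLib pdacdetect, .registration = TRUE
NULL

#' 3D scalar volume with voxel geometry
#'
#' `CTVolume` is the carrier for every 3D grid in the package: CT
#' intensities, anatomical label maps and voxel-level tumor likelihood
#' maps. Values are stored as a plain 3D array indexed `[x, y, z]` (the
#' native NIfTI/R layout); `spacing` gives the physical voxel pitch in mm
#' per axis and `origin` the world coordinate (mm) of the corner of the
#' first voxel. Only axis-aligned geometry is supported: world position of
#' the center of voxel `(i, j, k)` is `origin + (c(i, j, k) - 0.5) * spacing`.
#'
#' @slot values 3D numeric/integer array of voxel values.
#' @slot spacing numeric(3), strictly positive, mm per voxel.
#' @slot origin numeric(3), world offset in mm.
#'
#' @seealso [LabelVolume-class], [LikelihoodVolume-class], [readVolume()]
#' @export
setClass("CTVolume",
  representation(values = "array", spacing = "numeric", origin = "numeric"),
  prototype(values = array(0, c(1, 1, 1)), spacing = c(1, 1, 1),
            origin = c(0, 0, 0)))

setValidity("CTVolume", function(object) {
  d <- dim(object@values)
  if (length(d) != 3L)
    return("values must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("spacing must be 3 strictly positive finite reals (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("origin must be 3 finite reals (mm)")
  TRUE
})

#' Integer anatomical label map
#'
#' A [CTVolume-class] whose voxels carry non-negative integer anatomical
#' class ids. Every id occurring in the volume must be present in the
#' label table (id -> structure name). The default encoding is
#' [pancreasLabels()]: background 0, tumor 1, pancreas parenchyma 2,
#' pancreatic duct 3, common bile duct 4, veins 5, arteries 6, cyst 7,
#' thrombosis 8.
#'
#' @slot labelTable named integer vector mapping structure name -> label id.
#' @export
setClass("LabelVolume", contains = "CTVolume",
  representation(labelTable = "integer"),
  prototype(labelTable = c(background = 0L)))

setValidity("LabelVolume", function(object) {
  v <- object@values
  if (any(v < 0) || any(v != round(v)))
    return("label values must be non-negative integers")
  if (is.null(names(object@labelTable)))
    return("labelTable must be a named integer vector (name -> id)")
  present <- unique(as.integer(v))
  unknown <- setdiff(present, object@labelTable)
  if (length(unknown))
    return(sprintf("voxel labels not in labelTable: %s",
                   paste(unknown, collapse = ", ")))
  TRUE
})

#' Voxel-level tumor likelihood map
#'
#' A [CTVolume-class] whose values are per-voxel detection confidences and
#' must lie in [0, 1] exactly (no tolerance).
#'
#' @export
setClass("LikelihoodVolume", contains = "CTVolume")

setValidity("LikelihoodVolume", function(object) {
  v <- object@values
  if (anyNA(v)) return("likelihood values must not contain NA")
  if (min(v) < 0 || max(v) > 1)
    return("likelihood values must lie in [0, 1]")
  TRUE
})

#' Axis-aligned 3D bounding box
#'
#' Per-axis index interval in 1-based inclusive voxel coordinates
#' (`lo[a] <= i <= hi[a]`), together with the shape of the reference grid
#' the box indexes into. Used to crop a region of interest out of a full
#' scan and to map candidate coordinates back into original-image space:
#' an index `i` inside the crop corresponds to `i + lo - 1` in the
#' reference grid.
#'
#' @slot lo integer(3) lower corner (inclusive).
#' @slot hi integer(3) upper corner (inclusive).
#' @slot refShape integer(3) shape of the reference volume.
#' @export
setClass("BoundingBox3D",
  representation(lo = "integer", hi = "integer", refShape = "integer"))

setValidity("BoundingBox3D", function(object) {
  if (length(object@lo) != 3L || length(object@hi) != 3L ||
      length(object@refShape) != 3L)
    return("lo, hi, refShape must each have length 3")
  if (any(object@lo < 1L) || any(object@hi < object@lo) ||
      any(object@hi > object@refShape))
    return("box must satisfy 1 <= lo <= hi <= refShape on every axis")
  TRUE
})

#' Segmentation / detection adapter
#'
#' Contract standing in for a trained segmentation network at inference
#' time. An adapter is a stateless callable applied to one volume; it must
#' return output on exactly the grid it was given. Coarse pancreas
#' segmenters return a binary mask (or probabilities, binarized at 0.5 by
#' the pipeline); tumor detectors return a [LikelihoodVolume-class], or a
#' list with elements `likelihood` and optionally `pancreas` for models
#' that also segment the organ.
#'
#' @slot fun the callable, `function(volume, patientId = NULL)`.
#' @slot name human-readable model name.
#' @slot configId configuration identifier recorded in provenance.
#' @seealso [oracleCoarseAdapter()], [mockDetectorAdapter()],
#'   [precomputedAdapter()]
#' @export
setClass("SegmentationAdapter",
  representation(fun = "function", name = "character", configId = "character"),
  prototype(name = "adapter", configId = "default"))

#' Region-of-interest extraction result
#'
#' @slot box [BoundingBox3D-class] in original-image space.
#' @slot cropped the cropped [CTVolume-class].
#' @slot coarseMask the upsampled + dilated binary pancreas mask
#'   (full-resolution grid) the box was derived from.
#' @slot params list: `coarseShape`, `dilationMm`, `marginMm`.
#' @export
setClass("RoiResult",
  representation(box = "BoundingBox3D", cropped = "CTVolume",
                 coarseMask = "array", params = "list"))

#' Operating-characteristic curve (ROC or FROC)
#'
#' Ordered operating points swept over score thresholds. For `kind =
#' "ROC"`, `x` is the patient-level false-positive rate and `y` the
#' sensitivity; `auc` holds the trapezoidal area. For `kind = "FROC"`,
#' `x` is the mean number of false-positive candidates per patient and
#' `y` the lesion-level sensitivity; `pauc` holds the partial area over
#' `paucInterval` (mean FP/patient axis, linear scale).
#'
#' @slot x,y,threshold numeric vectors of equal length, ordered by
#'   decreasing threshold (x, y non-decreasing).
#' @slot kind "ROC" or "FROC".
#' @slot auc numeric(1), NA for FROC curves.
#' @slot pauc numeric(1), NA for ROC curves.
#' @slot paucInterval numeric(2) FP/patient integration interval.
#' @export
setClass("EvalCurve",
  representation(x = "numeric", y = "numeric", threshold = "numeric",
                 kind = "character", auc = "numeric", pauc = "numeric",
                 paucInterval = "numeric"),
  prototype(kind = "ROC", auc = NA_real_, pauc = NA_real_,
            paucInterval = c(NA_real_, NA_real_)))

setValidity("EvalCurve", function(object) {
  n <- length(object@x)
  if (length(object@y) != n || length(object@threshold) != n)
    return("x, y, threshold must have equal length")
  if (!object@kind %in% c("ROC", "FROC"))
    return("kind must be 'ROC' or 'FROC'")
  if (is.unsorted(object@x) || is.unsorted(object@y))
    return("x and y must be non-decreasing along the sweep")
  TRUE
})
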