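#' @rdname CTVolume-accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @rdname CTVolume-accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname CTVolume-accessors
#' @export
setGeneric("worldOrigin", function(x) standardGeneric("worldOrigin"))

#' @rdname LabelVolume-accessors
#' @export
setGeneric("labelTable", function(x) standardGeneric("labelTable"))

#' @rdname resampleVolume
#' @export
setGeneric("resampleVolume",
  function(x, targetShape, mode = c("nearest", "linear"))
    standardGeneric("resampleVolume"))

#' Accessors for volume geometry
#'
#' `voxelData` returns the raw 3D array, `voxelSpacing` the mm voxel
#' pitch, `worldOrigin` the world offset of the grid, and `dim` the voxel
#' shape.
#'
#' @param x a [CTVolume-class] (or subclass).
#' @return `voxelData`: a 3D array; `voxelSpacing`, `worldOrigin`:
#'   numeric(3).
#' @name CTVolume-accessors
#' @aliases voxelData,CTVolume-method voxelSpacing,CTVolume-method
#'   worldOrigin,CTVolume-method
NULL

setMethod("voxelData", "CTVolume", function(x) x@values)
setMethod("voxelSpacing", "CTVolume", function(x) x@spacing)
setMethod("worldOrigin", "CTVolume", function(x) x@origin)

#' @export
setMethod("dim", "CTVolume", function(x) dim(x@values))

#' Accessor for the label table of a [LabelVolume-class]
#'
#' @param x a [LabelVolume-class].
#' @return named integer vector, structure name -> label id.
#' @name LabelVolume-accessors
#' @aliases labelTable,LabelVolume-method
NULL

setMethod("labelTable", "LabelVolume", function(x) x@labelTable)

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("%s %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              class(object), d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  value range [%.4g, %.4g]\n",
              min(object@values), max(object@values)))
  invisible(object)
})

setMethod("show", "LabelVolume", function(object) {
  callNextMethod()
  present <- sort(unique(as.integer(object@values)))
  nm <- names(object@labelTable)[match(present, object@labelTable)]
  cat("  labels present:", paste(sprintf("%s=%d", nm, present),
                                 collapse = ", "), "\n")
  invisible(object)
})

setMethod("show", "BoundingBox3D", function(object) {
  cat(sprintf("BoundingBox3D [%d..%d, %d..%d, %d..%d] in %d x %d x %d grid\n",
              object@lo[1], object@hi[1], object@lo[2], object@hi[2],
              object@lo[3], object@hi[3],
              object@refShape[1], object@refShape[2], object@refShape[3]))
  invisible(object)
})

setMethod("show", "EvalCurve", function(object) {
  cat(sprintf("EvalCurve (%s), %d operating points\n", object@kind,
              length(object@x)))
  if (object@kind == "ROC" && !is.na(object@auc))
    cat(sprintf("  AUC-ROC = %.4f\n", object@auc))
  if (object@kind == "FROC" && !is.na(object@pauc))
    cat(sprintf("  pAUC-FROC = %.4f over [%g, %g] FP/patient\n",
                object@pauc, object@paucInterval[1], object@paucInterval[2]))
  invisible(object)
})

setMethod("show", "SegmentationAdapter", function(object) {
  cat(sprintf("SegmentationAdapter '%s' (config %s)\n", object@name,
              object@configId))
  invisible(object)
})

setMethod("show", "RoiResult", function(object) {
  d <- dim(object@cropped@values)
  cat(sprintf("RoiResult: ROI %d x %d x %d voxels (dilation %g mm, margin %g mm)\n",
              d[1], d[2], d[3], object@params$dilationMm,
              object@params$marginMm))
  show(object@box)
  invisible(object)
})
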