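#' Construct volumes
#'
#' `ctVolume` wraps a 3D array with voxel geometry. `asLabelVolume` and
#' `asLikelihoodVolume` convert (and validate) a volume into the typed
#' subclasses used throughout the pipeline.
#'
#' @param values 3D array of voxel values.
#' @param spacing numeric(3), mm per voxel.
#' @param origin numeric(3), world offset in mm.
#' @return a [CTVolume-class].
#' @examples
#' v <- ctVolume(array(0, c(4, 4, 4)), spacing = c(1, 1, 2))
#' dim(v)
#' @export
ctVolume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (is.logical(values)) storage.mode(values) <- "integer"
  new("CTVolume", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' @rdname ctVolume
#' @param x a [CTVolume-class] or 3D array.
#' @param labels named integer vector mapping structure name -> label id;
#'   defaults to [pancreasLabels()].
#' @export
asLabelVolume <- function(x, labels = pancreasLabels(),
                          spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is(x, "CTVolume")) x <- ctVolume(x, spacing, origin)
  vals <- x@values
  storage.mode(vals) <- "integer"
  new("LabelVolume", values = vals, spacing = x@spacing, origin = x@origin,
      labelTable = as.integer(labels) |> stats::setNames(names(labels)))
}

#' @rdname ctVolume
#' @export
asLikelihoodVolume <- function(x, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is(x, "CTVolume")) x <- ctVolume(x, spacing, origin)
  vals <- x@values
  storage.mode(vals) <- "double"
  new("LikelihoodVolume", values = vals, spacing = x@spacing,
      origin = x@origin)
}

#' Anatomical label encoding
#'
#' The package's fixed label-id table for abdominal anatomy around the
#' pancreas: the tumor, the pancreas parenchyma, and the surrounding
#' structures relevant for pancreatic-cancer reading (pancreatic duct,
#' common bile duct, veins, arteries, cysts, venous thrombosis).
#'
#' @return named integer vector, structure name -> label id.
#' @examples
#' pancreasLabels()
#' @export
pancreasLabels <- function() {
  c(background = 0L, tumor = 1L, pancreas = 2L, duct = 3L,
    common_bile_duct = 4L, veins = 5L, arteries = 6L, cyst = 7L,
    thrombosis = 8L)
}

#' Read and write NIfTI volumes
#'
#' Volumes are exchanged as NIfTI-1 files (`.nii` / `.nii.gz`); geometry
#' (spacing, origin) is taken from the NIfTI header. Only 3D,
#' axis-aligned images are accepted. `type = "label"` returns a
#' [LabelVolume-class] (the label table is read from a `<file>.labels.json`
#' sidecar when present, else defaults to [pancreasLabels()]);
#' `type = "likelihood"` validates the [0, 1] range and returns a
#' [LikelihoodVolume-class].
#'
#' Round trips preserve integer label values exactly and float maps to
#' better than 1e-6; spacing is preserved to 1e-5 mm.
#'
#' @param path file path to a `.nii` or `.nii.gz` file.
#' @param type one of "intensity", "label", "likelihood".
#' @return a [CTVolume-class] subclass according to `type`.
#' @export
readVolume <- function(path, type = c("intensity", "label", "likelihood")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D NIfTI image, got ", length(d), " dimensions: ", path)
  pd <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(pd)) || any(pd <= 0))
    stop("non-positive voxel spacing in NIfTI header: ", path)
  xf <- try(RNifti::xform(img), silent = TRUE)
  origin <- c(0, 0, 0)
  if (!inherits(xf, "try-error") && is.matrix(xf)) {
    rot <- abs(xf[1:3, 1:3])
    offdiag <- rot - diag(diag(rot))
    if (max(offdiag) > 1e-4 * max(rot))
      stop("oblique / rotated NIfTI orientation is not supported: ", path)
    origin <- as.numeric(xf[1:3, 4])
  }
  vals <- array(as.vector(img), dim = d)
  vol <- ctVolume(vals, spacing = as.numeric(pd), origin = origin)
  switch(type,
    intensity = vol,
    label = {
      labels <- pancreasLabels()
      sidecar <- paste0(sub("\\.nii(\\.gz)?$", "", path), ".labels.json")
      if (file.exists(sidecar)) {
        tab <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
        labels <- stats::setNames(as.integer(tab), names(tab))
      }
      asLabelVolume(vol, labels = labels)
    },
    likelihood = asLikelihoodVolume(vol))
}

#' @rdname readVolume
#' @param volume the [CTVolume-class] to write.
#' @param writeSidecar for [LabelVolume-class] inputs, also write the
#'   label table as a `<file>.labels.json` sidecar.
#' @export
writeVolume <- function(volume, path, writeSidecar = TRUE) {
  stopifnot(is(volume, "CTVolume"))
  validObject(volume)
  vals <- volume@values
  datatype <- if (is.integer(vals)) "int32" else "double"
  attr(vals, "pixdim") <- volume@spacing
  img <- RNifti::asNifti(vals, datatype = datatype)
  # axis-aligned qform carrying spacing + origin
  xf <- diag(c(volume@spacing, 1))
  xf[1:3, 4] <- volume@origin
  img <- RNifti::`qform<-`(img, structure(xf, code = 2L))
  RNifti::writeNifti(img, path)
  if (is(volume, "LabelVolume") && writeSidecar) {
    sidecar <- paste0(sub("\\.nii(\\.gz)?$", "", path), ".labels.json")
    jsonlite::write_json(as.list(volume@labelTable), sidecar,
                         auto_unbox = TRUE)
  }
  invisible(path)
}
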