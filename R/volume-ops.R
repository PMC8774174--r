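#' Resample a volume to a new grid shape
#'
#' Resamples onto `targetShape` voxels while preserving the physical
#' extent of the image: the output spacing is
#' `spacing * dim(x) / targetShape` per axis and the origin is unchanged,
#' so downsampling a 512 x 512 in-plane scan to 256 x 256 doubles the
#' in-plane spacing. `mode = "nearest"` picks the value of the nearest
#' input voxel center (mandatory for label maps, and guaranteed to emit
#' only labels present in the input); `mode = "linear"` performs
#' trilinear interpolation.
#'
#' @param x a [CTVolume-class] (or subclass).
#' @param targetShape integer(3), positive.
#' @param mode "nearest" or "linear"; label volumes accept only "nearest".
#' @return a volume of the same class on the new grid.
#' @examples
#' v <- ctVolume(array(rnorm(8^3), c(8, 8, 8)))
#' dim(resampleVolume(v, c(4, 4, 8)))
#' @rdname resampleVolume
#' @aliases resampleVolume,CTVolume-method resampleVolume,LabelVolume-method
#'   resampleVolume,LikelihoodVolume-method
setMethod("resampleVolume", "CTVolume",
  function(x, targetShape, mode = c("nearest", "linear")) {
    mode <- match.arg(mode)
    targetShape <- as.integer(targetShape)
    if (length(targetShape) != 3L || any(targetShape < 1L))
      stop("targetShape must be 3 positive integers")
    out <- resampleArray(x@values, targetShape, mode)
    newSpacing <- x@spacing * dim(x@values) / targetShape
    ctVolume(out, spacing = newSpacing, origin = x@origin)
  })

#' @rdname resampleVolume
setMethod("resampleVolume", "LabelVolume",
  function(x, targetShape, mode = c("nearest", "linear")) {
    mode <- match.arg(mode)
    if (mode != "nearest")
      stop("label maps must be resampled with mode = 'nearest'")
    v <- callNextMethod(x, targetShape, mode = "nearest")
    asLabelVolume(v, labels = x@labelTable)
  })

#' @rdname resampleVolume
setMethod("resampleVolume", "LikelihoodVolume",
  function(x, targetShape, mode = c("nearest", "linear")) {
    v <- callNextMethod(x, targetShape, mode = match.arg(mode))
    # trilinear interpolation of values in [0,1] stays in [0,1]; guard
    # against floating round-off only
    v@values <- pmin(pmax(v@values, 0), 1)
    asLikelihoodVolume(v)
  })

# map output voxel centers to continuous input indices (same world frame)
resampleArray <- function(arr, targetShape, mode) {
  d <- dim(arr)
  cont <- lapply(1:3, function(a)
    (seq_len(targetShape[a]) - 0.5) * d[a] / targetShape[a] + 0.5)
  if (mode == "nearest") {
    idx <- lapply(1:3, function(a) pmin(pmax(round(cont[[a]]), 1L), d[a]))
    return(arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE])
  }
  lo <- lapply(1:3, function(a) pmin(pmax(floor(cont[[a]]), 1L), d[a]))
  hi <- lapply(1:3, function(a) pmin(lo[[a]] + 1L, d[a]))
  fr <- lapply(1:3, function(a)
    pmin(pmax(cont[[a]] - lo[[a]], 0), 1))
  out <- array(0, targetShape)
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    ix <- if (cx) hi[[1]] else lo[[1]]
    iy <- if (cy) hi[[2]] else lo[[2]]
    iz <- if (cz) hi[[3]] else lo[[3]]
    wx <- if (cx) fr[[1]] else 1 - fr[[1]]
    wy <- if (cy) fr[[2]] else 1 - fr[[2]]
    wz <- if (cz) fr[[3]] else 1 - fr[[3]]
    w <- outer(outer(wx, wy), wz)
    out <- out + w * arr[ix, iy, iz, drop = FALSE]
  }
  out
}

#' Spherical (metric) binary dilation
#'
#' Dilates a binary mask with a spherical structuring element defined in
#' millimetres: a voxel belongs to the output iff its center lies within
#' `radiusMm` (Euclidean, world coordinates) of the center of some
#' foreground voxel. Because the ball is built in mm, anisotropic voxel
#' spacing is respected. Used to close gaps in the upsampled coarse
#' pancreas mask before extracting the region of interest.
#'
#' @param mask a binary [CTVolume-class]/[LabelVolume-class], or a
#'   logical/0-1 array (then `spacing` must be given).
#' @param radiusMm dilation radius in mm, `>= 0` (0 is the identity).
#' @param spacing voxel spacing, ignored when `mask` is a volume.
#' @return same type as the input, binary.
#' @export
sphericalDilate <- function(mask, radiusMm, spacing = NULL) {
  if (radiusMm < 0) stop("radiusMm must be >= 0")
  isVol <- is(mask, "CTVolume")
  arr <- if (isVol) mask@values else mask
  sp <- if (isVol) mask@spacing else spacing
  if (is.null(sp)) stop("spacing required for plain-array input")
  fg <- arr != 0
  if (!all(arr %in% c(0, 1))) stop("mask must be binary (0/1)")
  out <- dilateBinary(fg, sp, radiusMm)
  res <- array(as.integer(out), dim(arr))
  if (!isVol) return(res)
  v <- ctVolume(res, spacing = mask@spacing, origin = mask@origin)
  if (is(mask, "LabelVolume")) v <- asLabelVolume(v, labels = mask@labelTable)
  v
}

# union of mask shifted by every lattice offset inside the mm ball
dilateBinary <- function(fg, spacing, radiusMm) {
  if (radiusMm == 0 || !any(fg)) return(fg)
  d <- dim(fg)
  off <- ballOffsets(spacing, radiusMm, maxOffset = d - 1L)
  out <- fg
  for (k in seq_len(nrow(off))) {
    o <- off[k, ]
    if (all(o == 0) || any(abs(o) >= d)) next
    sx <- max(1, 1 + o[1]):min(d[1], d[1] + o[1])
    sy <- max(1, 1 + o[2]):min(d[2], d[2] + o[2])
    sz <- max(1, 1 + o[3]):min(d[3], d[3] + o[3])
    out[sx, sy, sz] <- out[sx, sy, sz] | fg[sx - o[1], sy - o[2], sz - o[3]]
  }
  out
}

ballOffsets <- function(spacing, radiusMm, maxOffset = NULL) {
  r <- sapply(spacing, function(s) floor(radiusMm / s))
  # shifts beyond the grid size saturate; never enumerate past them
  if (!is.null(maxOffset)) r <- pmin(r, maxOffset)
  g <- expand.grid(x = -r[1]:r[1], y = -r[2]:r[2], z = -r[3]:r[3])
  d2 <- (g$x * spacing[1])^2 + (g$y * spacing[2])^2 + (g$z * spacing[3])^2
  as.matrix(g[d2 <= radiusMm^2 + 1e-9, , drop = FALSE])
}

#' Bounding box of a binary mask with a metric margin
#'
#' Returns the tightest axis-aligned box containing every foreground
#' voxel, expanded by `ceiling(marginMm / spacing)` voxels per axis and
#' clamped to the volume. An empty mask is an error: downstream the
#' pipeline must surface "pancreas not found" rather than silently fall
#' back to the full volume.
#'
#' @param mask binary [CTVolume-class] or array (then `spacing` needed).
#' @param marginMm margin in mm, `>= 0`.
#' @inheritParams sphericalDilate
#' @return a [BoundingBox3D-class].
#' @export
boundingBox3D <- function(mask, marginMm = 0, spacing = NULL) {
  if (marginMm < 0) stop("marginMm must be >= 0")
  isVol <- is(mask, "CTVolume")
  arr <- if (isVol) mask@values else mask
  sp <- if (isVol) mask@spacing else spacing
  if (is.null(sp)) stop("spacing required for plain-array input")
  idx <- which(arr != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    stop("empty mask: no foreground voxels (pancreas not found?)")
  d <- dim(arr)
  pad <- ceiling(marginMm / sp)
  lo <- pmax(apply(idx, 2, min) - pad, 1)
  hi <- pmin(apply(idx, 2, max) + pad, d)
  new("BoundingBox3D", lo = as.integer(lo), hi = as.integer(hi),
      refShape = as.integer(d))
}

#' Crop and un-crop a volume with a bounding box
#'
#' `cropVolume` extracts the box from a volume, keeping spacing and
#' shifting the world origin so world coordinates are preserved.
#' `uncropVolume` places a cropped volume back into a zero-filled
#' reference grid, so that voxel `(i, j, k)` of the crop lands at
#' `(i, j, k) + lo - 1` in original-image space; `cropVolume(uncropVolume(x))`
#' is the identity.
#'
#' @param volume a [CTVolume-class] subclass.
#' @param box a [BoundingBox3D-class] valid for the volume's grid.
#' @return a volume of the same class.
#' @export
cropVolume <- function(volume, box) {
  stopifnot(is(volume, "CTVolume"), is(box, "BoundingBox3D"))
  if (!identical(as.integer(dim(volume@values)), box@refShape))
    stop("bounding box reference shape does not match the volume")
  vals <- volume@values[box@lo[1]:box@hi[1], box@lo[2]:box@hi[2],
                        box@lo[3]:box@hi[3], drop = FALSE]
  out <- volume
  out@values <- vals
  out@origin <- volume@origin + (box@lo - 1) * volume@spacing
  out
}

#' @rdname cropVolume
#' @param cropped volume previously cropped with `box`.
#' @export
uncropVolume <- function(cropped, box) {
  stopifnot(is(cropped, "CTVolume"), is(box, "BoundingBox3D"))
  if (!identical(as.integer(dim(cropped@values)), as.integer(box@hi - box@lo + 1L)))
    stop("cropped volume shape does not match the bounding box")
  full <- array(if (is.integer(cropped@values)) 0L else 0, box@refShape)
  full[box@lo[1]:box@hi[1], box@lo[2]:box@hi[2], box@lo[3]:box@hi[3]] <-
    cropped@values
  out <- cropped
  out@values <- full
  out@origin <- cropped@origin - (box@lo - 1) * cropped@spacing
  out
}

#' Map crop-space indices to original-image space
#'
#' Candidate lesions are extracted inside the cropped region of interest;
#' this helper translates their voxel indices back to the full scan.
#'
#' @param idx integer matrix (n x 3) or vector of linear indices into the
#'   cropped grid (then `croppedShape` is required).
#' @param box the [BoundingBox3D-class] used to crop.
#' @param croppedShape shape of the cropped grid, for linear input.
#' @return same form as the input, in original-image coordinates.
#' @export
mapToOriginal <- function(idx, box, croppedShape = NULL) {
  stopifnot(is(box, "BoundingBox3D"))
  if (is.matrix(idx)) {
    return(sweep(idx, 2, box@lo - 1L, `+`))
  }
  if (is.null(croppedShape)) stop("croppedShape required for linear indices")
  sub <- arrayInd(idx, croppedShape)
  sub <- sweep(sub, 2, box@lo - 1L, `+`)
  as.integer(sub[, 1] + (sub[, 2] - 1L) * box@refShape[1] +
             (sub[, 3] - 1L) * box@refShape[1] * box@refShape[2])
}
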