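#' Mask a likelihood map to the pancreas region
#'
#' Post-processing step that suppresses detector output outside the
#' pancreas: voxels where the pancreas mask is 0 are set to likelihood 0,
#' so only PDAC predictions inside the organ are kept. Both inputs must
#' share one grid. Masking can only remove candidates and can only lower
#' the patient likelihood.
#'
#' @param map a [LikelihoodVolume-class].
#' @param pancreas binary pancreas mask ([CTVolume-class]/[LabelVolume-class]
#'   or 0/1 array) on the same grid.
#' @return the masked [LikelihoodVolume-class].
#' @export
maskToPancreas <- function(map, pancreas) {
  stopifnot(is(map, "LikelihoodVolume"))
  parr <- if (is(pancreas, "CTVolume")) pancreas@values else pancreas
  if (!identical(dim(map@values), dim(parr)))
    stop("likelihood map and pancreas mask are on different grids")
  out <- map
  out@values <- map@values * (parr != 0)
  out
}

#' Iterative candidate-lesion extraction
#'
#' Extracts candidate lesions from a voxel likelihood map the way a
#' CAD pipeline reports findings: repeatedly select the voxel with the
#' globally maximum predicted likelihood (the peak), grow the candidate
#' as the 3D-connected set of voxels (26-neighborhood by default) whose
#' likelihood is at least `relThreshold` times the peak (threshold ties
#' included), remove the candidate from the prediction by zeroing its
#' voxels, and repeat until no peak of at least `minPeak` remains or
#' `maxCandidates` lesions have been extracted. Peak ties are broken
#' deterministically toward the lowest linear (x, y, z) index.
#'
#' Each candidate carries its confidence — the maximum likelihood inside
#' it, which by construction is its seed peak — so candidates are
#' returned in non-increasing confidence order.
#'
#' @param map a [LikelihoodVolume-class].
#' @param relThreshold relative growth threshold in (0, 1\]; default 0.4
#'   (voxels with at least 40\% of the peak likelihood).
#' @param maxCandidates maximum number of lesions to extract (default 5).
#' @param minPeak smallest peak worth extracting; a (near-)zero peak
#'   terminates extraction.
#' @param connectivity 26 (default) or 6.
#' @return list of candidates, each a list with `rank`, `confidence`
#'   (= peak), `voxels` (sorted linear indices), `nVoxels`, `volumeMm3`.
#' @examples
#' m <- array(0, c(8, 8, 8)); m[2:3, 2, 2] <- c(0.9, 0.5); m[6, 6, 6] <- 0.3
#' cands <- extractCandidates(asLikelihoodVolume(m))
#' sapply(cands, `[[`, "confidence")
#' @export
extractCandidates <- function(map, relThreshold = 0.4, maxCandidates = 5L,
                              minPeak = 1e-6, connectivity = 26L) {
  stopifnot(is(map, "LikelihoodVolume"))
  if (relThreshold <= 0 || relThreshold > 1)
    stop("relThreshold must lie in (0, 1]")
  if (minPeak <= 0) stop("minPeak must be > 0")
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  raw <- cpp_extract_candidates(as.double(map@values), dim(map@values),
                                relThreshold, as.integer(maxCandidates),
                                minPeak, as.integer(connectivity))
  voxMm3 <- prod(map@spacing)
  lapply(seq_along(raw), function(i) {
    list(rank = i, confidence = raw[[i]]$peak, voxels = raw[[i]]$indices,
         nVoxels = length(raw[[i]]$indices),
         volumeMm3 = length(raw[[i]]$indices) * voxMm3)
  })
}

#' Patient-level tumor likelihood
#'
#' The framework's final patient score: the maximum value of the
#' (post-processed) tumor likelihood map; 0 for an all-zero map. Equal to
#' the confidence of the rank-1 candidate whenever any candidate exists.
#'
#' @param map a [LikelihoodVolume-class].
#' @return numeric(1) in \[0, 1\].
#' @export
patientLikelihood <- function(map) {
  stopifnot(is(map, "LikelihoodVolume"))
  max(map@values)
}

#' Ensemble likelihood maps by voxelwise mean
#'
#' Combines the predictions of several models into one map by arithmetic
#' voxelwise averaging, the standard way an nnU-Net-style ensemble of
#' independently trained models is merged at inference time.
#'
#' @param maps list of [LikelihoodVolume-class] on one grid.
#' @return the mean [LikelihoodVolume-class].
#' @export
ensembleMaps <- function(maps) {
  if (!length(maps)) stop("need at least one likelihood map")
  stopifnot(all(vapply(maps, is, logical(1), "LikelihoodVolume")))
  d <- dim(maps[[1]]@values)
  for (m in maps[-1])
    if (!identical(dim(m@values), d))
      stop("ensemble maps are on different grids")
  acc <- Reduce(`+`, lapply(maps, slot, "values")) / length(maps)
  out <- maps[[1]]
  out@values <- acc
  out
}

#' Candidate-label map
#'
#' Renders a candidate list as an integer label map where each voxel
#' carries the extraction rank of its candidate (0 elsewhere), for
#' serialization alongside the per-patient candidate JSON.
#'
#' @param candidates output of [extractCandidates()].
#' @param shape,spacing,origin grid geometry of the source map.
#' @return a [LabelVolume-class].
#' @export
candidateLabelMap <- function(candidates, shape, spacing = c(1, 1, 1),
                              origin = c(0, 0, 0)) {
  lab <- array(0L, shape)
  for (cd in candidates) lab[cd$voxels] <- as.integer(cd$rank)
  ids <- c(background = 0L)
  if (length(candidates))
    ids <- c(ids, stats::setNames(seq_along(candidates),
                                  paste0("candidate_", seq_along(candidates))))
  asLabelVolume(ctVolume(lab, spacing, origin), labels = ids)
}

#' Serialize candidates to JSON
#'
#' Writes rank, confidence, voxel count, volume and bounding box of each
#' candidate (original-image index space) plus the patient likelihood.
#'
#' @param candidates output of [extractCandidates()].
#' @param shape grid shape the voxel indices refer to.
#' @param path output JSON path.
#' @param patientId,patientScore provenance fields.
#' @export
writeCandidateJson <- function(candidates, shape, path, patientId = NA,
                               patientScore = NA) {
  entries <- lapply(candidates, function(cd) {
    sub <- arrayInd(cd$voxels, shape)
    list(rank = cd$rank, confidence = cd$confidence, nVoxels = cd$nVoxels,
         volumeMm3 = cd$volumeMm3,
         bbox = list(lo = apply(sub, 2, min), hi = apply(sub, 2, max)))
  })
  jsonlite::write_json(
    list(patientId = patientId, patientLikelihood = patientScore,
         nCandidates = length(candidates), candidates = entries),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
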