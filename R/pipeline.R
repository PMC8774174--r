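#' Generate a cohort of phantom patients (ground truth only)
#'
#' Like [makeCohort()] but without mock detections: use it to drive the
#' full inference pipeline ([runCohortPipeline()]), which applies a
#' detector through the ROI-extraction chain instead. Per-patient RNG
#' substreams make the cohort reproducible and order-independent.
#'
#' @inheritParams makeCohort
#' @return list of per-patient lists: `id`, `class`, `labels`,
#'   `nTumors`, `tumorSizesCm`, `gtMasks` (list of lesion voxel-index
#'   vectors in original-image space).
#' @export
makePhantomCohort <- function(nPos, nNeg,
                              phantomSpec = pdacdetect::phantomSpec(),
                              seed = 1L) {
  stopifnot(nPos >= 0, nNeg >= 0)
  n <- nPos + nNeg
  ids <- sprintf("P%03d", seq_len(n))
  classes <- rep(c("PDAC", "non-PDAC"), c(nPos, nNeg))
  streams <- patientStreams(seed, n)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    spec <- phantomSpec
    if (classes[i] == "non-PDAC") spec$nTumors <- 0L
    labels <- withStream(streams[[i]], .makePhantom(spec))
    gt <- tumorMasks(labels)
    sizes <- vapply(gt, tumorSize, numeric(1), shape = dim(labels@values),
                    spacing = labels@spacing)
    out[[i]] <- list(id = ids[i], class = classes[i], labels = labels,
                     nTumors = length(gt), tumorSizesCm = sizes,
                     gtMasks = gt)
  }
  out
}

withStream <- function(stream, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", stream, envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  expr
}

#' Run the full detection pipeline over a phantom cohort
#'
#' For every patient: extract the pancreas ROI with an oracle coarse
#' segmenter built from the patient's own ground truth (optionally
#' eroded, emulating an imperfect low-resolution network), run the mock
#' detector on the cropped ROI, optionally mask the likelihood map to
#' the detector's pancreas segmentation, score the patient, and extract
#' and match candidate lesions. Patients whose coarse mask comes back
#' empty are skipped and recorded, never aborting the cohort run.
#'
#' @param phantoms output of [makePhantomCohort()].
#' @param detectorSpec a [mockDetectorSpec()].
#' @param withPancreas detector also returns a pancreas segmentation
#'   (enables masking, like a tumor+pancreas model); `FALSE` emulates a
#'   tumor-only model.
#' @param applyMasking mask likelihoods to the pancreas segmentation.
#' @param erodeVoxels erosion applied to the oracle coarse mask.
#' @inheritParams extractROI
#' @inheritParams extractCandidates
#' @inheritParams matchCandidates
#' @param seed seed for the per-patient detector substreams.
#' @param detectorAdapter optional [SegmentationAdapter-class] replacing
#'   the mock detector (e.g. [precomputedAdapter()] for stored outputs
#'   of an external model).
#' @param outDir when given, writes `<id>_likelihood.nii.gz` and
#'   `<id>_candidates.json` per patient.
#' @return list with `perPatient` (id, class, score, match, nLesions,
#'   lesionSizesCm), `scores` (data.frame id, class, score), `skipped`
#'   (patient ids), `params`.
#' @export
runCohortPipeline <- function(phantoms, detectorSpec = mockDetectorSpec(),
                              withPancreas = TRUE,
                              applyMasking = withPancreas,
                              erodeVoxels = 0L, coarseShape = NULL,
                              dilationMm = 5, marginMm = 10,
                              relThreshold = 0.4, maxCandidates = 5L,
                              minPeak = 1e-6, connectivity = 26L,
                              diceMin = 0.1, seed = 1L,
                              detectorAdapter = NULL, outDir = NULL) {
  detector <- if (is.null(detectorAdapter))
    mockDetectorAdapter(detectorSpec, withPancreas = withPancreas)
  else detectorAdapter
  streams <- patientStreams(seed, length(phantoms))
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  perPatient <- list()
  skipped <- character(0)
  for (i in seq_along(phantoms)) {
    ph <- phantoms[[i]]
    coarse <- oracleCoarseAdapter(ph$labels, erodeVoxels = erodeVoxels)
    res <- withStream(streams[[i]], tryCatch(
      runPatient(ph$labels, coarse, detector, coarseShape = coarseShape,
                 dilationMm = dilationMm, marginMm = marginMm,
                 applyMasking = applyMasking, patientId = ph$id),
      pancreasNotFound = function(e) NULL))
    if (is.null(res)) {
      skipped <- c(skipped, ph$id)
      next
    }
    # candidates are extracted inside the ROI (identical result: outside
    # is zero) and mapped back to original-image space
    roiLik <- cropVolume(res$likelihood, res$roi@box)
    cands <- extractCandidates(roiLik, relThreshold = relThreshold,
                               maxCandidates = maxCandidates,
                               minPeak = minPeak,
                               connectivity = connectivity)
    shape <- dim(ph$labels@values)
    cands <- lapply(cands, function(cd) {
      cd$voxels <- sort(mapToOriginal(cd$voxels, res$roi@box,
                                      dim(roiLik@values)))
      cd
    })
    m <- matchCandidates(cands, ph$gtMasks, diceMin = diceMin)
    if (!is.null(outDir)) {
      writeVolume(res$likelihood,
                  file.path(outDir, paste0(ph$id, "_likelihood.nii.gz")))
      writeCandidateJson(cands, shape,
                         file.path(outDir, paste0(ph$id, "_candidates.json")),
                         patientId = ph$id,
                         patientScore = res$patientLikelihood)
    }
    perPatient[[length(perPatient) + 1L]] <-
      list(id = ph$id, class = ph$class, score = res$patientLikelihood,
           match = m, nLesions = length(ph$gtMasks),
           lesionSizesCm = ph$tumorSizesCm)
  }
  scores <- data.frame(
    id = vapply(perPatient, `[[`, character(1), "id"),
    class = vapply(perPatient, `[[`, character(1), "class"),
    score = vapply(perPatient, `[[`, numeric(1), "score"),
    stringsAsFactors = FALSE)
  list(perPatient = perPatient, scores = scores, skipped = skipped,
       params = list(withPancreas = withPancreas,
                     applyMasking = applyMasking,
                     dilationMm = dilationMm, marginMm = marginMm,
                     relThreshold = relThreshold,
                     maxCandidates = maxCandidates,
                     connectivity = connectivity, diceMin = diceMin,
                     detector = detector@name, seed = seed))
}

#' Evaluate a cohort detection run
#'
#' Computes the patient-level ROC curve with its AUC and the
#' lesion-level FROC curve with its partial AUC over `[fpLo, fpHi]`
#' false positives per patient. With `maxSizeCm` set, evaluation is
#' restricted to the subgroup of lesions up to that axial diameter:
#' larger lesions leave the FROC denominator (candidates matched to them
#' are ignored rather than counted as false positives), and positive
#' patients without any retained lesion leave the ROC analysis.
#'
#' @param run output of [runCohortPipeline()], or any list with
#'   compatible `perPatient` / `scores` elements.
#' @param fpLo,fpHi pAUC-FROC integration interval (FP/patient).
#' @param maxSizeCm optional lesion-size cutoff in cm (e.g. 2 for the
#'   small-lesion subgroup).
#' @param outDir when given, writes `metrics.json`, `roc.csv`,
#'   `froc.csv`.
#' @return list with `roc`, `froc` ([EvalCurve-class]), `aucRoc`,
#'   `paucFroc`, `metrics`.
#' @export
evaluateCohortRun <- function(run, fpLo = 0.001, fpHi = 5,
                              maxSizeCm = NULL, outDir = NULL) {
  pp <- run$perPatient
  if (!is.null(maxSizeCm)) pp <- restrictLesionSize(pp, maxSizeCm)
  scores <- data.frame(
    id = vapply(pp, `[[`, character(1), "id"),
    class = vapply(pp, `[[`, character(1), "class"),
    score = vapply(pp, `[[`, numeric(1), "score"),
    nLesions = vapply(pp, `[[`, numeric(1), "nLesions"),
    stringsAsFactors = FALSE)
  keepRoc <- scores$class == "non-PDAC" | scores$nLesions > 0
  pos <- scores$score[keepRoc & scores$class == "PDAC"]
  neg <- scores$score[keepRoc & scores$class == "non-PDAC"]
  roc <- rocCurve(pos, neg)
  froc <- frocCurve(pp)
  pa <- paucFroc(froc, fpLo, fpHi)
  froc@pauc <- pa
  froc@paucInterval <- c(fpLo, fpHi)
  metrics <- list(auc_roc = roc@auc, pauc_froc = pa,
                  fp_interval = c(fpLo, fpHi),
                  n_patients = nrow(scores), n_pos = length(pos),
                  n_neg = length(neg),
                  n_lesions = sum(scores$nLesions),
                  n_skipped = length(run$skipped))
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    jsonlite::write_json(metrics, file.path(outDir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(curveToDataFrame(roc), file.path(outDir, "roc.csv"),
                     row.names = FALSE)
    utils::write.csv(curveToDataFrame(froc), file.path(outDir, "froc.csv"),
                     row.names = FALSE)
  }
  list(roc = roc, froc = froc, aucRoc = roc@auc, paucFroc = pa,
       metrics = metrics, perPatient = pp)
}

# drop GT lesions larger than the cutoff: they leave the sensitivity
# denominator and their matched candidates are ignored (not FPs)
restrictLesionSize <- function(perPatient, maxSizeCm) {
  lapply(perPatient, function(p) {
    if (!p$nLesions) return(p)
    keep <- which(p$lesionSizesCm <= maxSizeCm)
    cd <- p$match$candidates
    if (nrow(cd)) {
      drop <- !is.na(cd$lesion) & !(cd$lesion %in% keep)
      cd <- cd[!drop, , drop = FALSE]
      cd$isTP <- cd$isTP & cd$lesion %in% keep
    }
    p$match$candidates <- cd
    p$match$lesions <- p$match$lesions[keep, , drop = FALSE]
    p$nLesions <- length(keep)
    p$lesionSizesCm <- p$lesionSizesCm[keep]
    p
  })
}

#' @rdname evaluateCohortRun
#' @param curve an [EvalCurve-class].
#' @export
curveToDataFrame <- function(curve) {
  data.frame(threshold = curve@threshold, x = curve@x, y = curve@y)
}

#' Compare two detection runs with paired permutation tests
#'
#' Runs the paired patient-level permutation test for the difference in
#' AUC-ROC and in pAUC-FROC between two runs evaluated on the same
#' cohort, at confidence level `1 - alpha` with Bonferroni correction
#' over `nComparisons` pairwise model comparisons.
#'
#' @param runA,runB outputs of [runCohortPipeline()] on one cohort.
#' @inheritParams permutationTest
#' @param outFile optional CSV path for the comparison table.
#' @return data.frame with one row per statistic: observed difference,
#'   p-value, Bonferroni-adjusted alpha, significance flag.
#' @export
compareRuns <- function(runA, runB, iterations = 100000L, fpLo = 0.001,
                        fpHi = 5, alpha = 0.025, nComparisons = 1L,
                        seed = 1L, outFile = NULL) {
  tAuc <- permutationTest(runA$scores, runB$scores, statistic = "auc",
                          iterations = iterations, alpha = alpha,
                          nComparisons = nComparisons, seed = seed)
  tPauc <- permutationTest(runA$perPatient, runB$perPatient,
                           statistic = "pauc_froc",
                           iterations = iterations, fpLo = fpLo,
                           fpHi = fpHi, alpha = alpha,
                           nComparisons = nComparisons, seed = seed + 1L)
  out <- data.frame(
    statistic = c("auc_roc", "pauc_froc"),
    observed_difference = c(tAuc$observed, tPauc$observed),
    p_value = c(tAuc$p, tPauc$p),
    iterations = iterations,
    alpha_adjusted = c(tAuc$alpha, tPauc$alpha),
    significant = c(tAuc$significant, tPauc$significant))
  if (!is.null(outFile)) utils::write.csv(out, outFile, row.names = FALSE)
  out
}

#' Write a simulated cohort to disk
#'
#' Emits per-patient NIfTI pairs (`<id>_gt.nii.gz` ground-truth label
#' map with its label-table sidecar, `<id>_likelihood.nii.gz` mock
#' detector output) plus a cohort manifest CSV (patient id, class,
#' number of tumors, tumor sizes in cm).
#'
#' @inheritParams makeCohort
#' @param dir output directory (created if needed).
#' @return the manifest data.frame, invisibly.
#' @export
simulateCohortFiles <- function(dir, nPos, nNeg,
                                phantomSpec = pdacdetect::phantomSpec(),
                                detectorSpec = mockDetectorSpec(),
                                seed = 1L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cohort <- makeCohort(nPos, nNeg, phantomSpec, detectorSpec, seed)
  rows <- lapply(cohort, function(p) {
    writeVolume(p$labels, file.path(dir, paste0(p$id, "_gt.nii.gz")))
    writeVolume(p$likelihood,
                file.path(dir, paste0(p$id, "_likelihood.nii.gz")))
    data.frame(id = p$id, class = p$class, n_tumors = p$nTumors,
               tumor_sizes_cm = paste(round(p$tumorSizesCm, 3),
                                      collapse = ";"))
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Evaluate stored likelihood maps against stored ground truth
#'
#' File-based evaluation entry point: reads per-patient ground truth
#' (`<id>_gt.nii.gz`) from `gtDir` and likelihood maps
#' (`<id>_likelihood.nii.gz`) from `predDir`, extracts and matches
#' candidate lesions, and returns the run structure accepted by
#' [evaluateCohortRun()] and [compareRuns()].
#'
#' @param gtDir directory of ground-truth label maps.
#' @param predDir directory of likelihood maps.
#' @inheritParams runCohortPipeline
#' @return list with `perPatient` and `scores`.
#' @export
loadPredictionRun <- function(gtDir, predDir, relThreshold = 0.4,
                              maxCandidates = 5L, minPeak = 1e-6,
                              connectivity = 26L, diceMin = 0.1) {
  phantoms <- loadCohortFiles(gtDir)
  perPatient <- lapply(phantoms, function(ph) {
    lik <- readVolume(file.path(predDir,
                                paste0(ph$id, "_likelihood.nii.gz")),
                      type = "likelihood")
    cands <- extractCandidates(lik, relThreshold = relThreshold,
                               maxCandidates = maxCandidates,
                               minPeak = minPeak,
                               connectivity = connectivity)
    m <- matchCandidates(cands, ph$gtMasks, diceMin = diceMin)
    list(id = ph$id, class = ph$class, score = patientLikelihood(lik),
         match = m, nLesions = length(ph$gtMasks),
         lesionSizesCm = ph$tumorSizesCm)
  })
  scores <- data.frame(
    id = vapply(perPatient, `[[`, character(1), "id"),
    class = vapply(perPatient, `[[`, character(1), "class"),
    score = vapply(perPatient, `[[`, numeric(1), "score"),
    stringsAsFactors = FALSE)
  list(perPatient = perPatient, scores = scores, skipped = character(0))
}

#' Load a cohort previously written to disk
#'
#' Reads per-patient ground-truth label maps (`<id>_gt.nii.gz`) from a
#' directory written by [simulateCohortFiles()] (or arranged the same
#' way for real annotations), reconstructing the per-patient structure
#' accepted by [runCohortPipeline()].
#'
#' @param dir cohort directory containing `manifest.csv` or
#'   `*_gt.nii.gz` files.
#' @return list as returned by [makePhantomCohort()].
#' @export
loadCohortFiles <- function(dir) {
  gtFiles <- sort(list.files(dir, pattern = "_gt\\.nii(\\.gz)?$",
                             full.names = TRUE))
  if (!length(gtFiles)) stop("no *_gt.nii[.gz] files in ", dir)
  lapply(gtFiles, function(f) {
    id <- sub("_gt\\.nii(\\.gz)?$", "", basename(f))
    labels <- readVolume(f, type = "label")
    gt <- tumorMasks(labels)
    sizes <- vapply(gt, tumorSize, numeric(1), shape = dim(labels@values),
                    spacing = labels@spacing)
    list(id = id, class = if (length(gt)) "PDAC" else "non-PDAC",
         labels = labels, nTumors = length(gt), tumorSizesCm = sizes,
         gtMasks = gt)
  })
}

#' Build and validate a pipeline run configuration
#'
#' Collects every tunable of the Fig-1-style pipeline in one
#' serializable object; [runPipeline()] consumes it. Defaults mirror the
#' published protocol wherever it states a value (relative candidate
#' threshold 0.4, at most 5 candidates, DICE hit criterion 0.1, FP
#' interval \[0.001, 5\], 100,000 permutation iterations, alpha 0.025
#' before Bonferroni); the dilation radius and ROI margin are package
#' defaults.
#'
#' @param outDir run output directory.
#' @param nPos,nNeg simulated cohort sizes.
#' @param phantom,detector named lists of overrides passed to
#'   [phantomSpec()] / [mockDetectorSpec()].
#' @param withPancreas,applyMasking,erodeVoxels,dilationMm,marginMm pipeline
#'   parameters, see [runCohortPipeline()].
#' @param relThreshold,maxCandidates,minPeak,connectivity candidate
#'   extraction parameters, see [extractCandidates()].
#' @param diceMin,fpLo,fpHi,iterations,alpha,nComparisons evaluation and
#'   comparison parameters, see [evaluateCohortRun()] and
#'   [permutationTest()].
#' @param seed master seed of the run.
#' @return validated config object of class `"pdacRunConfig"`.
#' @export
runConfig <- function(outDir = ".", nPos = 10L, nNeg = 10L,
                      phantom = list(), detector = list(),
                      withPancreas = TRUE, applyMasking = TRUE,
                      erodeVoxels = 0L, dilationMm = 5, marginMm = 10,
                      relThreshold = 0.4, maxCandidates = 5L,
                      minPeak = 1e-6, connectivity = 26L, diceMin = 0.1,
                      fpLo = 0.001, fpHi = 5, iterations = 100000L,
                      alpha = 0.025, nComparisons = 1L, seed = 1L) {
  cfg <- list(outDir = outDir, nPos = as.integer(nPos),
              nNeg = as.integer(nNeg), phantom = phantom,
              detector = detector, withPancreas = withPancreas,
              applyMasking = applyMasking,
              erodeVoxels = as.integer(erodeVoxels),
              dilationMm = dilationMm, marginMm = marginMm,
              relThreshold = relThreshold,
              maxCandidates = as.integer(maxCandidates),
              minPeak = minPeak, connectivity = as.integer(connectivity),
              diceMin = diceMin, fpLo = fpLo, fpHi = fpHi,
              iterations = as.integer(iterations), alpha = alpha,
              nComparisons = as.integer(nComparisons),
              seed = as.integer(seed))
  validateRunConfig(cfg)
  structure(cfg, class = "pdacRunConfig")
}

validateRunConfig <- function(cfg) {
  with(cfg, {
    if (relThreshold <= 0 || relThreshold > 1)
      stop("relThreshold must lie in (0, 1]")
    if (maxCandidates < 1) stop("maxCandidates must be >= 1")
    if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
    if (diceMin < 0 || diceMin > 1) stop("diceMin must lie in [0, 1]")
    if (fpLo >= fpHi) stop("fpLo must be < fpHi")
    if (dilationMm < 0 || marginMm < 0)
      stop("dilationMm and marginMm must be >= 0")
    if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
    if (iterations < 1) stop("iterations must be >= 1")
    if (nPos < 0 || nNeg < 0) stop("cohort sizes must be >= 0")
  })
  invisible(cfg)
}

#' Read / write a run configuration as YAML
#'
#' Round trips are byte-identical (write, read, write yields the same
#' file), so a saved config plus its seed reproduces a run.
#'
#' @param cfg a [runConfig()] object.
#' @param path YAML file path.
#' @export
writeRunConfig <- function(cfg, path) {
  validateRunConfig(cfg)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(runConfig, raw)
}

#' Run the end-to-end pipeline from a configuration
#'
#' Simulates the configured phantom cohort, runs ROI extraction,
#' detection, post-processing and candidate extraction for every
#' patient, evaluates patient-level ROC and lesion-level FROC, and
#' writes all artifacts into `outDir`: per-patient likelihood NIfTI and
#' candidate JSON, `metrics.json`, `roc.csv` / `froc.csv`, the resolved
#' `config.yaml` (including package version and seed), and `run_log.txt`
#' with per-stage timing and per-patient status.
#'
#' @param cfg a [runConfig()] (validated before any I/O).
#' @return the [evaluateCohortRun()] result, invisibly, with elements
#'   `run` and `phantoms` attached.
#' @export
runPipeline <- function(cfg) {
  validateRunConfig(cfg)
  if (!dir.exists(cfg$outDir)) dir.create(cfg$outDir, recursive = TRUE)
  logFile <- file.path(cfg$outDir, "run_log.txt")
  logLine <- function(...) cat(sprintf(...), "\n", sep = "",
                               file = logFile, append = TRUE)
  cat("", file = logFile)
  t0 <- Sys.time()
  phSpec <- do.call(phantomSpec, cfg$phantom)
  detSpec <- do.call(mockDetectorSpec, cfg$detector)
  phantoms <- makePhantomCohort(cfg$nPos, cfg$nNeg, phSpec,
                                seed = cfg$seed)
  logLine("simulate: %d patients in %.1fs", length(phantoms),
          as.numeric(Sys.time() - t0, units = "secs"))
  t1 <- Sys.time()
  run <- runCohortPipeline(phantoms, detSpec,
                           withPancreas = cfg$withPancreas,
                           applyMasking = cfg$applyMasking,
                           erodeVoxels = cfg$erodeVoxels,
                           dilationMm = cfg$dilationMm,
                           marginMm = cfg$marginMm,
                           relThreshold = cfg$relThreshold,
                           maxCandidates = cfg$maxCandidates,
                           minPeak = cfg$minPeak,
                           connectivity = cfg$connectivity,
                           diceMin = cfg$diceMin,
                           seed = cfg$seed + 1L, outDir = cfg$outDir)
  for (p in run$perPatient) logLine("patient %s: ok (score %.4f)",
                                    p$id, p$score)
  for (s in run$skipped) logLine("patient %s: skipped (pancreas not found)",
                                 s)
  logLine("detect: %.1fs", as.numeric(Sys.time() - t1, units = "secs"))
  t2 <- Sys.time()
  ev <- evaluateCohortRun(run, fpLo = cfg$fpLo, fpHi = cfg$fpHi,
                          outDir = cfg$outDir)
  logLine("evaluate: %.1fs", as.numeric(Sys.time() - t2, units = "secs"))
  resolved <- unclass(cfg)
  resolved$package_version <-
    as.character(utils::packageVersion("pdacdetect"))
  yaml::write_yaml(resolved, file.path(cfg$outDir, "config.yaml"))
  ev$run <- run
  ev$phantoms <- phantoms
  invisible(ev)
}
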