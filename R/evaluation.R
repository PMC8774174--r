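#' DICE similarity coefficient of two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)` computed in 3D on voxel sets. Masks
#' may be given as binary volumes/arrays on one grid or as (sorted or
#' unsorted) linear voxel index vectors. Two empty masks are an error
#' (the coefficient is undefined).
#'
#' @param a,b binary [CTVolume-class]/arrays of identical shape, or
#'   integer vectors of linear voxel indices.
#' @return numeric(1) in \[0, 1\].
#' @examples
#' diceCoefficient(c(1L, 2L, 3L, 4L), c(2L, 3L, 4L, 7L, 8L, 9L))
#' @export
diceCoefficient <- function(a, b) {
  toIdx <- function(x) {
    if (is(x, "CTVolume")) return(list(idx = which(x@values != 0),
                                       d = dim(x@values)))
    if (is.array(x)) return(list(idx = which(x != 0), d = dim(x)))
    list(idx = as.integer(x), d = NULL)
  }
  A <- toIdx(a); B <- toIdx(b)
  if (!is.null(A$d) && !is.null(B$d) && !identical(A$d, B$d))
    stop("masks are on different grids")
  nA <- length(A$idx); nB <- length(B$idx)
  if (nA == 0L && nB == 0L)
    stop("DICE is undefined for two empty masks")
  2 * length(intersect(A$idx, B$idx)) / (nA + nB)
}

#' Match candidate lesions to ground-truth lesions
#'
#' Greedy one-to-one assignment implementing the detection hit
#' criterion: candidates are processed in descending confidence; each is
#' matched to the still-unmatched ground-truth lesion with the highest
#' DICE, provided that DICE is at least `diceMin` (inclusive, default
#' 0.1). Unmatched candidates are false positives; on a tumor-free
#' patient every candidate is a false positive.
#'
#' @param candidates output of [extractCandidates()] (voxel indices in
#'   the same space as the ground truth).
#' @param gtLesions list of ground-truth lesion masks (linear voxel index
#'   vectors), e.g. from [tumorMasks()].
#' @param diceMin minimum DICE for a hit.
#' @return list with `candidates`: data.frame(rank, confidence, isTP,
#'   lesion, dice), and `lesions`: data.frame(lesion, hit, confidence)
#'   where `confidence` is the matched candidate's confidence (NA if
#'   missed).
#' @export
matchCandidates <- function(candidates, gtLesions, diceMin = 0.1) {
  nC <- length(candidates); nL <- length(gtLesions)
  candDf <- data.frame(rank = integer(0), confidence = numeric(0),
                       isTP = logical(0), lesion = integer(0),
                       dice = numeric(0))
  lesDf <- data.frame(lesion = seq_len(nL), hit = rep(FALSE, nL),
                      confidence = rep(NA_real_, nL))
  if (nC) {
    conf <- vapply(candidates, `[[`, numeric(1), "confidence")
    ord <- order(conf, decreasing = TRUE)
    taken <- rep(FALSE, nL)
    rows <- vector("list", nC)
    for (o in ord) {
      cd <- candidates[[o]]
      best <- 0; bestL <- NA_integer_
      if (nL) for (l in seq_len(nL)) {
        if (taken[l]) next
        dc <- 2 * length(intersect(cd$voxels, gtLesions[[l]])) /
          (cd$nVoxels + length(gtLesions[[l]]))
        if (dc > best) { best <- dc; bestL <- l }
      }
      hit <- !is.na(bestL) && best >= diceMin
      if (hit) {
        taken[bestL] <- TRUE
        lesDf$hit[bestL] <- TRUE
        lesDf$confidence[bestL] <- cd$confidence
      }
      rows[[o]] <- data.frame(rank = cd$rank, confidence = cd$confidence,
                              isTP = hit,
                              lesion = if (hit) bestL else NA_integer_,
                              dice = if (hit) best else NA_real_)
    }
    candDf <- do.call(rbind, rows)
    candDf <- candDf[order(candDf$rank), , drop = FALSE]
    rownames(candDf) <- NULL
  }
  list(candidates = candDf, lesions = lesDf)
}

#' Patient-level ROC curve and AUC
#'
#' Sweeps a threshold over the patient likelihoods, plotting sensitivity
#' (true-positive rate) against 1 - specificity. The AUC is computed by
#' the trapezoidal rule, which with threshold sweeping over unique scores
#' equals the rank-sum estimator `P(score_pos > score_neg) + 0.5 P(tie)`.
#'
#' @param scoresPos patient likelihoods of tumor-bearing patients.
#' @param scoresNeg patient likelihoods of tumor-free patients.
#' @return an [EvalCurve-class] of kind "ROC".
#' @examples
#' rocCurve(c(0.9, 0.8), c(0.1, 0.2))@auc
#' @export
rocCurve <- function(scoresPos, scoresNeg) {
  if (!length(scoresPos) || !length(scoresNeg))
    stop("need at least one positive and one negative patient")
  thr <- sort(unique(c(scoresPos, scoresNeg)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scoresPos >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scoresNeg >= t), numeric(1))
  x <- c(0, fpr); y <- c(0, tpr); th <- c(Inf, thr)
  if (x[length(x)] < 1 || y[length(y)] < 1) {  # anchor at (1, 1)
    x <- c(x, 1); y <- c(y, 1); th <- c(th, -Inf)
  }
  auc <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  new("EvalCurve", x = x, y = y, threshold = th, kind = "ROC", auc = auc)
}

#' Lesion-level FROC curve
#'
#' Free-response ROC: lesion sensitivity against the mean number of
#' false-positive candidates per patient, swept over candidate
#' confidences. Sensitivity at threshold `t` is the fraction of all
#' ground-truth lesions (pooled over the cohort) whose matched
#' true-positive candidate has confidence `>= t`; the FP rate averages
#' false-positive candidates with confidence `>= t` over all patients,
#' tumor-free patients included.
#'
#' @param perPatient list with one entry per patient, each a list with
#'   `match` (output of [matchCandidates()]) and `nLesions`; use
#'   [evaluateCohort()] to build it from maps.
#' @return an [EvalCurve-class] of kind "FROC".
#' @export
frocCurve <- function(perPatient) {
  nPat <- length(perPatient)
  totLesions <- sum(vapply(perPatient, `[[`, numeric(1), "nLesions"))
  if (totLesions == 0)
    stop("FROC requires at least one ground-truth lesion in the cohort")
  cands <- do.call(rbind, lapply(perPatient, function(p) p$match$candidates))
  if (is.null(cands) || !nrow(cands)) {
    return(new("EvalCurve", x = 0, y = 0, threshold = Inf, kind = "FROC"))
  }
  thr <- sort(unique(cands$confidence), decreasing = TRUE)
  sens <- vapply(thr, function(t)
    sum(cands$isTP & cands$confidence >= t) / totLesions, numeric(1))
  fp <- vapply(thr, function(t)
    sum(!cands$isTP & cands$confidence >= t) / nPat, numeric(1))
  new("EvalCurve", x = c(0, fp), y = c(0, sens), threshold = c(Inf, thr),
      kind = "FROC")
}

#' Partial area under the FROC curve
#'
#' Integrates lesion sensitivity over the mean-FP-per-patient axis
#' (linear scale) restricted to `[fpLo, fpHi]`, by the trapezoidal rule
#' on the piecewise-linear interpolation of the curve's operating
#' points; beyond its last point the curve is extended as a constant
#' (last sensitivity carried forward). The maximum attainable value over
#' the default interval \[0.001, 5\] is 4.999.
#'
#' @param curve an [EvalCurve-class] of kind "FROC".
#' @param fpLo,fpHi integration interval on the FP/patient axis.
#' @return numeric(1) partial area, in \[0, fpHi - fpLo\].
#' @export
paucFroc <- function(curve, fpLo = 0.001, fpHi = 5) {
  stopifnot(is(curve, "EvalCurve"))
  if (curve@kind != "FROC") stop("pAUC-FROC requires a FROC curve")
  if (fpLo >= fpHi) stop("fpLo must be < fpHi")
  x <- curve@x; y <- curve@y
  n <- length(x)
  interp <- function(t) {
    if (t <= x[1]) return(y[1])
    if (t >= x[n]) return(y[n])
    j <- findInterval(t, x, rightmost.closed = FALSE) + 1L
    # x[j-1] <= t < x[j]; findInterval returns the last index with x <= t,
    # step over any exact ties to the segment's upper knot value
    while (j <= n && x[j] == t) j <- j + 1L
    jl <- j - 1L
    if (x[j] == x[jl]) return(y[j])
    y[jl] + (t - x[jl]) / (x[j] - x[jl]) * (y[j] - y[jl])
  }
  area <- 0; prevX <- fpLo; prevY <- interp(fpLo)
  for (i in seq_len(n)) {
    if (x[i] <= fpLo) next
    if (x[i] >= fpHi) break
    area <- area + (x[i] - prevX) * (prevY + y[i]) / 2
    prevX <- x[i]; prevY <- y[i]
  }
  area + (fpHi - prevX) * (prevY + interp(fpHi)) / 2
}

#' Mean operating curve with pointwise confidence band
#'
#' Interpolates each curve onto a shared x grid (monotone step-wise,
#' last value carried forward) and returns the pointwise mean together
#' with the 2.5 and 97.5 percentiles, as used to display the spread of
#' an ensemble of independently trained models.
#'
#' @param curves list of [EvalCurve-class] objects of one kind (>= 2).
#' @param grid x values to evaluate on; defaults to the union of the
#'   curves' x knots.
#' @return data.frame with columns `x`, `mean`, `lower`, `upper`;
#'   attribute `kind` carries the curve kind.
#' @export
meanCurves <- function(curves, grid = NULL) {
  if (length(curves) < 2) stop("need at least two curves")
  kinds <- unique(vapply(curves, slot, character(1), "kind"))
  if (length(kinds) != 1) stop("cannot average curves of mixed kinds")
  if (is.null(grid))
    grid <- sort(unique(unlist(lapply(curves, slot, "x"))))
  vals <- vapply(curves, function(cv) {
    vapply(grid, function(g) {
      i <- which(cv@x <= g)
      if (!length(i)) cv@y[1] else max(cv@y[i])  # step, carried forward
    }, numeric(1))
  }, numeric(length(grid)))
  vals <- matrix(vals, nrow = length(grid))
  out <- data.frame(x = grid,
                    mean = rowMeans(vals),
                    lower = apply(vals, 1, stats::quantile, 0.025),
                    upper = apply(vals, 1, stats::quantile, 0.975))
  attr(out, "kind") <- kinds
  out
}

#' Paired permutation test for a difference in AUC-ROC or pAUC-FROC
#'
#' Tests whether two models differ in patient-level AUC-ROC or
#' lesion-level pAUC-FROC on the same patient cohort. The observed
#' statistic is `stat(A) - stat(B)`; under the null the per-patient
#' model assignment is exchangeable, so each iteration independently
#' swaps A and B within each patient with probability 1/2 and recomputes
#' the difference. The two-sided p-value uses the +1 finite-sample
#' correction, `p = (1 + #(|perm| >= |observed|)) / (iterations + 1)`.
#' Significance is judged at `alpha / nComparisons` (Bonferroni), with
#' `alpha = 0.025` matching a 97.5% confidence level.
#'
#' @param predA,predB paired per-patient predictions. For
#'   `statistic = "auc"`: data.frames with columns `id`, `score`,
#'   `class` ("PDAC"/"non-PDAC"). For `statistic = "pauc_froc"`: lists
#'   as accepted by [frocCurve()] plus an `id` element per patient.
#' @param statistic "auc" or "pauc_froc".
#' @param iterations Monte-Carlo iterations (default 100000).
#' @param fpLo,fpHi pAUC integration interval (FROC statistic only).
#' @param alpha pre-Bonferroni significance level.
#' @param nComparisons number of pairwise comparisons corrected for.
#' @param seed RNG seed for the permutation draws.
#' @return list with `observed`, `p`, `iterations`, `alpha`,
#'   `significant`, `statistic`, `seed`.
#' @export
permutationTest <- function(predA, predB, statistic = c("auc", "pauc_froc"),
                            iterations = 100000L, fpLo = 0.001, fpHi = 5,
                            alpha = 0.025, nComparisons = 1L, seed = 1L) {
  statistic <- match.arg(statistic)
  iterations <- as.integer(iterations)
  if (statistic == "auc") {
    if (!identical(predA$id, predB$id))
      stop("predictions are not paired: patient ids differ")
    isPos <- predA$class == "PDAC"
    if (!identical(isPos, predB$class == "PDAC"))
      stop("class labels differ between paired predictions")
    statA <- rocCurve(predA$score[isPos], predA$score[!isPos])@auc
    statB <- rocCurve(predB$score[isPos], predB$score[!isPos])@auc
    observed <- statA - statB
    perm <- withSeed(seed,
      cpp_perm_auc(predA$score, predB$score, isPos, iterations))
  } else {
    idA <- vapply(predA, `[[`, character(1), "id")
    idB <- vapply(predB, `[[`, character(1), "id")
    if (!identical(idA, idB))
      stop("predictions are not paired: patient ids differ")
    observed <- paucFroc(frocCurve(predA), fpLo, fpHi) -
      paucFroc(frocCurve(predB), fpLo, fpHi)
    flat <- function(pred, src) {
      do.call(rbind, lapply(seq_along(pred), function(i) {
        cd <- pred[[i]]$match$candidates
        if (is.null(cd) || !nrow(cd)) return(NULL)
        data.frame(patient = i - 1L, conf = cd$confidence, isTP = cd$isTP,
                   src = src)
      }))
    }
    tab <- rbind(flat(predA, 0L), flat(predB, 1L))
    totLesions <- sum(vapply(predA, `[[`, numeric(1), "nLesions"))
    perm <- withSeed(seed,
      cpp_perm_pauc(tab$patient, tab$conf, tab$isTP, tab$src,
                    length(predA), totLesions, fpLo, fpHi, iterations))
  }
  p <- (1 + sum(abs(perm) >= abs(observed) - 1e-12)) / (iterations + 1)
  alphaAdj <- alpha / nComparisons
  list(observed = observed, p = p, iterations = iterations,
       alpha = alphaAdj, significant = p < alphaAdj,
       statistic = statistic, seed = seed)
}
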