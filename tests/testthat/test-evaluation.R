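test_that("DICE coefficient follows its set definition", {
  a <- c(1L, 2L, 3L, 4L)
  expect_equal(diceCoefficient(a, a), 1.0)
  expect_equal(diceCoefficient(a, c(10L, 11L)), 0.0)
  expect_equal(diceCoefficient(a, c(2L, 3L, 4L, 7L, 8L, 9L)), 0.6)
  expect_error(diceCoefficient(integer(0), integer(0)), "undefined")
  x <- array(0L, c(4, 4, 4)); x[1:2, 1, 1] <- 1L
  y <- array(0L, c(5, 5, 5)); y[1, 1, 1] <- 1L
  expect_error(diceCoefficient(x, y), "different grids")
})

test_that("candidate-lesion matching is greedy, one-to-one, and inclusive
           at the DICE threshold", {
  mkCand <- function(vox, conf, rank)
    list(rank = rank, confidence = conf, voxels = as.integer(vox),
         nVoxels = length(vox), volumeMm3 = length(vox))

  lesion <- 1:10
  # identical candidate: hit
  m <- matchCandidates(list(mkCand(1:10, 0.9, 1)), list(lesion))
  expect_true(m$lesions$hit[1])
  expect_equal(m$lesions$confidence[1], 0.9)

  # DICE exactly 0.1 is a hit ("at least 0.1"): |A|=10, |B|=30, |int|=2
  cand <- c(1:2, 100:127)
  expect_equal(diceCoefficient(cand, lesion), 0.1)
  m2 <- matchCandidates(list(mkCand(cand, 0.5, 1)), list(lesion))
  expect_true(m2$lesions$hit[1])
  # ... and just below 0.1 is a miss
  cand3 <- c(1L, 100:128)
  m3 <- matchCandidates(list(mkCand(cand3, 0.5, 1)), list(lesion))
  expect_false(m3$lesions$hit[1])
  expect_false(m3$candidates$isTP[1])

  # two candidates over one lesion: the higher-confidence one wins
  m4 <- matchCandidates(list(mkCand(1:8, 0.4, 1), mkCand(3:10, 0.8, 2)),
                        list(lesion))
  expect_equal(m4$candidates$isTP, c(FALSE, TRUE))
  # tumor-free patient: everything is a false positive
  m5 <- matchCandidates(list(mkCand(1:4, 0.9, 1)), list())
  expect_false(any(m5$candidates$isTP))
})

test_that("ROC curves and AUC match the pairwise probability estimator", {
  expect_equal(rocCurve(c(0.9, 0.8), c(0.1, 0.2))@auc, 1.0)
  expect_equal(rocCurve(0.5, 0.5)@auc, 0.5)
  expect_error(rocCurve(numeric(0), c(0.1)), "at least one")

  set.seed(99)
  for (rep in 1:10) {
    nP <- sample(2:40, 1); nN <- sample(2:40, 1)
    pool <- round(runif(20), 1)                 # coarse grid forces ties
    pos <- sample(pool, nP, TRUE); neg <- sample(pool, nN, TRUE)
    cv <- rocCurve(pos, neg)
    expect_equal(cv@auc, bruteAUC(pos, neg), tolerance = 1e-12)
    expect_true(all(diff(cv@x) >= 0) && all(diff(cv@y) >= 0))
  }
})

test_that("pAUC-FROC integrates the curve over the FP interval", {
  mkFroc <- function(x, y)
    new("EvalCurve", x = x, y = y, threshold = seq_along(x) * -1.0,
        kind = "FROC")
  expect_equal(paucFroc(mkFroc(c(0, 6), c(1, 1))), 4.999)  # constant 1
  expect_equal(paucFroc(mkFroc(c(0, 6), c(0, 0))), 0)
  pw <- mkFroc(c(0.001, 1, 5), c(0.2, 0.5, 0.9))
  expect_equal(paucFroc(pw), riemannPauc(c(0.001, 1, 5), c(0.2, 0.5, 0.9),
                                         0.001, 5, n = 2e6),
               tolerance = 1e-6)
  # step carried forward past the last observed FP rate
  short <- mkFroc(c(0, 0.5), c(0, 0.8))
  expect_equal(paucFroc(short),
               riemannPauc(c(0, 0.5), c(0, 0.8), 0.001, 5, n = 2e6),
               tolerance = 1e-6)
  expect_error(paucFroc(pw, fpLo = 5, fpHi = 1), "fpLo")
  expect_error(paucFroc(rocCurve(1, 0)), "FROC")
})

test_that("FROC curves anchor at zero and recover a hand-built cohort", {
  mkCand <- function(vox, conf, rank)
    list(rank = rank, confidence = conf, voxels = as.integer(vox),
         nVoxels = length(vox), volumeMm3 = length(vox))
  # patient 1: lesion hit at confidence 1.0; patient 2: tumor-free, no FPs
  p1 <- list(id = "a", class = "PDAC",
             match = matchCandidates(list(mkCand(1:10, 1.0, 1)),
                                     list(1:10)),
             nLesions = 1)
  p2 <- list(id = "b", class = "non-PDAC",
             match = matchCandidates(list(), list()), nLesions = 0)
  cv <- frocCurve(list(p1, p2))
  expect_equal(cv@x[1], 0); expect_equal(cv@y[1], 0)  # anchor point
  expect_equal(cv@y[length(cv@y)], 1.0)
  expect_equal(cv@x[length(cv@x)], 0)   # perfect: sens 1 at 0 FP/patient
  expect_error(frocCurve(list(p2)), "at least one ground-truth")

  # an FP on the negative patient moves the FP average over both patients
  p2fp <- list(id = "b", class = "non-PDAC",
               match = matchCandidates(list(mkCand(50:55, 0.4, 1)),
                                       list()),
               nLesions = 0)
  cv2 <- frocCurve(list(p1, p2fp))
  expect_equal(max(cv2@x), 0.5)  # 1 FP over 2 patients
  i <- which(cv2@threshold == 1.0)
  expect_equal(cv2@y[i], 1.0); expect_equal(cv2@x[i], 0)
})

test_that("mean curves average step-interpolated members with a band", {
  cv <- rocCurve(c(0.9, 0.8), c(0.1, 0.2))
  mc <- meanCurves(rep(list(cv), 10))
  expect_true(all(mc$upper - mc$lower == 0))     # identical members
  lo <- new("EvalCurve", x = c(0, 1), y = c(0, 0), threshold = c(Inf, 0),
            kind = "ROC")
  hi <- new("EvalCurve", x = c(0, 1), y = c(1, 1), threshold = c(Inf, 0),
            kind = "ROC")
  mc2 <- meanCurves(list(lo, hi), grid = c(0, 0.5, 1))
  expect_equal(mc2$mean, rep(0.5, 3))
  set.seed(5)
  curves <- lapply(1:6, function(i) {
    s <- sort(runif(5)); rocCurve(runif(8), runif(8))
  })
  grid <- seq(0, 1, 0.25)
  mc3 <- meanCurves(curves, grid)
  stepAt <- function(cv, g) {
    i <- which(cv@x <= g); if (!length(i)) cv@y[1] else max(cv@y[i])
  }
  direct <- rowMeans(sapply(curves, function(cv)
    vapply(grid, stepAt, numeric(1), cv = cv)))
  expect_equal(mc3$mean, direct)
  froc <- new("EvalCurve", x = c(0, 1), y = c(0, 1),
              threshold = c(Inf, 0), kind = "FROC")
  expect_error(meanCurves(list(lo, froc)), "mixed")
})

test_that("permutation test is exact on identical inputs and agrees with
           full enumeration at n = 6", {
  sc <- data.frame(id = sprintf("P%d", 1:8),
                   class = rep(c("PDAC", "non-PDAC"), each = 4),
                   score = c(0.9, 0.7, 0.4, 0.8, 0.2, 0.3, 0.5, 0.1))
  same <- permutationTest(sc, sc, "auc", iterations = 500, seed = 3)
  expect_equal(same$observed, 0)
  expect_equal(same$p, 1.0)

  # n = 6 patients: exact null from all 2^6 sign patterns
  set.seed(11)
  a <- data.frame(id = sprintf("P%d", 1:6),
                  class = rep(c("PDAC", "non-PDAC"), each = 3),
                  score = runif(6))
  b <- a; b$score <- runif(6)
  isPos <- a$class == "PDAC"
  aucOf <- function(s) bruteAUC(s[isPos], s[!isPos])
  obs <- aucOf(a$score) - aucOf(b$score)
  diffs <- vapply(0:63, function(mask) {
    sw <- as.logical(bitwAnd(bitwShiftR(mask, 0:5), 1L))
    sa <- ifelse(sw, b$score, a$score)
    sb <- ifelse(sw, a$score, b$score)
    aucOf(sa) - aucOf(sb)
  }, numeric(1))
  pExact <- mean(abs(diffs) >= abs(obs) - 1e-12)
  iters <- 20000L
  mc <- permutationTest(a, b, "auc", iterations = iters, seed = 17)
  expect_equal(mc$observed, obs, tolerance = 1e-12)
  se <- sqrt(pExact * (1 - pExact) / iters)
  expect_lt(abs(mc$p - pExact), 3 * se + 2 / iters)
  expect_error(permutationTest(a, b[6:1, ], "auc"), "paired")
})

test_that("pAUC-FROC permutation statistic agrees with the R-side curve
           computation", {
  mkCand <- function(vox, conf, rank)
    list(rank = rank, confidence = conf, voxels = as.integer(vox),
         nVoxels = length(vox), volumeMm3 = length(vox))
  # one patient, so every sign flip yields exactly +/- the observed diff:
  # the C++ permutation pAUC must reproduce the R pAUC to within fp noise
  pA <- list(list(id = "a", class = "PDAC",
                  match = matchCandidates(list(mkCand(1:10, 0.9, 1),
                                               mkCand(60:70, 0.3, 2)),
                                          list(1:10)),
             nLesions = 1))
  pB <- list(list(id = "a", class = "PDAC",
                  match = matchCandidates(list(mkCand(2:9, 0.6, 1)),
                                          list(1:10)),
             nLesions = 1))
  res <- permutationTest(pA, pB, "pauc_froc", iterations = 200, seed = 5)
  obs <- paucFroc(frocCurve(pA)) - paucFroc(frocCurve(pB))
  expect_equal(res$observed, obs)
  perm <- pdacdetect:::withSeed(5, pdacdetect:::cpp_perm_pauc(
    c(0L, 0L, 0L), c(0.9, 0.3, 0.6), c(TRUE, FALSE, TRUE), c(0L, 0L, 1L),
    1L, 1L, 0.001, 5, 200L))
  expect_true(all(abs(abs(perm) - abs(obs)) < 1e-12))
  expect_equal(res$p, 1.0)   # |perm| always equals |observed|
})
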