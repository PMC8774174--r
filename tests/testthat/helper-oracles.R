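# Independent brute-force reference implementations used to validate the
# package's algorithms. These deliberately share no code with R/ or src/:
# plain loops, recomputing everything from scratch.

# iterative argmax + flood-fill candidate extraction, recomputed from
# scratch each iteration
bruteExtractCandidates <- function(arr, relThreshold = 0.4,
                                   maxCandidates = 5L, minPeak = 1e-6,
                                   connectivity = 26L) {
  d <- dim(arr)
  w <- arr
  out <- list()
  neigh <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  neigh <- neigh[!(neigh$dx == 0 & neigh$dy == 0 & neigh$dz == 0), ]
  if (connectivity == 6L)
    neigh <- neigh[abs(neigh$dx) + abs(neigh$dy) + abs(neigh$dz) == 1, ]
  repeat {
    if (length(out) >= maxCandidates) break
    peak <- max(w)
    if (peak < minPeak) break
    seed <- which(w == peak)[1]           # lowest linear index on ties
    thr <- relThreshold * peak
    inReg <- array(FALSE, d)
    inReg[seed] <- TRUE
    repeat {
      grew <- FALSE
      idx <- which(inReg, arr.ind = TRUE)
      for (r in seq_len(nrow(idx))) {
        for (k in seq_len(nrow(neigh))) {
          p <- idx[r, ] + c(neigh$dx[k], neigh$dy[k], neigh$dz[k])
          if (any(p < 1) || any(p > d)) next
          if (!inReg[p[1], p[2], p[3]] && w[p[1], p[2], p[3]] >= thr) {
            inReg[p[1], p[2], p[3]] <- TRUE
            grew <- TRUE
          }
        }
      }
      if (!grew) break
    }
    out[[length(out) + 1L]] <- list(indices = sort(which(inReg)),
                                    peak = peak)
    w[inReg] <- 0
  }
  out
}

# metric dilation by exhaustive pairwise distance check
bruteDilate <- function(mask, spacing, radiusMm) {
  d <- dim(mask)
  fg <- which(mask != 0, arr.ind = TRUE)
  if (nrow(fg) == 0) return(mask)
  out <- array(FALSE, d)
  all <- which(array(TRUE, d), arr.ind = TRUE)
  for (i in seq_len(nrow(all))) {
    dd <- sweep(fg, 2, all[i, ])
    d2 <- (dd[, 1] * spacing[1])^2 + (dd[, 2] * spacing[2])^2 +
          (dd[, 3] * spacing[3])^2
    out[all[i, 1], all[i, 2], all[i, 3]] <- any(d2 <= radiusMm^2 + 1e-9)
  }
  out
}

# pairwise P(pos > neg) + 0.5 P(tie) AUC estimator
bruteAUC <- function(pos, neg) {
  s <- 0
  for (p in pos) for (n in neg)
    s <- s + (p > n) + 0.5 * (p == n)
  s / (length(pos) * length(neg))
}

# fine-grid Riemann integral of the piecewise-linear interpolation of
# (x, y) knots, constant beyond the ends
riemannPauc <- function(x, y, lo, hi, n = 1e6) {
  grid <- seq(lo, hi, length.out = n)
  vals <- approx(x, y, xout = grid, rule = 2, ties = list("ordered", max))$y
  mid <- (vals[-1] + vals[-n]) / 2
  sum(mid * diff(grid))
}

# binary ball mask centered in a cubic grid
makeBall <- function(n, radiusVox, center = rep((n + 1) / 2, 3)) {
  idx <- which(array(TRUE, c(n, n, n)), arr.ind = TRUE)
  d2 <- (idx[, 1] - center[1])^2 + (idx[, 2] - center[2])^2 +
        (idx[, 3] - center[3])^2
  array(as.integer(d2 <= radiusVox^2), c(n, n, n))
}

diceArrays <- function(a, b) {
  2 * sum(a != 0 & b != 0) / (sum(a != 0) + sum(b != 0))
}

# small fast phantom spec for unit tests
testPhantomSpec <- function(...) {
  phantomSpec(shape = c(48L, 48L, 32L), spacing = c(2.5, 2.5, 3),
              pancreasRadiusMm = 12, tumorRadiusRange = c(8, 12), ...)
}
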