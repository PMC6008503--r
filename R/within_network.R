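# Within-network voxelwise group inference: permutation of group labels,
# threshold-free cluster enhancement of the two-sample t map, and
# family-wise error control by the null distribution of the maximum
# enhanced statistic over the mask.

#' TFCE parameters
#'
#' Defaults are the standard published TFCE settings: height exponent
#' `H = 2`, extent exponent `E = 0.5`, 26-voxel connectivity, integration
#' step `dh = max/100` (chosen per map when `dh` is `NA`).
#'
#' @param H height exponent (>= 0).
#' @param E extent exponent (>= 0).
#' @param dh threshold integration step; `NA` = max of the map / 100.
#' @param connectivity 6, 18, or 26.
#' @return list of class `tfceParams`.
#' @export
tfceParams <- function(H = 2, E = 0.5, dh = NA_real_, connectivity = 26L) {
  stopifnot(H >= 0, E >= 0, is.na(dh) || dh > 0,
            connectivity %in% c(6L, 18L, 26L))
  structure(list(H = H, E = E, dh = dh,
                 connectivity = as.integer(connectivity)),
            class = "tfceParams")
}

as3d <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("statmap must be an array")
  if (length(d) == 2L) {
    dim(x) <- c(d, 1L)
  } else if (length(d) != 3L) stop("statmap must be 2D or 3D")
  x
}

#' Threshold-free cluster enhancement
#'
#' For each voxel, integrates `extent(h)^E * h^H dh` over cluster-forming
#' thresholds `h` up to the voxel's height, where `extent(h)` is the size
#' of the connected suprathreshold cluster containing the voxel. Positive
#' and negative tails are enhanced separately and combined into a signed
#' map: positive values enhance positive statistics, negative values
#' negative ones.
#'
#' @param statmap 2D or 3D numeric array of voxelwise statistics.
#' @param params a [tfceParams()] list.
#' @param mask optional logical array; voxels outside are ignored.
#' @return signed enhanced array, same shape as `statmap`.
#' @export
tfce <- function(statmap, params = tfceParams(), mask = NULL) {
  v <- as3d(statmap)
  if (!is.null(mask)) {
    m <- as3d(mask)
    if (!identical(dim(m), dim(v))) stop("mask shape mismatch")
    if (!any(m)) stop("mask is empty")
    v[!m] <- 0
  }
  d <- dim(v)
  dh <- if (is.na(params$dh)) -1 else params$dh
  pos <- .tfcePositive(as.numeric(pmax(v, 0)), as.integer(d),
                       params$H, params$E, dh, params$connectivity)
  neg <- .tfcePositive(as.numeric(pmax(-v, 0)), as.integer(d),
                       params$H, params$E, dh, params$connectivity)
  out <- array(pos - neg, d)
  dim(out) <- dim(statmap)
  out
}

pooledT <- function(X, isA) {
  nA <- sum(isA); nB <- sum(!isA)
  mA <- colMeans(X[isA, , drop = FALSE])
  mB <- colMeans(X[!isA, , drop = FALSE])
  vA <- colSums(sweep(X[isA, , drop = FALSE], 2, mA)^2)
  vB <- colSums(sweep(X[!isA, , drop = FALSE], 2, mB)^2)
  sp <- (vA + vB) / (nA + nB - 2)
  se <- sqrt(sp * (1 / nA + 1 / nB))
  se[se < .Machine$double.eps] <- Inf
  (mA - mB) / se
}

#' Permutation scheme
#'
#' @param nPermutations random group-label permutations (default 5000);
#'   when the number of distinct label splits is smaller, all splits are
#'   enumerated instead (with a warning).
#' @param seed integer seed making the test deterministic.
#' @return list of class `permScheme`.
#' @export
permScheme <- function(nPermutations = 5000L, seed = 1L) {
  stopifnot(nPermutations >= 1L)
  structure(list(nPermutations = as.integer(nPermutations),
                 seed = as.integer(seed)), class = "permScheme")
}

#' Permutation test of a group difference within a mask
#'
#' Voxelwise two-sample (pooled-variance) t statistics on subject-level
#' maps are enhanced by TFCE; group labels are permuted and the maximum
#' absolute enhanced statistic over the mask forms the null. Corrected p
#' values are `(1 + #\{null max >= observed\}) / (1 + nPermutations)` —
#' the identity labeling is part of the null, so p > 0 — reported
#' directionally for both tails (A > B and B > A) against the common
#' max-|TFCE| null, which controls family-wise error over the two-sided
#' family. With few subjects, all distinct label splits are enumerated and
#' `p = #\{enumerated max >= observed\} / n_splits`.
#'
#' @param mapsA,mapsB subjects x voxels matrices of subject-level maps
#'   (vectorized over the full volume), one row per subject.
#' @param volumeDim integer(3) spatial dimensions the voxel axis folds to.
#' @param mask logical array restricting inference (e.g. an extreme-10%
#'   network mask from [topFractionMask()]).
#' @param scheme a [permScheme()].
#' @param params a [tfceParams()].
#' @return list of class `permTestResult`: `tmap`, `enhanced` (signed
#'   observed TFCE), `pPos`, `pNeg` (corrected p arrays, NA outside the
#'   mask), `nullMax`, `nPermutations`, `exhaustive`, `seed`.
#' @export
permutationTest <- function(mapsA, mapsB, volumeDim, mask,
                            scheme = permScheme(), params = tfceParams()) {
  nA <- nrow(mapsA); nB <- nrow(mapsB)
  if (nA < 2L || nB < 2L) stop("need at least 2 subjects per group")
  X <- rbind(mapsA, mapsB)
  m3 <- as3d(mask)
  if (!any(m3)) stop("mask is empty")
  mv <- as.vector(m3)
  if (ncol(X) != length(mv)) stop("map length does not match volumeDim")
  n <- nA + nB
  isA0 <- c(rep(TRUE, nA), rep(FALSE, nB))
  Xm <- X[, mv, drop = FALSE]

  # fix dh from the observed map so the enhancement is comparable across
  # permutations (per-permutation dh would rescale the null)
  tObs <- pooledT(Xm, isA0)
  dh <- params$dh
  if (is.na(dh)) {
    dh <- max(abs(tObs)) / 100
    if (dh <= 0) dh <- 1e-3
  }
  prm <- tfceParams(params$H, params$E, dh, params$connectivity)

  enhOf <- function(tvals) {
    full <- numeric(length(mv))
    full[mv] <- tvals
    tfce(array(full, dim(m3)), prm)
  }
  enhObs <- enhOf(tObs)
  obsVals <- enhObs[m3]

  nSplits <- choose(n, nA)
  exhaustive <- is.finite(nSplits) && nSplits <= scheme$nPermutations
  if (exhaustive) {
    if (nSplits < scheme$nPermutations)
      warning(sprintf(
        "only %d distinct label splits; enumerating all of them", nSplits))
    splits <- combn(n, nA)
    nullMax <- apply(splits, 2, function(idx) {
      isA <- seq_len(n) %in% idx
      max(abs(enhOf(pooledT(Xm, isA))[m3]))
    })
    countGe <- function(x) sum(nullMax >= x - 1e-12)
    pOf <- function(x) countGe(x) / nSplits
  } else {
    nullMax <- withSeed(scheme$seed, {
      vapply(seq_len(scheme$nPermutations), function(b) {
        isA <- seq_len(n) %in% sample(n, nA)
        max(abs(enhOf(pooledT(Xm, isA))[m3]))
      }, numeric(1))
    })
    pOf <- function(x) (1 + sum(nullMax >= x - 1e-12)) /
      (1 + scheme$nPermutations)
  }
  pPos <- array(NA_real_, dim(m3))
  pNeg <- array(NA_real_, dim(m3))
  pPos[m3] <- vapply(pmax(obsVals, 0), pOf, numeric(1))
  pNeg[m3] <- vapply(pmax(-obsVals, 0), pOf, numeric(1))
  tArr <- array(NA_real_, dim(m3)); tArr[m3] <- tObs
  structure(list(tmap = tArr, enhanced = enhObs, pPos = pPos, pNeg = pNeg,
                 nullMax = nullMax,
                 nPermutations = if (exhaustive) nSplits else
                   scheme$nPermutations,
                 exhaustive = exhaustive, seed = scheme$seed),
            class = "permTestResult")
}

#' Summarize suprathreshold clusters of a p map
#'
#' Connected components (26-connectivity by default) of voxels with
#' `p <= alpha`, with size, peak (minimum-p) voxel and peak p, sorted by
#' size.
#'
#' @param pmap numeric array of corrected p values (NA outside the mask).
#' @param alpha significance threshold.
#' @param connectivity 6, 18 or 26.
#' @return data.frame: cluster, size, x, y, z (1-based peak voxel indices),
#'   peakP. Zero rows when nothing survives.
#' @export
clusterSummary <- function(pmap, alpha = 0.05, connectivity = 26L) {
  p3 <- as3d(pmap)
  sig <- !is.na(p3) & p3 <= alpha
  if (!any(sig))
    return(data.frame(cluster = integer(), size = integer(),
                      x = integer(), y = integer(), z = integer(),
                      peakP = numeric()))
  lab <- array(.labelComponents(as.vector(sig), as.integer(dim(p3)),
                                as.integer(connectivity)), dim(p3))
  ids <- sort(unique(lab[lab > 0]))
  rows <- lapply(ids, function(id) {
    w <- which(lab == id, arr.ind = TRUE)
    pv <- p3[lab == id]
    peak <- which.min(pv)
    data.frame(cluster = id, size = nrow(w),
               x = w[peak, 1], y = w[peak, 2], z = w[peak, 3],
               peakP = pv[peak])
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$size), ]
  out$cluster <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
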