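# FIR task design and nuisance regression. One free indicator per
# (condition, poststimulus scan) estimates the HDR shape without assuming
# its form; nuisance variance (rigid-body motion first, then drift and
# intercept) is removed before the multivariate decomposition.

#' Build a finite impulse response design matrix
#'
#' For each trial, the onset scan is the first full scan starting at or
#' after stimulus onset; indicator 1s are placed at that scan and the
#' following `nBins - 1` scans in the trial's condition columns, one column
#' per poststimulus bin. Overlapping trials sum. The modeled poststimulus
#' window spans `nBins * tr` seconds. Trials whose FIR window would run off
#' the scan axis are truncated with a warning.
#'
#' @param events data.frame with columns onset (s), duration (s), condition.
#' @param nScans number of scans on the time axis.
#' @param tr repetition time (s).
#' @param nBins poststimulus bins (default 6).
#' @param conditions condition levels (default: sorted unique conditions).
#' @param binAnchor `"midpoint"` labels bin k at `(k - 0.5) * tr` (scan
#'   midpoint, the default); `"onset"` labels it `(k - 1) * tr`.
#' @return a [FirDesign-class].
#' @export
buildFirDesign <- function(events, nScans, tr, nBins = 6L, conditions = NULL,
                           binAnchor = c("midpoint", "onset")) {
  binAnchor <- match.arg(binAnchor)
  nBins <- as.integer(nBins)
  stopifnot(nBins >= 1L, nScans >= 1L, tr > 0)
  if (is.null(conditions))
    conditions <- sort(unique(as.character(events$condition)))
  if (nrow(events) && !all(events$condition %in% conditions))
    stop("events contain conditions outside the supplied levels")
  cols <- expand.grid(bin = seq_len(nBins), condition = conditions,
                      stringsAsFactors = FALSE)[, c("condition", "bin")]
  G <- matrix(0, nScans, nrow(cols))
  colnames(G) <- paste0(cols$condition, ":bin", cols$bin)
  truncated <- 0L
  for (i in seq_len(nrow(events))) {
    # first full scan at or after onset; scan r starts at (r-1)*tr
    s0 <- as.integer(ceiling(round(events$onset[i] / tr, 9))) + 1L
    if (s0 > nScans) {
      truncated <- truncated + 1L
      next
    }
    ci <- match(events$condition[i], conditions)
    for (b in seq_len(nBins)) {
      r <- s0 + b - 1L
      if (r > nScans) {
        truncated <- truncated + 1L
        break
      }
      j <- (ci - 1L) * nBins + b
      G[r, j] <- G[r, j] + 1
    }
  }
  if (truncated > 0L)
    warning(sprintf("%d trial(s) had FIR windows truncated at the scan axis",
                    truncated))
  binTimes <- if (binAnchor == "midpoint")
    (seq_len(nBins) - 0.5) * tr else (seq_len(nBins) - 1) * tr
  new("FirDesign", G = G, columns = cols, tr = tr, nBins = nBins,
      binTimes = binTimes)
}

#' Build a nuisance regressor matrix
#'
#' Columns ordered as the variance is removed: rigid-body motion parameters
#' first, then polynomial drift terms, then the intercept.
#'
#' @param motion scans x 6 matrix of rigid-body parameters (or NULL).
#' @param nScans number of scans.
#' @param driftOrder polynomial drift degree (0 = none).
#' @param intercept include an intercept column (default TRUE).
#' @return numeric matrix with labeled columns.
#' @export
buildNuisance <- function(motion = NULL, nScans, driftOrder = 2L,
                          intercept = TRUE) {
  parts <- list()
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    stopifnot(nrow(motion) == nScans)
    colnames(motion) <- colnames(motion) %||%
      paste0("motion", seq_len(ncol(motion)))
    parts$motion <- motion
  }
  if (driftOrder > 0L) {
    P <- poly(seq_len(nScans), degree = driftOrder, simple = TRUE)
    colnames(P) <- paste0("drift", seq_len(driftOrder))
    parts$drift <- P
  }
  if (intercept)
    parts$intercept <- matrix(1, nScans, 1,
                              dimnames = list(NULL, "intercept"))
  do.call(cbind, parts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Remove nuisance variance by least squares
#'
#' Returns `Y` minus its least-squares projection onto the column space of
#' `N`; residuals are orthogonal to every nuisance column. Rank-deficient
#' `N` is handled by pivoting with a warning, which is equivalent to
#' projecting onto the span actually present.
#'
#' @param Y scans x voxels matrix.
#' @param N scans x m nuisance matrix.
#' @return matrix of residuals, same shape as `Y`.
#' @export
residualize <- function(Y, N) {
  Y <- as.matrix(Y); N <- as.matrix(N)
  if (nrow(Y) != nrow(N)) stop("Y and N must have the same number of rows")
  fit <- stats::lm.fit(N, Y)
  if (fit$rank < ncol(N))
    warning("nuisance matrix is rank deficient; projecting onto its span")
  res <- as.matrix(fit$residuals)
  dimnames(res) <- dimnames(Y)
  res
}

#' Stack subjects for the shared-network decomposition
#'
#' Each subject's residualized voxel time series is z-scored (per voxel,
#' mean 0 / SD 1, so no subject's variance scale dominates the SVD) and the
#' subjects are stacked along the scan axis. The FIR designs are placed in
#' a block-diagonal sparse matrix with subject-specific columns, so the
#' downstream predictor weights are subject- and condition-specific while
#' the spatial components are shared.
#'
#' @param perSubject named list; each element a list with `Y` (scans x
#'   voxels residualized matrix) and `fir` (a [FirDesign-class]).
#' @param zscore z-score each subject's voxel columns (default TRUE).
#' @return a [StackedDesign-class].
#' @export
stackSubjects <- function(perSubject, zscore = TRUE) {
  stopifnot(length(perSubject) >= 1L)
  ids <- names(perSubject) %||% sprintf("sub-%02d", seq_along(perSubject))
  nVox <- ncol(perSubject[[1]]$Y)
  first <- perSubject[[1]]$fir
  Zs <- vector("list", length(perSubject))
  Gs <- vector("list", length(perSubject))
  cols <- vector("list", length(perSubject))
  rows <- vector("list", length(perSubject))
  for (i in seq_along(perSubject)) {
    Y <- as.matrix(perSubject[[i]]$Y)
    if (ncol(Y) != nVox) stop("subjects differ in voxel count")
    fir <- perSubject[[i]]$fir
    if (zscore) {
      mu <- colMeans(Y)
      sdv <- sqrt(colMeans(Y^2) - mu^2) * sqrt(nrow(Y) / (nrow(Y) - 1))
      sdv[sdv < .Machine$double.eps^0.5] <- 1  # constant voxels stay 0
      Y <- sweep(sweep(Y, 2, mu), 2, sdv, "/")
    }
    Zs[[i]] <- Y
    Gs[[i]] <- designMatrix(fir)
    cc <- designColumns(fir)
    cc$subject <- ids[i]
    cols[[i]] <- cc[, c("subject", "condition", "bin")]
    rows[[i]] <- data.frame(subject = ids[i], scan = seq_len(nrow(Y)),
                            stringsAsFactors = FALSE)
  }
  new("StackedDesign",
      Z = do.call(rbind, Zs),
      G = methods::as(Matrix::bdiag(Gs), "CsparseMatrix"),
      columns = do.call(rbind, cols),
      rows = do.call(rbind, rows),
      tr = first@tr, nBins = first@nBins, binTimes = first@binTimes)
}
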