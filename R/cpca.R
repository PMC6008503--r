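# Constrained PCA of the task-related BOLD variance. The stacked signal Z
# is regressed onto the block-diagonal FIR design G; the predicted matrix
# GC isolates the variance the task can explain, and its SVD yields
# functional networks shared across subjects. Loadings are singular-value
# scaled (V D) and varimax-rotated; scores are counter-rotated so the
# reconstruction scores %*% t(loadings) is rotation-invariant.

economySvd <- function(M) {
  # full spectrum via the smaller Gram matrix; numerically adequate here
  # because downstream use is rank truncation well above noise floor
  if (ncol(M) <= nrow(M)) {
    e <- eigen(crossprod(M), symmetric = TRUE)
    d <- sqrt(pmax(e$values, 0))
    V <- e$vectors
    pos <- d > max(d[1], .Machine$double.eps) * 1e-7
    U <- sweep(M %*% V[, pos, drop = FALSE], 2, d[pos], "/")
    list(d = d, U = U, V = V, nPos = sum(pos))
  } else {
    e <- eigen(tcrossprod(M), symmetric = TRUE)
    d <- sqrt(pmax(e$values, 0))
    pos <- d > max(d[1], .Machine$double.eps) * 1e-7
    U <- e$vectors[, pos, drop = FALSE]
    V <- sweep(crossprod(M, U), 2, d[pos], "/")
    list(d = d, U = U, V = V, nPos = sum(pos))
  }
}

#' Fit a constrained PCA model
#'
#' Solves the multivariate regression `G C ~ Z` by (sparse) normal
#' equations, forms the predicted task-related matrix `GC`, takes its SVD
#' `GC = U D V'`, retains `nComponents`, scales loadings as `V D`, applies
#' varimax rotation (optional), counter-rotates the scores, and orients
#' each component so its largest-magnitude loading is positive. Rotated
#' components are ordered by decreasing explained task-related variance.
#'
#' @param stacked a [StackedDesign-class] (or list with `Z`, `G`, `columns`,
#'   `rows`, `binTimes`).
#' @param nComponents components to retain.
#' @param rotate apply varimax rotation (default TRUE; with 1 component no
#'   rotation is possible).
#' @param kaiser use Kaiser row normalization in varimax (default TRUE).
#' @return a [CpcaModel-class].
#' @export
fitCpca <- function(stacked, nComponents, rotate = TRUE, kaiser = TRUE) {
  Z <- stacked@Z
  G <- stacked@G
  nComponents <- as.integer(nComponents)
  GtG <- as.matrix(Matrix::crossprod(G))
  GtZ <- as.matrix(Matrix::crossprod(G, Z))
  ev <- eigen(GtG, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < max(ev) * 1e-10) {
    warning(sprintf(
      "design Gram matrix is ill-conditioned (cond ~ %.2e); using pseudo-inverse",
      max(ev) / max(min(ev), .Machine$double.eps)))
    e <- eigen(GtG, symmetric = TRUE)
    keep <- e$values > max(e$values) * 1e-10
    Cmat <- e$vectors[, keep, drop = FALSE] %*%
      (t(e$vectors[, keep, drop = FALSE]) %*% GtZ / e$values[keep])
  } else {
    Cmat <- solve(GtG, GtZ)
  }
  P <- as.matrix(G %*% Cmat)
  s <- economySvd(P)
  if (nComponents > s$nPos)
    stop("nComponents exceeds the rank of the predicted matrix")
  k <- nComponents
  d <- s$d
  V <- s$V[, seq_len(k), drop = FALSE]
  U <- s$U[, seq_len(k), drop = FALSE]
  dk <- d[seq_len(k)]
  rot <- diag(k)
  if (rotate && k >= 2L) {
    # rotation determined on the orthonormal spatial basis V, so the
    # criterion sees component patterns at equal scale and is not frozen
    # by the dominant component
    nz <- rowSums(V^2) > .Machine$double.eps  # all-zero voxels break Kaiser
    vr <- stats::varimax(V[nz, , drop = FALSE], normalize = kaiser,
                         eps = 1e-10)
    rot <- vr$rotmat
  }
  # rotated loadings (V R) Delta and scores U D R Delta^-1 with
  # Delta_k = ||D R e_k||: scores %*% t(loadings) = U D V' exactly for any
  # orthogonal R, rotated column sum-of-squares Delta_k^2 partitions the
  # retained task-related variance, and with R = I this reduces to the
  # unrotated loadings V D, scores U
  delta <- sqrt(colSums((dk * rot)^2))
  load <- sweep(V %*% rot, 2, delta, "*")
  scores <- sweep(U %*% (dk * rot), 2, delta, "/")
  # sign convention: largest-|loading| voxel positive per component
  flips <- vapply(seq_len(k), function(j) {
    v <- load[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  load <- sweep(load, 2, flips, "*")
  scores <- sweep(scores, 2, flips, "*")
  rot <- sweep(rot, 2, flips, "*")
  # order rotated components by explained task-related variance
  ssTotal <- sum(d^2)
  ssComp <- colSums(load^2)
  ord <- order(ssComp, decreasing = TRUE)
  load <- load[, ord, drop = FALSE]
  scores <- scores[, ord, drop = FALSE]
  rot <- rot[, ord, drop = FALSE]
  colnames(load) <- colnames(scores) <- paste0("comp", seq_len(k))
  new("CpcaModel",
      regWeights = Cmat, loadings = load, scores = scores, rotation = rot,
      singularValues = d[seq_len(s$nPos)],
      varianceFractions = list(
        unrotated = d[seq_len(k)]^2 / ssTotal,
        rotated = ssComp[ord] / ssTotal),
      nComponents = k,
      columns = stacked@columns, rows = stacked@rows,
      binTimes = stacked@binTimes)
}

#' Varimax rotation of a loading matrix
#'
#' Maximizes the varimax criterion (the sum over components of the variance
#' of squared, optionally row-normalized, loadings) over orthogonal
#' rotations. Thin wrapper around [stats::varimax()] returning rotated
#' loadings and the rotation matrix; total squared loading mass is
#' preserved.
#'
#' @param loadings voxels x components matrix, components >= 2.
#' @param kaiser Kaiser row normalization (default TRUE).
#' @param eps convergence tolerance on the criterion gain.
#' @return list with `loadings` (rotated) and `rotation`.
#' @export
varimaxRotate <- function(loadings, kaiser = TRUE, eps = 1e-10) {
  if (ncol(loadings) < 2L) stop("varimax needs at least 2 components")
  vr <- stats::varimax(loadings, normalize = kaiser, eps = eps)
  list(loadings = loadings %*% vr$rotmat, rotation = vr$rotmat)
}

#' Varimax criterion value
#'
#' @param L loadings matrix.
#' @param kaiser row-normalize before evaluating (default TRUE).
#' @return the raw varimax criterion: sum over columns of the variance of
#'   squared loadings.
#' @export
varimaxCriterion <- function(L, kaiser = TRUE) {
  if (kaiser) {
    h <- sqrt(rowSums(L^2))
    h[h == 0] <- 1
    L <- L / h
  }
  sq <- L^2
  sum(apply(sq, 2, function(x) mean(x^2) - mean(x)^2))
}

#' Predictor weights tracing estimated HDR shapes
#'
#' Regresses each component's scores onto the stacked FIR design columns.
#' Because the design is block-diagonal by subject with condition- and
#' bin-specific columns, the weights index as (subject, condition,
#' poststimulus bin, component) and trace each subject's estimated HDR
#' shape for each condition on each network. Scores are the counter-rotated
#' ones, so the weights are consistent with the rotated loadings.
#'
#' @param model a [CpcaModel-class].
#' @param stacked the [StackedDesign-class] the model was fit to.
#' @return data.frame: subject, condition, bin, binTime, component, weight.
#' @export
predictorWeights <- function(model, stacked) {
  G <- stacked@G
  S <- model@scores
  if (nrow(S) != nrow(G))
    stop("model scores and design rows do not match")
  W <- as.matrix(Matrix::solve(Matrix::crossprod(G),
                               Matrix::crossprod(G, S)))
  cols <- stacked@columns
  k <- ncol(W)
  out <- cols[rep(seq_len(nrow(cols)), k), ]
  out$binTime <- stacked@binTimes[out$bin]
  out$component <- rep(colnames(model@loadings), each = nrow(cols))
  out$weight <- as.vector(W)
  rownames(out) <- NULL
  out
}

#' Per-subject expression maps of a component
#'
#' One voxel map per subject per component — the subject-level image fed
#' to within-network permutation inference. The default
#' (`"betaProjection"`) contracts the subject's FIR regression coefficient
#' maps (the subject's rows of `C`) with the component's cohort-mean
#' predictor-weight profile (unit-normalized), i.e. the subject's beta map
#' projected onto the network's HDR shape: voxel-specific, linear in the
#' subject's planted amplitude, and far less noisy than per-subject score
#' regression. The alternative (`"scoreRegression"`) regresses the
#' subject's stacked data rows onto the subject's rows of the component
#' scores.
#'
#' @param model a [CpcaModel-class].
#' @param stacked the [StackedDesign-class] the model was fit to.
#' @param component component name or index.
#' @param method `"betaProjection"` (default) or `"scoreRegression"`.
#' @return subjects x voxels matrix with subject IDs as row names.
#' @export
subjectComponentMaps <- function(model, stacked, component = 1L,
                                 method = c("betaProjection",
                                            "scoreRegression")) {
  method <- match.arg(method)
  j <- if (is.character(component))
    match(component, colnames(model@loadings)) else as.integer(component)
  if (is.na(j) || j < 1L || j > model@nComponents)
    stop("unknown component")
  ids <- unique(stacked@rows$subject)
  out <- matrix(NA_real_, length(ids), ncol(stacked@Z),
                dimnames = list(ids, NULL))
  if (method == "betaProjection") {
    pw <- predictorWeights(model, stacked)
    pw <- pw[pw$component == colnames(model@loadings)[j], ]
    prof <- stats::aggregate(weight ~ condition + bin, data = pw, FUN = mean)
    for (id in ids) {
      cc <- model@columns$subject == id
      cols <- model@columns[cc, ]
      w <- prof$weight[match(paste(cols$condition, cols$bin),
                             paste(prof$condition, prof$bin))]
      w <- w / sqrt(sum(w^2))
      out[id, ] <- as.vector(crossprod(model@regWeights[cc, , drop = FALSE],
                                       w))
    }
  } else {
    for (id in ids) {
      r <- stacked@rows$subject == id
      s <- model@scores[r, , drop = FALSE]
      y <- stacked@Z[r, , drop = FALSE]
      # multivariate regression on all k scores; take this component's row
      coefs <- solve(crossprod(s), crossprod(s, y))
      out[id, ] <- coefs[j, ]
    }
  }
  out
}

#' Scree summary and advisory component count
#'
#' Variance fractions per singular value plus an elbow suggestion. The
#' predominant components sit above the flat bulk of the spectrum, so the
#' suggestion is the largest index `k` (within the first `maxK`) at which
#' the spectrum still drops noticeably — successive ratio
#' `d_k / d_(k+1) >= minGain` — i.e. the last visible drop before the
#' tail flattens. An effectively zero `d_(k+1)` marks the rank edge and
#' counts as an infinite drop. When no ratio reaches `minGain` the
#' spectrum has no elbow and the suggestion falls back to `fallback`. The
#' suggestion is advisory; the retained count is an analysis choice.
#'
#' @param x a [CpcaModel-class] or numeric vector of singular values.
#' @param fallback suggested count when no elbow is found (default 1).
#' @param maxK largest index considered (default `min(20, length - 1)`;
#'   practitioners read a scree plot's leading edge, and the bulk's own
#'   lower edge would otherwise produce spurious drops).
#' @param minGain minimal successive ratio counting as a drop
#'   (default 1.15).
#' @return list with `values`, `fractions`, `suggested`, `rule`.
#' @export
scree <- function(x, fallback = 1L, maxK = NULL, minGain = 1.15) {
  d <- if (is(x, "CpcaModel")) x@singularValues else as.numeric(x)
  if (!length(d)) stop("no singular values")
  d <- sort(d, decreasing = TRUE)
  fr <- d^2 / sum(d^2)
  if (length(d) == 1L)
    return(list(values = d, fractions = fr, suggested = 1L,
                rule = "single value"))
  if (is.null(maxK)) maxK <- min(20L, length(d) - 1L)
  maxK <- min(maxK, length(d) - 1L)
  zero <- d < d[1] * 1e-10
  ratios <- vapply(seq_len(maxK), function(k) {
    if (zero[k]) return(NA_real_)       # inside the numerical null space
    if (zero[k + 1]) return(Inf)        # rank edge
    d[k] / d[k + 1]
  }, numeric(1))
  drops <- which(!is.na(ratios) & ratios >= minGain)
  if (!length(drops)) {
    sug <- as.integer(fallback); rule <- "no elbow; fallback"
  } else {
    sug <- max(drops); rule <- "last successive drop >= minGain"
  }
  list(values = d, fractions = fr, suggested = as.integer(sug), rule = rule)
}
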