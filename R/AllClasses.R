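#' @import methods
#' @importFrom stats rnorm runif sd cor prcomp p.adjust pf pt t.test aov
#'   cor.test setNames quantile var poly
#' @importFrom utils combn head
#' @useDynLib fmricpca, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Network template for the synthetic-data generator
#'
#' A network template couples a spatial map (values in \[-1, 1\] on the voxel
#' grid) to a planted hemodynamic response expressed directly as FIR bin
#' amplitudes, one curve per task condition, plus a per-group amplitude
#' multiplier. Planting the ground truth in FIR-bin space (rather than as a
#' canonical HRF) means recovery tests compare the estimator's native
#' quantities with like quantities.
#'
#' @slot name character label for the network.
#' @slot map 3D numeric array, spatial loading pattern in \[-1, 1\].
#' @slot hdr numeric matrix, `nBins x nConditions`, planted FIR bin
#'   amplitudes (signal units) with condition labels as column names.
#' @slot groupMultiplier named numeric, amplitude multiplier per group.
#' @export
setClass("NetworkTemplate",
  representation(
    name = "character",
    map = "array",
    hdr = "matrix",
    groupMultiplier = "numeric"
  )
)

setValidity("NetworkTemplate", function(object) {
  msg <- character()
  if (length(dim(object@map)) != 3L)
    msg <- c(msg, "map must be a 3D array")
  if (max(abs(object@map), na.rm = TRUE) > 1 + 1e-12)
    msg <- c(msg, "map values must lie in [-1, 1]")
  if (is.null(colnames(object@hdr)))
    msg <- c(msg, "hdr must have condition labels as column names")
  if (!all(is.finite(object@groupMultiplier)))
    msg <- c(msg, "group multipliers must be finite")
  if (length(msg)) msg else TRUE
})

#' Simulation configuration for the synthetic grip-task cohort
#'
#' Captures the study design the generator emulates: two groups performing
#' visually cued isometric hand grips at two force levels, with FIR-bin
#' ground-truth networks, AR(1) + polynomial-drift noise, and a planted
#' coupling between sensorimotor network amplitude and the behavioral
#' composite.
#'
#' @slot nControls,nPatients group sizes.
#' @slot volumeShape integer(3), voxel grid.
#' @slot tr repetition time (s).
#' @slot nTrials grips per subject.
#' @slot gripDuration grip hold duration (s).
#' @slot isiRange numeric(2), uniform inter-stimulus interval bounds (s).
#' @slot forceLevels ordered condition labels.
#' @slot nBins FIR bins modeled per trial.
#' @slot networks list of [NetworkTemplate-class] ground-truth networks.
#' @slot noiseAr1 AR(1) coefficient of voxel noise, in \[0, 1).
#' @slot noiseSd marginal SD of voxel noise (signal units).
#' @slot driftOrder polynomial drift degree (0 = none).
#' @slot driftSd SD of each drift coefficient (signal units).
#' @slot subjectAmpSd SD of the multiplicative between-subject amplitude
#'   jitter around the group mean.
#' @slot behaviorCoupling slope linking the planted sensorimotor amplitude
#'   (z-scored across patients) to the behavioral measures.
#' @slot behaviorNoiseSd SD of per-measure behavioral noise (z units).
#' @slot lesionProb probability that a patient carries a lesion mask.
#' @slot seed integer master seed.
#' @export
setClass("GripSimConfig",
  representation(
    nControls = "integer",
    nPatients = "integer",
    volumeShape = "integer",
    tr = "numeric",
    nTrials = "integer",
    gripDuration = "numeric",
    isiRange = "numeric",
    forceLevels = "character",
    nBins = "integer",
    networks = "list",
    noiseAr1 = "numeric",
    noiseSd = "numeric",
    driftOrder = "integer",
    driftSd = "numeric",
    subjectAmpSd = "numeric",
    behaviorCoupling = "numeric",
    behaviorNoiseSd = "numeric",
    lesionProb = "numeric",
    seed = "integer"
  )
)

setValidity("GripSimConfig", function(object) {
  msg <- character()
  if (length(object@volumeShape) != 3L || any(object@volumeShape < 4L))
    msg <- c(msg, "volumeShape must be 3 integers, each >= 4")
  if (object@isiRange[1] > object@isiRange[2])
    msg <- c(msg, "isiRange min must be <= max")
  if (object@nTrials < 1L)
    msg <- c(msg, "nTrials must be positive")
  if (object@noiseAr1 < 0 || object@noiseAr1 >= 1)
    msg <- c(msg, "noiseAr1 must be in [0, 1)")
  if (length(object@forceLevels) < 1L)
    msg <- c(msg, "at least one force level required")
  for (nw in object@networks) {
    if (!identical(dim(nw@map), object@volumeShape))
      msg <- c(msg, sprintf("network '%s' map shape differs from volumeShape",
                            nw@name))
    if (nrow(nw@hdr) != object@nBins)
      msg <- c(msg, sprintf("network '%s' hdr must have nBins rows", nw@name))
    if (!all(object@forceLevels %in% colnames(nw@hdr)))
      msg <- c(msg, sprintf("network '%s' hdr lacks some force levels",
                            nw@name))
    if (!all(is.finite(nw@groupMultiplier)))
      msg <- c(msg, sprintf("network '%s' has non-finite group multipliers",
                            nw@name))
  }
  if (length(msg)) msg else TRUE
})

#' Synthetic multi-subject dataset
#'
#' Holds the per-subject simulated data (4D BOLD array, event table, motion
#' parameters, behavioral scores, optional lesion mask) together with the
#' lossless ground truth needed by recovery tests: the planted spatial maps,
#' the planted group-by-condition HDR curves, each subject's realized
#' network amplitudes, and the planted behavior coupling.
#'
#' @slot subjects named list; each element has `bold` (4D array), `events`
#'   (data.frame onset/duration/condition), `motion` (scans x 6 matrix),
#'   `group`, `behavior` (named numeric(3)), `lesion` (3D 0/1 array or NULL),
#'   and `truth` (per-subject planted amplitudes per network).
#' @slot config the [GripSimConfig-class] that generated the cohort.
#' @slot affine 4x4 voxel-to-world transform shared by all volumes.
#' @slot groundTruth list with `maps`, `hdr` (group x condition curves per
#'   network), and `behaviorCoupling`.
#' @export
setClass("SyntheticCohort",
  representation(
    subjects = "list",
    config = "GripSimConfig",
    affine = "matrix",
    groundTruth = "list"
  )
)

#' FIR design matrix for one subject
#'
#' Indicator ("stick") design: for each trial of condition `c` whose onset
#' falls at (or before) the start of scan `s` — the first full scan at or
#' after stimulus onset — a 1 is placed at rows `s .. s + nBins - 1` of the
#' columns for condition `c`, bins `1 .. nBins`. Overlapping trials sum.
#'
#' @slot G scans x (conditions x bins) numeric matrix.
#' @slot columns data.frame with one row per column of `G`: condition, bin.
#' @slot tr repetition time (s).
#' @slot nBins number of poststimulus bins.
#' @slot binTimes numeric, time label per bin (s); by default scan midpoints
#'   `(bin - 0.5) * tr`.
#' @export
setClass("FirDesign",
  representation(
    G = "matrix",
    columns = "data.frame",
    tr = "numeric",
    nBins = "integer",
    binTimes = "numeric"
  )
)

setValidity("FirDesign", function(object) {
  msg <- character()
  if (nrow(object@columns) != ncol(object@G))
    msg <- c(msg, "columns must describe every column of G")
  if (length(object@binTimes) != object@nBins)
    msg <- c(msg, "binTimes length must equal nBins")
  if (length(msg)) msg else TRUE
})

#' Stacked multi-subject data and block-diagonal FIR design
#'
#' Subjects are stacked along the scan axis; the task design becomes
#' block-diagonal with subject-specific FIR columns, so downstream predictor
#' weights are subject- and condition-specific while the spatial components
#' are shared across all subjects.
#'
#' @slot Z total-scans x voxels numeric matrix (residualized, per-subject
#'   z-scored time series).
#' @slot G sparse block-diagonal design (`Matrix::dgCMatrix`).
#' @slot columns data.frame per design column: subject, condition, bin.
#' @slot rows data.frame per row: subject, scan.
#' @slot tr repetition time (s).
#' @slot nBins FIR bins.
#' @slot binTimes bin time labels (s).
#' @export
setClass("StackedDesign",
  representation(
    Z = "matrix",
    G = "Matrix",
    columns = "data.frame",
    rows = "data.frame",
    tr = "numeric",
    nBins = "integer",
    binTimes = "numeric"
  )
)

setValidity("StackedDesign", function(object) {
  msg <- character()
  if (nrow(object@Z) != nrow(object@G))
    msg <- c(msg, "Z and G must have the same number of rows")
  if (nrow(object@columns) != ncol(object@G))
    msg <- c(msg, "columns must describe every column of G")
  if (length(msg)) msg else TRUE
})

#' Fitted constrained-PCA model
#'
#' The task-related portion of the stacked signal, `GC` with
#' `C = (G'G)^{-1} G' Z`, is decomposed as `GC = U D V'`. Retained loadings
#' are singular-value scaled (`V D`), varimax-rotated, and sign-oriented so
#' each component's largest-magnitude loading is positive; scores are
#' counter-rotated (`U R`) so that `scores %*% t(loadings)` reproduces the
#' rank-k approximation of `GC` regardless of rotation.
#'
#' @slot regWeights design-columns x voxels regression weights (C).
#' @slot loadings voxels x components rotated, scaled loadings.
#' @slot scores rows x components counter-rotated component scores.
#' @slot rotation components x components orthogonal rotation matrix.
#' @slot singularValues all singular values of `GC` (not just retained).
#' @slot varianceFractions list with `unrotated` (d_k^2 / sum d^2 for the
#'   retained components) and `rotated` (sum of squared rotated loadings per
#'   component over total task-related sum of squares).
#' @slot nComponents retained component count.
#' @slot columns design-column bookkeeping (subject, condition, bin).
#' @slot rows row bookkeeping (subject, scan).
#' @slot binTimes bin time labels (s).
#' @export
setClass("CpcaModel",
  representation(
    regWeights = "matrix",
    loadings = "matrix",
    scores = "matrix",
    rotation = "matrix",
    singularValues = "numeric",
    varianceFractions = "list",
    nComponents = "integer",
    columns = "data.frame",
    rows = "data.frame",
    binTimes = "numeric"
  )
)

setValidity("CpcaModel", function(object) {
  msg <- character()
  k <- object@nComponents
  if (ncol(object@loadings) != k || ncol(object@scores) != k)
    msg <- c(msg, "loadings/scores must have nComponents columns")
  rr <- crossprod(object@rotation)
  if (max(abs(rr - diag(nrow(rr)))) > 1e-6)
    msg <- c(msg, "rotation must be orthogonal")
  if (length(msg)) msg else TRUE
})

#' Binary voxel mask with spatial metadata
#'
#' Masks live on the image's native 0-based voxel grid; world coordinates
#' are reached only through the affine. Used for lesions, in-brain masks,
#' and thresholded ("extreme k%") network masks.
#'
#' @slot data logical 3D array of voxel membership.
#' @slot affine 4x4 voxel-to-world transform.
#' @slot space free-text space label (e.g. "study").
#' @export
setClass("VolumeMask",
  representation(
    data = "array",
    affine = "matrix",
    space = "character"
  )
)

setValidity("VolumeMask", function(object) {
  msg <- character()
  if (!is.logical(object@data) || length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a logical 3D array")
  if (!identical(dim(object@affine), c(4L, 4L)) ||
      abs(det(object@affine)) < 1e-12)
    msg <- c(msg, "affine must be an invertible 4x4 matrix")
  if (length(msg)) msg else TRUE
})
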