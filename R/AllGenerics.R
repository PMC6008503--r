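#' @name accessors
#' @title Accessors for fmricpca classes
#' @description Slot access goes through these accessors; slots are
#'   implementation detail.
#' @param object an fmricpca S4 object.
#' @param x an fmricpca S4 object.
NULL

#' @rdname accessors
#' @export
setGeneric("maskArray", function(object) standardGeneric("maskArray"))

#' @rdname accessors
#' @export
setGeneric("maskAffine", function(object) standardGeneric("maskAffine"))

#' @rdname accessors
#' @export
setGeneric("designMatrix", function(object) standardGeneric("designMatrix"))

#' @rdname accessors
#' @export
setGeneric("designColumns", function(object) standardGeneric("designColumns"))

#' @rdname accessors
#' @export
setGeneric("binTimes", function(object) standardGeneric("binTimes"))

#' @rdname accessors
#' @export
setGeneric("regressionWeights",
           function(object) standardGeneric("regressionWeights"))

#' @rdname accessors
#' @export
setGeneric("componentLoadings",
           function(object) standardGeneric("componentLoadings"))

#' @rdname accessors
#' @export
setGeneric("componentScores",
           function(object) standardGeneric("componentScores"))

#' @rdname accessors
#' @export
setGeneric("singularValues",
           function(object) standardGeneric("singularValues"))

#' @rdname accessors
#' @export
setGeneric("varianceFractions",
           function(object) standardGeneric("varianceFractions"))

#' @rdname accessors
#' @export
setGeneric("nComponents", function(object) standardGeneric("nComponents"))

#' @rdname accessors
#' @export
setGeneric("cohortSubjects", function(object) standardGeneric("cohortSubjects"))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setGeneric("simConfigOf", function(object) standardGeneric("simConfigOf"))

setMethod("maskArray", "VolumeMask", function(object) object@data)
setMethod("maskAffine", "VolumeMask", function(object) object@affine)

setMethod("designMatrix", "FirDesign", function(object) object@G)
setMethod("designMatrix", "StackedDesign", function(object) object@G)
setMethod("designColumns", "FirDesign", function(object) object@columns)
setMethod("designColumns", "StackedDesign", function(object) object@columns)
setMethod("designColumns", "CpcaModel", function(object) object@columns)
setMethod("binTimes", "FirDesign", function(object) object@binTimes)
setMethod("binTimes", "StackedDesign", function(object) object@binTimes)
setMethod("binTimes", "CpcaModel", function(object) object@binTimes)

setMethod("regressionWeights", "CpcaModel", function(object) object@regWeights)
setMethod("componentLoadings", "CpcaModel", function(object) object@loadings)
setMethod("componentScores", "CpcaModel", function(object) object@scores)
setMethod("singularValues", "CpcaModel", function(object) object@singularValues)
setMethod("varianceFractions", "CpcaModel",
          function(object) object@varianceFractions)
setMethod("nComponents", "CpcaModel", function(object) object@nComponents)

setMethod("cohortSubjects", "SyntheticCohort", function(object) object@subjects)
setMethod("groundTruth", "SyntheticCohort", function(object) object@groundTruth)
setMethod("simConfigOf", "SyntheticCohort", function(object) object@config)

setMethod("show", "GripSimConfig", function(object) {
  cat("GripSimConfig:", object@nControls, "controls +", object@nPatients,
      "patients\n")
  cat("  volume", paste(object@volumeShape, collapse = "x"),
      "| TR", object@tr, "s |", object@nTrials, "trials of",
      object@gripDuration, "s | ISI",
      paste(object@isiRange, collapse = "-"), "s\n")
  cat("  conditions:", paste(object@forceLevels, collapse = ", "),
      "| FIR bins:", object@nBins, "\n")
  cat("  networks:", paste(vapply(object@networks, slot, "", "name"),
                           collapse = ", "), "\n")
  cat("  noise: AR1", object@noiseAr1, "sd", object@noiseSd,
      "| drift order", object@driftOrder, "| seed", object@seed, "\n")
})

setMethod("show", "SyntheticCohort", function(object) {
  grp <- vapply(object@subjects, `[[`, "", "group")
  cat("SyntheticCohort:", length(object@subjects), "subjects (",
      sum(grp == "control"), "controls,", sum(grp == "patient"),
      "patients )\n")
  d <- dim(object@subjects[[1]]$bold)
  cat("  per-subject BOLD:", paste(d, collapse = " x "), "\n")
})

setMethod("show", "FirDesign", function(object) {
  cat("FirDesign:", nrow(object@G), "scans x", ncol(object@G),
      "columns (", length(unique(object@columns$condition)), "conditions x",
      object@nBins, "bins ), TR", object@tr, "s\n")
})

setMethod("show", "StackedDesign", function(object) {
  cat("StackedDesign:", nrow(object@Z), "stacked scans x", ncol(object@Z),
      "voxels;", length(unique(object@columns$subject)),
      "subject design blocks,", ncol(object@G), "columns\n")
})

setMethod("show", "CpcaModel", function(object) {
  cat("CpcaModel:", object@nComponents, "components over",
      nrow(object@loadings), "voxels\n")
  vf <- object@varianceFractions$rotated
  cat("  task-related variance per rotated component (%):",
      paste(sprintf("%.1f", 100 * vf), collapse = ", "), "\n")
})

setMethod("show", "VolumeMask", function(object) {
  cat("VolumeMask:", paste(dim(object@data), collapse = "x"), "voxels,",
      sum(object@data), "in mask, space:", object@space, "\n")
})
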