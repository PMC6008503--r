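# End-to-end orchestration: simulate -> design -> CPCA -> predictor-weight
# ANOVAs -> within-network permutation inference -> lesion overlap ->
# behavioral composite and brain-behavior correlation, with a
# reproducibility manifest. All randomness funnels through the config seed.

#' Pipeline configuration
#'
#' @param simConfig a [GripSimConfig-class]; its seed is overridden by
#'   `seed` so one value controls the whole run.
#' @param nComponents components to retain (default 4).
#' @param displayFraction dominant-loading fraction for display masks
#'   (default 0.05).
#' @param analysisFraction extreme-loading fraction for within-network
#'   inference masks (default 0.10).
#' @param maskSign sign rule for the network masks (default "absolute").
#' @param nPermutations permutations for group inference (default 5000).
#' @param tfce a [tfceParams()].
#' @param alpha significance level for cluster summaries (default 0.05).
#' @param binAnchor FIR bin time labeling, `"midpoint"` or `"onset"`.
#' @param seed master seed.
#' @return list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(simConfig = gripSimConfig(),
                           nComponents = 4L,
                           displayFraction = 0.05,
                           analysisFraction = 0.10,
                           maskSign = "absolute",
                           nPermutations = 5000L,
                           tfce = tfceParams(),
                           alpha = 0.05,
                           binAnchor = "midpoint",
                           seed = 1L) {
  stopifnot(displayFraction > 0, displayFraction < 1,
            analysisFraction > 0, analysisFraction < 1,
            alpha > 0, alpha < 1)
  simConfig@seed <- as.integer(seed)
  structure(list(simConfig = simConfig,
                 nComponents = as.integer(nComponents),
                 displayFraction = displayFraction,
                 analysisFraction = analysisFraction,
                 maskSign = maskSign,
                 nPermutations = as.integer(nPermutations),
                 tfce = tfce, alpha = alpha, binAnchor = binAnchor,
                 seed = as.integer(seed)),
            class = "pipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys map to [pipelineConfig()] arguments; a `sim` block maps
#' to scalar [gripSimConfig()] arguments; a `tfce` block to [tfceParams()].
#'
#' @param path YAML file.
#' @return a `pipelineConfig` list.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- do.call(gripSimConfig, y$sim %||% list())
  tf <- do.call(tfceParams, y$tfce %||% list())
  args <- y[setdiff(names(y), c("sim", "tfce"))]
  do.call(pipelineConfig, c(list(simConfig = sim, tfce = tf), args))
}

#' Match recovered components to ground-truth network maps
#'
#' Greedy assignment by maximum absolute spatial correlation between each
#' planted map and the rotated loading maps.
#'
#' @param loadings voxels x components matrix.
#' @param maps named list of planted 3D maps (vectorized to the same voxel
#'   order).
#' @return data.frame: network, component, correlation (signed, at the
#'   matched pairing).
#' @export
matchComponents <- function(loadings, maps) {
  k <- ncol(loadings)
  rmat <- sapply(maps, function(m) {
    as.vector(cor(loadings, as.vector(m)))
  })  # k x nMaps
  rmat <- matrix(rmat, nrow = k, dimnames = list(colnames(loadings),
                                                 names(maps)))
  out <- data.frame(network = character(), component = character(),
                    correlation = numeric(), stringsAsFactors = FALSE)
  free <- abs(rmat)
  for (i in seq_len(min(k, length(maps)))) {
    w <- which(free == max(free), arr.ind = TRUE)[1, ]
    out <- rbind(out, data.frame(
      network = colnames(rmat)[w[2]],
      component = rownames(rmat)[w[1]],
      correlation = rmat[w[1], w[2]], stringsAsFactors = FALSE))
    free[w[1], ] <- -Inf
    free[, w[2]] <- -Inf
  }
  out[order(out$network), ]
}

#' Run the full analysis pipeline
#'
#' Simulates (or accepts) a cohort, removes nuisance variance (motion
#' first, then drift and intercept), stacks subjects, fits the constrained
#' PCA, derives predictor weights and their mixed ANOVAs with FDR-corrected
#' simple effects, thresholds network masks, runs within-network
#' permutation/TFCE group inference, computes the lesion overlap map and
#' its Dice similarity to each network mask, scores the behavioral
#' composite, and correlates significant-cluster activity with it. When
#' `outputDir` is given, maps (NIfTI), tables (TSV) and a manifest with
#' checksums are written.
#'
#' @param config a [pipelineConfig()].
#' @param outputDir optional output directory.
#' @param cohort optional pre-built [SyntheticCohort-class] (default:
#'   simulated from `config`).
#' @return list with all stage results (cohort, stacked, model, scree,
#'   weights, anova, simpleEffects, masks, permTests, clusters, overlap,
#'   dice, behavior, correlation, manifest).
#' @export
runPipeline <- function(config = pipelineConfig(), outputDir = NULL,
                        cohort = NULL) {
  cfg <- config$simConfig
  if (is.null(cohort)) cohort <- simulateCohort(cfg)
  subs <- cohortSubjects(cohort)
  shape <- cfg@volumeShape
  nVox <- prod(shape)

  perSubject <- lapply(subs, function(s) {
    nScans <- dim(s$bold)[4]
    Y <- t(matrix(s$bold, nVox, nScans))  # scans x voxels
    N <- buildNuisance(s$motion, nScans, driftOrder = cfg@driftOrder)
    fir <- buildFirDesign(s$events, nScans = nScans, tr = cfg@tr,
                          nBins = cfg@nBins, conditions = cfg@forceLevels,
                          binAnchor = config$binAnchor)
    list(Y = residualize(Y, N), fir = fir)
  })
  stacked <- stackSubjects(perSubject)
  model <- fitCpca(stacked, config$nComponents)
  sc <- scree(model, fallback = config$nComponents)
  weights <- predictorWeights(model, stacked)
  groupOf <- vapply(subs, `[[`, "", "group")
  weights$group <- groupOf[weights$subject]

  comps <- colnames(componentLoadings(model))
  anovas <- list(); simple <- list()
  for (cp in comps) {
    w <- weights[weights$component == cp, ]
    w$force <- w$condition
    anovas[[cp]] <- mixedAnova(w)
    simple[[cp]] <- list(force = simpleEffects(w, "force"),
                         group = simpleEffects(w, "group"))
  }

  aff <- cohort@affine
  L <- componentLoadings(model)
  analysisMasks <- list(); displayMasks <- list()
  for (j in seq_along(comps)) {
    lm3 <- array(L[, j], shape)
    analysisMasks[[comps[j]]] <-
      topFractionMask(lm3, config$analysisFraction, config$maskSign,
                      affine = aff)
    displayMasks[[comps[j]]] <-
      topFractionMask(lm3, config$displayFraction, config$maskSign,
                      affine = aff)
  }

  isPat <- groupOf == "patient"
  permTests <- list(); clusters <- list()
  for (j in seq_along(comps)) {
    maps <- subjectComponentMaps(model, stacked, j)
    pt <- permutationTest(
      maps[!isPat, , drop = FALSE], maps[isPat, , drop = FALSE],
      volumeDim = shape, mask = maskArray(analysisMasks[[j]]),
      scheme = permScheme(config$nPermutations, config$seed + j),
      params = config$tfce)
    permTests[[comps[j]]] <- pt
    clusters[[comps[j]]] <- list(
      controlsGtPatients = clusterSummary(pt$pPos, config$alpha),
      patientsGtControls = clusterSummary(pt$pNeg, config$alpha))
  }

  lesions <- Filter(Negate(is.null), lapply(subs, `[[`, "lesion"))
  overlap <- NULL; diceTable <- NULL
  if (length(lesions)) {
    overlap <- lesionOverlap(lapply(lesions, function(x)
      volumeMask(x > 0, aff)))
    overlapMask <- volumeMask(overlap > 0, aff)
    diceTable <- data.frame(
      component = comps,
      dice = vapply(comps, function(cp)
        dice(analysisMasks[[cp]], overlapMask), numeric(1)))
  }

  beh <- cohortBehavior(cohort)
  patBeh <- beh[beh$group == "patient", c("gripStrength", "nhpt", "bbt")]
  behavior <- NULL; correlation <- NULL
  if (nrow(patBeh) >= 3L) {
    behavior <- compositeScore(patBeh)
    # activity scalar: mean subject expression over the significant
    # motor-network cluster (largest surviving cluster, either tail);
    # falls back to the full analysis mask when nothing survives
    mt <- matchComponents(L, groundTruth(cohort)$maps)
    motorComp <- mt$component[mt$network == "motor"]
    if (!length(motorComp)) motorComp <- comps[1]
    cl <- clusters[[motorComp]]
    tab <- rbind(cl$controlsGtPatients, cl$patientsGtControls)
    clMask <- maskArray(analysisMasks[[motorComp]])
    usedCluster <- FALSE
    if (nrow(tab)) {
      pt <- permTests[[motorComp]]
      best <- tab[which.max(tab$size), ]
      pm <- if (best$peakP %in% pt$pPos[!is.na(pt$pPos)]) pt$pPos else
        pt$pNeg
      lab <- array(.labelComponents(
        as.vector(!is.na(pm) & pm <= config$alpha),
        as.integer(shape), 26L), shape)
      clMask <- lab == lab[best$x, best$y, best$z]
      usedCluster <- TRUE
    }
    maps <- subjectComponentMaps(model, stacked, motorComp)
    activity <- rowMeans(maps[, as.vector(clMask), drop = FALSE])
    patIds <- names(subs)[isPat]
    if (length(patIds) >= 4L)
      correlation <- c(
        brainBehaviorCorrelation(activity[patIds], behavior$scores),
        list(component = motorComp, usedCluster = usedCluster,
             clusterSize = sum(clMask)))
  }

  result <- list(cohort = cohort, stacked = stacked, model = model,
                 scree = sc, weights = weights, anova = anovas,
                 simpleEffects = simple, analysisMasks = analysisMasks,
                 displayMasks = displayMasks, permTests = permTests,
                 clusters = clusters, overlap = overlap, dice = diceTable,
                 behavior = behavior, correlation = correlation,
                 config = config)
  if (!is.null(outputDir))
    result$manifest <- writePipelineOutputs(result, outputDir)
  result
}

writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

writePipelineOutputs <- function(result, outputDir) {
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  cfg <- result$config
  shape <- cfg$simConfig@volumeShape
  aff <- result$cohort@affine
  files <- character()
  L <- componentLoadings(result$model)
  for (cp in colnames(L)) {
    f <- file.path(outputDir, paste0("loadings_", cp, ".nii"))
    writeVolume(array(L[, cp], shape), f, affine = aff)
    files <- c(files, f)
  }
  files <- c(files,
             writeTsv(result$weights,
                      file.path(outputDir, "predictor_weights.tsv")))
  vf <- varianceFractions(result$model)
  files <- c(files, writeTsv(
    data.frame(component = colnames(L),
               taskVariancePct = 100 * vf$rotated),
    file.path(outputDir, "variance_table.tsv")))
  for (cp in names(result$anova)) {
    files <- c(files,
               writeTsv(result$anova[[cp]],
                        file.path(outputDir, paste0("anova_", cp, ".tsv"))),
               writeTsv(result$simpleEffects[[cp]]$force,
                        file.path(outputDir,
                                  paste0("simple_force_", cp, ".tsv"))))
  }
  for (cp in names(result$permTests)) {
    f <- file.path(outputDir, paste0("pmap_controlsGtPatients_", cp, ".nii"))
    writeVolume(array(result$permTests[[cp]]$pPos, shape), f, affine = aff)
    files <- c(files, f)
  }
  if (!is.null(result$overlap)) {
    f <- file.path(outputDir, "lesion_overlap.nii")
    writeVolume(result$overlap, f, affine = aff)
    files <- c(files, f,
               writeTsv(result$dice, file.path(outputDir, "dice.tsv")))
  }
  if (!is.null(result$behavior)) {
    beh <- data.frame(score = result$behavior$scores)
    files <- c(files, writeTsv(beh, file.path(outputDir, "composite.tsv")))
  }
  if (!is.null(result$correlation)) {
    co <- result$correlation
    files <- c(files, writeTsv(
      data.frame(component = co$component, r = co$r, p = co$p, n = co$n,
                 usedCluster = co$usedCluster, clusterSize = co$clusterSize),
      file.path(outputDir, "brain_behavior.tsv")))
  }
  manifest <- list(
    seed = cfg$seed,
    rVersion = as.character(getRversion()),
    package = as.character(utils::packageVersion("fmricpca")),
    created = format(Sys.time(), tz = "UTC"),
    files = lapply(files, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f))))
  )
  mf <- file.path(outputDir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE)
  manifest
}
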