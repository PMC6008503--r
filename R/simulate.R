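# Synthetic grip-task cohort generator. The defaults emulate the study
# design the analysis targets: 41 subjects (24 controls, 17 stroke-like
# patients), 50 visually cued isometric grips at 10% or 30% MVC in
# randomized order, 3 s holds, 3-7 s uniform ISI, TR 3.25 s, 6 FIR bins.

withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic per-subject seed derived from the master seed, kept < 2^31
subjectSeedFor <- function(masterSeed, i) {
  as.integer((as.numeric(masterSeed) * 7919 + i * 104729) %% 2147483629)
}

gaussianBlob <- function(shape, center, sigma) {
  cx <- (shape - 1) * center
  d2 <- outer(outer((seq_len(shape[1]) - 1 - cx[1])^2,
                    (seq_len(shape[2]) - 1 - cx[2])^2, "+"),
              (seq_len(shape[3]) - 1 - cx[3])^2, "+")
  exp(-d2 / (2 * sigma^2))
}

#' Construct a ground-truth network template
#'
#' @param name network label.
#' @param map 3D spatial map in \[-1, 1\].
#' @param hdr `nBins x nConditions` matrix of planted FIR bin amplitudes,
#'   columns named by condition.
#' @param groupMultiplier named numeric amplitude multiplier per group.
#' @return a [NetworkTemplate-class].
#' @export
networkTemplate <- function(name, map, hdr,
                            groupMultiplier = c(control = 1, patient = 1)) {
  new("NetworkTemplate", name = name, map = map, hdr = as.matrix(hdr),
      groupMultiplier = groupMultiplier)
}

#' Default ground-truth networks for the grip-task simulation
#'
#' Four spatially separated networks mirror the functional systems an
#' isometric grip task engages: a bilateral dorsal-attention system, an
#' early visual system, a left-lateralized sensorimotor system with a
#' force-dependent response and a poststimulus undershoot, and a midline
#' default-mode system that deactivates. Group structure is planted on the
#' last two: patients express the motor network at 0.6 of the control
#' amplitude and the DMN deactivation at 0.5.
#'
#' @param volumeShape integer(3) voxel grid.
#' @param nBins FIR bins (default 6).
#' @param forceLevels condition labels, low force first.
#' @param patientMotorMult,patientDmnMult patient amplitude multipliers for
#'   the motor and default-mode networks.
#' @return list of [NetworkTemplate-class] objects.
#' @export
defaultNetworks <- function(volumeShape, nBins = 6L,
                            forceLevels = c("force10", "force30"),
                            patientMotorMult = 0.6,
                            patientDmnMult = 0.5) {
  stopifnot(nBins >= 4L, length(forceLevels) == 2L)
  s <- as.integer(volumeShape)
  # blob width ~ a fifth of the grid: each network covers a few percent of
  # the volume, the typical extent of a task network relative to the brain
  sig <- max(min(s) / 5, 1)
  pad <- function(v) c(v, numeric(max(nBins - 6L, 0)))[seq_len(nBins)]
  curve2 <- function(base, lowScale) {
    m <- cbind(base * lowScale, base)
    colnames(m) <- forceLevels
    m
  }
  # spatially separated placements; HDR latencies staggered (visual
  # earliest, attention next, motor peaking later with an undershoot, DMN
  # deactivating slowest) as event-related grip responses show
  danMap <- pmin(gaussianBlob(s, c(0.18, 0.25, 0.65), sig) +
                 gaussianBlob(s, c(0.82, 0.25, 0.65), sig), 1)
  visMap <- pmin(gaussianBlob(s, c(0.50, 0.08, 0.30), sig), 1)
  motMap <- pmin(gaussianBlob(s, c(0.22, 0.62, 0.85), sig * 0.9) +
                 0.5 * gaussianBlob(s, c(0.40, 0.85, 0.80), sig * 0.7), 1)
  dmnMap <- pmin(gaussianBlob(s, c(0.62, 0.88, 0.40), sig * 0.9) +
                 0.7 * gaussianBlob(s, c(0.55, 0.55, 0.15), sig * 0.8), 1)
  list(
    networkTemplate("dorsalAttention", danMap,
                    curve2(pad(c(0.3, 1.0, 0.7, 0.2, 0.0, -0.1)), 0.85)),
    networkTemplate("visual", visMap,
                    curve2(pad(c(1.0, 0.6, 0.1, 0.0, 0.0, 0.0)), 0.9)),
    networkTemplate("motor", motMap,
                    curve2(pad(c(0.1, 0.6, 1.0, 0.5, -0.2, -0.3)), 0.7),
                    c(control = 1, patient = patientMotorMult)),
    networkTemplate("dmn", dmnMap,
                    curve2(pad(c(0.1, -0.1, -0.6, -1.0, -0.6, -0.1)), 1),
                    c(control = 1, patient = patientDmnMult))
  )
}

#' Simulation configuration
#'
#' Defaults are the emulated study conditions; see [defaultNetworks()] for
#' the planted networks. Noise is AR(1) with marginal SD `noiseSd` plus a
#' polynomial drift, the minimal structure that makes nuisance regression
#' and variance partitioning non-trivial.
#'
#' @param nControls,nPatients group sizes (defaults 24 and 17).
#' @param volumeShape voxel grid (default 12 x 12 x 12, desk scale).
#' @param tr repetition time in seconds (default 3.25).
#' @param nTrials grips per subject (default 50).
#' @param gripDuration grip hold in seconds (default 3).
#' @param isiRange inter-stimulus interval bounds in seconds (default 3-7).
#' @param forceLevels condition labels.
#' @param nBins FIR bins (default 6).
#' @param networks list of [NetworkTemplate-class]; default
#'   [defaultNetworks()] on `volumeShape`.
#' @param noiseAr1 AR(1) coefficient (default 0.3).
#' @param noiseSd marginal noise SD in signal units (default 0.5, i.e.
#'   planted peak responses of about twice the voxel noise SD, the regime
#'   in which the decomposition is well-posed at desk-scale volumes).
#' @param driftOrder polynomial drift degree (default 2).
#' @param driftSd per-coefficient drift SD (default 0.5).
#' @param subjectAmpSd between-subject amplitude jitter SD (default 0.2).
#' @param behaviorCoupling slope linking motor-network amplitude to the
#'   behavioral measures (default 0.8).
#' @param behaviorNoiseSd per-measure behavioral noise SD (default 0.4).
#' @param lesionProb probability a patient carries a lesion (default 1).
#' @param seed master seed.
#' @return a [GripSimConfig-class].
#' @export
gripSimConfig <- function(nControls = 24L, nPatients = 17L,
                          volumeShape = c(12L, 12L, 12L),
                          tr = 3.25, nTrials = 50L, gripDuration = 3,
                          isiRange = c(3, 7),
                          forceLevels = c("force10", "force30"),
                          nBins = 6L, networks = NULL,
                          noiseAr1 = 0.3, noiseSd = 0.5, driftOrder = 2L,
                          driftSd = 0.5, subjectAmpSd = 0.2,
                          behaviorCoupling = 0.8, behaviorNoiseSd = 0.4,
                          lesionProb = 1, seed = 1L) {
  volumeShape <- as.integer(volumeShape)
  if (is.null(networks))
    networks <- defaultNetworks(volumeShape, nBins = as.integer(nBins),
                                forceLevels = forceLevels)
  new("GripSimConfig",
      nControls = as.integer(nControls), nPatients = as.integer(nPatients),
      volumeShape = volumeShape, tr = tr, nTrials = as.integer(nTrials),
      gripDuration = gripDuration, isiRange = as.numeric(isiRange),
      forceLevels = forceLevels, nBins = as.integer(nBins),
      networks = networks, noiseAr1 = noiseAr1, noiseSd = noiseSd,
      driftOrder = as.integer(driftOrder), driftSd = driftSd,
      subjectAmpSd = subjectAmpSd, behaviorCoupling = behaviorCoupling,
      behaviorNoiseSd = behaviorNoiseSd, lesionProb = lesionProb,
      seed = as.integer(seed))
}

#' Simulate one subject's event schedule
#'
#' Conditions are a random permutation of a balanced label vector; ISIs are
#' drawn uniformly from `isiRange`, so consecutive onsets are separated by
#' `gripDuration + ISI`.
#'
#' @param cfg a [GripSimConfig-class].
#' @param subjectSeed integer seed; the schedule is deterministic given it.
#' @return data.frame with columns onset (s), duration (s), condition.
#' @export
simulateEvents <- function(cfg, subjectSeed) {
  nLev <- length(cfg@forceLevels)
  if (cfg@nTrials < nLev)
    stop("nTrials must be at least the number of force levels")
  withSeed(subjectSeed, {
    labels <- rep(cfg@forceLevels, length.out = cfg@nTrials)
    labels <- sample(labels)
    isi <- runif(cfg@nTrials, cfg@isiRange[1], cfg@isiRange[2])
    onsets <- 6 + cumsum(c(0, (cfg@gripDuration + isi)[-cfg@nTrials]))
    data.frame(onset = onsets, duration = cfg@gripDuration,
               condition = labels, stringsAsFactors = FALSE)
  })
}

arNoise <- function(nScans, nVox, ar, sdMarginal) {
  e <- matrix(rnorm(nScans * nVox), nScans, nVox)
  if (ar > 0) {
    innovSd <- sqrt(1 - ar^2)
    for (t in 2:nScans) e[t, ] <- ar * e[t - 1, ] + innovSd * e[t, ]
  }
  sdMarginal * e
}

scanCount <- function(cfg, events) {
  last <- max(events$onset) + cfg@gripDuration
  as.integer(ceiling(last / cfg@tr) + cfg@nBins + 2L)
}

lesionBlob <- function(shape) {
  center <- c(runif(1, 0.2, 0.4), runif(1, 0.35, 0.7), runif(1, 0.45, 0.8))
  radius <- runif(1, 0.10, 0.18) * min(shape)
  b <- gaussianBlob(shape, center, radius)
  out <- (b > exp(-0.5)) * 1L
  if (sum(out) == 0L) {  # tiny radius on a coarse grid: keep the core voxel
    i <- pmin(pmax(round((shape - 1) * center) + 1, 1), shape)
    out[i[1], i[2], i[3]] <- 1L
  }
  out
}

#' Simulate one subject
#'
#' Forward model: the BOLD volume is the sum over planted networks of
#' (spatial map) x (FIR event train convolved with the network's planted
#' bin amplitudes, scaled by the group multiplier and a subject-specific
#' amplitude factor), plus polynomial drift and AR(1) noise. Motion
#' parameters are smooth random walks; the behavioral triple couples to
#' the subject's realized sensorimotor amplitude through
#' `behaviorCoupling`.
#'
#' @param cfg a [GripSimConfig-class].
#' @param group `"control"` or `"patient"`.
#' @param subjectSeed integer seed.
#' @return list with `bold`, `events`, `motion`, `group`, `behavior`,
#'   `lesion` (or NULL), and `truth` (per-network realized amplitudes and
#'   the latent behavior factor).
#' @export
simulateSubject <- function(cfg, group = c("control", "patient"),
                            subjectSeed = 1L) {
  group <- match.arg(group)
  for (nw in cfg@networks)
    if (!identical(dim(nw@map), cfg@volumeShape))
      stop("network template shape does not match volumeShape")
  events <- simulateEvents(cfg, subjectSeed)
  nScans <- scanCount(cfg, events)
  nVox <- prod(cfg@volumeShape)
  fir <- buildFirDesign(events, nScans = nScans, tr = cfg@tr,
                        nBins = cfg@nBins, conditions = cfg@forceLevels)
  G <- designMatrix(fir)
  cols <- designColumns(fir)

  withSeed(subjectSeed + 1L, {
    y <- matrix(0, nScans, nVox)
    amps <- numeric(length(cfg@networks))
    names(amps) <- vapply(cfg@networks, slot, "", "name")
    jitters <- amps
    for (i in seq_along(cfg@networks)) {
      nw <- cfg@networks[[i]]
      mult <- nw@groupMultiplier[[group]]
      jitters[i] <- max(1 + rnorm(1, 0, cfg@subjectAmpSd), 0.05)
      amps[i] <- mult * jitters[i]
      # amplitude per design column in the (condition, bin) order of G
      beta <- amps[i] * nw@hdr[cbind(cols$bin, match(cols$condition,
                                                    colnames(nw@hdr)))]
      y <- y + as.vector(G %*% beta) %o% as.vector(nw@map)
    }
    if (cfg@driftOrder > 0L) {
      P <- poly(seq_len(nScans), degree = cfg@driftOrder, simple = TRUE)
      coefs <- matrix(rnorm(cfg@driftOrder * nVox, 0,
                            cfg@driftSd * sqrt(nScans)),
                      cfg@driftOrder, nVox)
      y <- y + P %*% coefs
    }
    if (cfg@noiseSd > 0)
      y <- y + arNoise(nScans, nVox, cfg@noiseAr1, cfg@noiseSd)

    motion <- apply(matrix(rnorm(nScans * 6, 0, 0.02), nScans, 6), 2, cumsum)
    colnames(motion) <- c("tx", "ty", "tz", "rx", "ry", "rz")

    motorIdx <- which(names(amps) == "motor")
    if (!length(motorIdx) && length(amps)) motorIdx <- 1L
    latent <- if (length(motorIdx))
      cfg@behaviorCoupling *
        (jitters[motorIdx] - 1) / max(cfg@subjectAmpSd, 1e-8)
    else 0
    base <- if (group == "patient") 50 else 100
    slope <- if (group == "patient") 20 else 5
    behavior <- pmax(base + slope * (latent +
      rnorm(3, 0, cfg@behaviorNoiseSd)), 0)
    names(behavior) <- c("gripStrength", "nhpt", "bbt")

    lesion <- NULL
    if (group == "patient" && runif(1) < cfg@lesionProb)
      lesion <- lesionBlob(cfg@volumeShape)

    list(bold = array(t(y), c(cfg@volumeShape, nScans)),
         events = events, motion = motion, group = group,
         behavior = behavior, lesion = lesion,
         truth = list(amplitudes = amps, jitters = jitters,
                      latentBehavior = latent))
  })
}

#' Simulate a full cohort
#'
#' Controls then patients, each with a distinct deterministic seed derived
#' from the master seed; identical configs yield bit-identical cohorts.
#'
#' @param cfg a [GripSimConfig-class].
#' @return a [SyntheticCohort-class].
#' @export
simulateCohort <- function(cfg) {
  validObject(cfg)
  groups <- c(rep("control", cfg@nControls), rep("patient", cfg@nPatients))
  ids <- sprintf("sub-%02d", seq_along(groups))
  subjects <- vector("list", length(groups))
  names(subjects) <- ids
  for (i in seq_along(groups))
    subjects[[i]] <- simulateSubject(cfg, groups[i],
                                     subjectSeedFor(cfg@seed, i))
  gtHdr <- lapply(cfg@networks, function(nw) {
    out <- list()
    for (g in names(nw@groupMultiplier))
      out[[g]] <- nw@hdr * nw@groupMultiplier[[g]]
    out
  })
  names(gtHdr) <- vapply(cfg@networks, slot, "", "name")
  maps <- lapply(cfg@networks, slot, "map")
  names(maps) <- names(gtHdr)
  new("SyntheticCohort", subjects = subjects, config = cfg,
      affine = diag(c(2, 2, 2, 1)),
      groundTruth = list(maps = maps, hdr = gtHdr,
                         behaviorCoupling = cfg@behaviorCoupling))
}

#' Behavioral table of a cohort
#'
#' @param cohort a [SyntheticCohort-class].
#' @return data.frame: subject, group, gripStrength, nhpt, bbt (each as a
#'   percentage of the unaffected hand).
#' @export
cohortBehavior <- function(cohort) {
  subs <- cohortSubjects(cohort)
  do.call(rbind, lapply(names(subs), function(id) {
    b <- subs[[id]]$behavior
    data.frame(subject = id, group = subs[[id]]$group,
               gripStrength = b[["gripStrength"]], nhpt = b[["nhpt"]],
               bbt = b[["bbt"]], stringsAsFactors = FALSE)
  }))
}

#' Write a cohort to disk in standard formats
#'
#' Per subject: a 4D NIfTI BOLD volume, a BIDS-style 3-column tab-separated
#' event file (onset, duration, trial_type), a plain-text 6-column motion
#' file, and (patients) a binary lesion NIfTI; plus one cohort-level
#' tab-separated table of group labels and behavioral scores.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  aff <- cohort@affine
  files <- character()
  subs <- cohortSubjects(cohort)
  for (id in names(subs)) {
    s <- subs[[id]]
    bold <- file.path(dir, paste0(id, "_bold.nii"))
    writeVolume(s$bold, bold, affine = aff)
    ev <- file.path(dir, paste0(id, "_events.tsv"))
    evd <- data.frame(onset = s$events$onset, duration = s$events$duration,
                      trial_type = s$events$condition)
    utils::write.table(evd, ev, sep = "\t", quote = FALSE, row.names = FALSE)
    mo <- file.path(dir, paste0(id, "_motion.txt"))
    utils::write.table(s$motion, mo, sep = " ", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    files <- c(files, bold, ev, mo)
    if (!is.null(s$lesion)) {
      lf <- file.path(dir, paste0(id, "_lesion.nii"))
      writeVolume(s$lesion, lf, affine = aff)
      files <- c(files, lf)
    }
  }
  ct <- file.path(dir, "participants.tsv")
  utils::write.table(cohortBehavior(cohort), ct, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(files, ct))
}
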