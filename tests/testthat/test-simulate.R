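test_that("event schedules honor trial count, balance, ISI bounds and seed", {
  cfg <- gripSimConfig(nTrials = 50L)
  ev <- simulateEvents(cfg, 101L)
  expect_equal(nrow(ev), 50L)
  expect_setequal(unique(ev$condition), cfg@forceLevels)
  expect_equal(sum(ev$condition == "force10"), 25L)
  # consecutive onsets separated by duration (3 s) + ISI in [3, 7]
  gaps <- diff(ev$onset)
  expect_true(all(gaps >= 6 - 1e-9 & gaps <= 10 + 1e-9))
  expect_true(all(diff(ev$onset) > 0))
  expect_identical(ev, simulateEvents(cfg, 101L))
  expect_false(identical(ev$onset, simulateEvents(cfg, 102L)$onset))
})

test_that("degenerate schedules: single trial works, too few trials error", {
  cfg1 <- gripSimConfig(nTrials = 1L, forceLevels = "force30",
                        networks = list())
  ev <- simulateEvents(cfg1, 5L)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$onset, 6)
  cfg2 <- gripSimConfig(nTrials = 1L)  # two force levels
  expect_error(simulateEvents(cfg2, 5L), "force levels")
})

test_that("noiseless, drift-free simulation is exactly the forward model", {
  shape <- c(8L, 8L, 8L)
  base <- defaultNetworks(shape)[[3]]
  nets <- list(networkTemplate("motor", base@map,
                               base@hdr[, "force30", drop = FALSE]))
  cfg <- gripSimConfig(nControls = 1L, nPatients = 0L, volumeShape = shape,
                       nTrials = 1L, forceLevels = "force30",
                       networks = nets, noiseSd = 0, driftOrder = 0L,
                       subjectAmpSd = 0)
  s <- simulateSubject(cfg, "control", 21L)
  nScans <- dim(s$bold)[4]
  # independent stamping oracle: place planted bin amplitudes at the first
  # full scans after onset, scaled by the map value
  ev <- s$events
  hdr <- nets[[1]]@hdr[, ev$condition[1]]
  onsetScan <- ceiling(ev$onset[1] / cfg@tr) + 1
  expected <- numeric(nScans)
  expected[onsetScan + seq_len(6) - 1] <- hdr
  v <- which(as.vector(nets[[1]]@map) == max(nets[[1]]@map))[1]
  vox <- arrayInd(v, shape)
  trace <- s$bold[vox[1], vox[2], vox[3], ]
  expect_equal(trace, expected * max(nets[[1]]@map), tolerance = 1e-12)
  # every voxel follows the same model: max abs deviation 0
  Y <- t(matrix(s$bold, prod(shape), nScans))
  expect_equal(max(abs(Y - outer(expected, as.vector(nets[[1]]@map)))), 0)
})

test_that("group amplitude multipliers scale the evoked response", {
  shape <- c(6L, 6L, 6L)
  nets <- defaultNetworks(shape, patientMotorMult = 0.5)[3]
  cfg <- gripSimConfig(nControls = 0L, nPatients = 0L, volumeShape = shape,
                       nTrials = 8L, networks = nets, noiseSd = 0.05,
                       driftOrder = 0L, subjectAmpSd = 0.15)
  v <- which.max(as.vector(nets[[1]]@map))
  vox <- arrayInd(v, shape)
  evoked <- function(group, seed) {
    s <- simulateSubject(cfg, group, seed)
    tr <- s$bold[vox[1], vox[2], vox[3], ]
    max(tr) - min(tr)  # peak-to-trough of the planted response
  }
  nPer <- 25L
  ec <- vapply(seq_len(nPer), function(i) evoked("control", 1000L + i),
               numeric(1))
  ep <- vapply(seq_len(nPer), function(i) evoked("patient", 2000L + i),
               numeric(1))
  expect_equal(mean(ec) / mean(ep), 2, tolerance = 0.15)
})

test_that("evoked variance scales with the squared multiplier", {
  shape <- c(6L, 6L, 6L)
  nets <- defaultNetworks(shape, patientMotorMult = 0.5)[3]
  cfg <- gripSimConfig(nControls = 0L, nPatients = 0L, volumeShape = shape,
                       nTrials = 8L, networks = nets, noiseSd = 0,
                       driftOrder = 0L, subjectAmpSd = 0.1)
  v <- which.max(as.vector(nets[[1]]@map))
  vox <- arrayInd(v, shape)
  voxVar <- function(group, seed) {
    s <- simulateSubject(cfg, group, seed)
    var(s$bold[vox[1], vox[2], vox[3], ])
  }
  vc <- vapply(1:50, function(i) voxVar("control", 3000L + i), numeric(1))
  vp <- vapply(1:50, function(i) voxVar("patient", 3000L + i), numeric(1))
  expect_equal(mean(vc) / mean(vp), 4, tolerance = 0.10)
})

test_that("planted behavior coupling yields strong amplitude-composite correlation", {
  cors <- vapply(1:20, function(seed) {
    cfg <- gripSimConfig(nControls = 0L, nPatients = 17L,
                         volumeShape = c(6L, 6L, 6L), nTrials = 4L,
                         networks = defaultNetworks(c(6L, 6L, 6L))[3],
                         noiseSd = 0, driftOrder = 0L, seed = seed)
    co <- simulateCohort(cfg)
    subs <- cohortSubjects(co)
    amp <- vapply(subs, function(s) s$truth$jitters[[1]], numeric(1))
    meas <- t(vapply(subs, function(s) s$behavior, numeric(3)))
    cs <- compositeScore(meas)
    cor(amp, cs$scores)
  }, numeric(1))
  expect_true(all(cors > 0.8))
})

test_that("cohorts have the configured size, seeding, groups and lesions", {
  cfg <- tinyCfg(nControls = 24L, nPatients = 17L, shape = c(6L, 6L, 6L),
                 nTrials = 4L, seed = 5L)
  co <- simulateCohort(cfg)
  subs <- cohortSubjects(co)
  expect_length(subs, 41L)
  grp <- vapply(subs, `[[`, "", "group")
  expect_equal(sum(grp == "control"), 24L)
  expect_equal(sum(grp == "patient"), 17L)
  # controls carry no lesion; every patient does (lesionProb = 1)
  lesions <- lapply(subs, `[[`, "lesion")
  expect_true(all(vapply(subs[grp == "control"],
                         function(s) is.null(s$lesion), logical(1))))
  patLesions <- lesions[grp == "patient"]
  expect_true(all(!vapply(patLesions, is.null, logical(1))))
  # lesions overlap the sensorimotor hemisphere: all mass in low-x half
  for (L in patLesions) {
    com <- which(L > 0, arr.ind = TRUE)
    expect_lt(mean(com[, 1]), dim(L)[1] / 2 + 1)
  }
  # bit-identical rerun under the same config
  co2 <- simulateCohort(cfg)
  expect_identical(subs[["sub-01"]]$bold, cohortSubjects(co2)[["sub-01"]]$bold)
  expect_identical(cohortBehavior(co), cohortBehavior(co2))
})

test_that("patients-free cohort has no lesion masks", {
  cfg <- tinyCfg(nControls = 3L, nPatients = 0L, shape = c(6L, 6L, 6L),
                 nTrials = 4L)
  co <- simulateCohort(cfg)
  expect_true(all(vapply(cohortSubjects(co), function(s) is.null(s$lesion),
                         logical(1))))
})

test_that("cohorts round-trip to standard on-disk formats", {
  cfg <- tinyCfg(nControls = 1L, nPatients = 1L, shape = c(6L, 6L, 6L),
                 nTrials = 4L)
  co <- simulateCohort(cfg)
  dir <- withr::local_tempdir()
  files <- writeCohort(co, dir)
  expect_true(file.exists(file.path(dir, "participants.tsv")))
  bold <- readVolume(file.path(dir, "sub-01_bold.nii"))
  expect_equal(dim(bold), dim(cohortSubjects(co)[["sub-01"]]$bold))
  expect_equal(max(abs(bold - cohortSubjects(co)[["sub-01"]]$bold)), 0,
               tolerance = 1e-6)
  ev <- read.delim(file.path(dir, "sub-02_events.tsv"))
  expect_named(ev, c("onset", "duration", "trial_type"))
  expect_equal(nrow(ev), 4L)
  expect_true(file.exists(file.path(dir, "sub-02_lesion.nii")))
})
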