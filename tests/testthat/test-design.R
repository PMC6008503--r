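test_that("FIR poststimulus window covers nBins scans of the TR", {
  ev <- data.frame(onset = 10, duration = 3, condition = "grip")
  fir <- buildFirDesign(ev, nScans = 20, tr = 3.25, nBins = 6)
  expect_equal(fir@nBins * fir@tr, 19.5)
  expect_equal(binTimes(fir), (1:6 - 0.5) * 3.25)
  firOn <- buildFirDesign(ev, 20, 3.25, 6, binAnchor = "onset")
  expect_equal(binTimes(firOn), (1:6 - 1) * 3.25)
})

test_that("empty event tables give an all-zero design", {
  ev <- data.frame(onset = numeric(), duration = numeric(),
                   condition = character())
  fir <- buildFirDesign(ev, nScans = 12, tr = 2, nBins = 4,
                        conditions = c("a", "b"))
  expect_equal(dim(designMatrix(fir)), c(12L, 8L))
  expect_true(all(designMatrix(fir) == 0))
})

test_that("FIR stick placement matches a per-trial stamping oracle", {
  tr <- 2.5
  ev <- data.frame(onset = c(1.2, 6.0, 11.3), duration = 2,
                   condition = c("a", "a", "b"))
  nScans <- 12L
  nBins <- 3L
  fir <- buildFirDesign(ev, nScans, tr, nBins, conditions = c("a", "b"))
  G <- designMatrix(fir)
  # oracle: explicit loop placing 1 at the first full scan at/after onset
  Gexp <- matrix(0, nScans, 2 * nBins)
  for (i in seq_len(nrow(ev))) {
    s0 <- 1L
    while ((s0 - 1) * tr < ev$onset[i] - 1e-9) s0 <- s0 + 1L
    ci <- match(ev$condition[i], c("a", "b"))
    for (b in seq_len(nBins)) {
      r <- s0 + b - 1L
      if (r <= nScans) {
        j <- (ci - 1L) * nBins + b
        Gexp[r, j] <- Gexp[r, j] + 1
      }
    }
  }
  expect_equal(unname(G), Gexp)
  # trials mapping to the same onset scan sum their indicators
  ev2 <- data.frame(onset = c(0.5, 1.5), duration = 1, condition = "a")
  G2 <- designMatrix(buildFirDesign(ev2, 8, 2.5, 3, conditions = "a"))
  expect_equal(max(G2), 2)
})

test_that("column sums equal the per-condition trial count when untruncated", {
  cfg <- gripSimConfig(nTrials = 20L, networks = list())
  ev <- simulateEvents(cfg, 33L)
  nScans <- ceiling((max(ev$onset) + 3) / cfg@tr) + 10
  fir <- buildFirDesign(ev, nScans, cfg@tr, 6, conditions = cfg@forceLevels)
  cs <- colSums(designMatrix(fir))
  cols <- designColumns(fir)
  for (cc in cfg@forceLevels) {
    expect_equal(unname(cs[cols$condition == cc]),
                 rep(sum(ev$condition == cc), 6))
  }
})

test_that("trials running off the scan axis are truncated with a warning", {
  ev <- data.frame(onset = c(2, 18), duration = 2, condition = "a")
  expect_warning(
    fir <- buildFirDesign(ev, nScans = 10, tr = 2, nBins = 4,
                          conditions = "a"),
    "truncated")
  # trial 1 fully placed (4 sticks); trial 2 fits only its first bin
  expect_equal(sum(designMatrix(fir)), 5)
})

test_that("residualize matches the normal-equations projection oracle", {
  set.seed(41)
  Y <- matrix(rnorm(20 * 5), 20)
  N <- cbind(1, matrix(rnorm(20 * 2), 20))
  R <- residualize(Y, N)
  Rexp <- Y - N %*% solve(t(N) %*% N, t(N) %*% Y)
  expect_equal(R, Rexp, tolerance = 1e-10)
  expect_lt(max(abs(crossprod(N, R))), 1e-10)
  # idempotence
  expect_equal(residualize(R, N), R, tolerance = 1e-12)
})

test_that("residualize closed forms: demeaning and perfect fit", {
  set.seed(42)
  Y <- matrix(rnorm(30 * 4), 30)
  ones <- matrix(1, 30, 1)
  expect_equal(residualize(Y, ones), sweep(Y, 2, colMeans(Y)),
               tolerance = 1e-12)
  N <- matrix(rnorm(30 * 3), 30)
  expect_lt(max(abs(residualize(N %*% matrix(rnorm(12), 3), N))), 1e-10)
  # rank-deficient nuisance: warned, treated as its span
  Ndup <- cbind(N, N[, 1])
  expect_warning(R <- residualize(Y, Ndup), "rank deficient")
  expect_equal(R, residualize(Y, N), tolerance = 1e-10)
})

test_that("stacking builds a block-diagonal design with z-scored data", {
  cfg <- tinyCfg(nControls = 3L, nPatients = 0L, shape = c(5L, 5L, 4L),
                 nTrials = 4L)
  co <- simulateCohort(cfg)
  per <- lapply(cohortSubjects(co), subjectYfir, cfg = cfg)
  st <- stackSubjects(per)
  n1 <- nrow(per[[1]]$Y)
  expect_equal(nrow(st@Z), sum(vapply(per, function(p) nrow(p$Y), 1L)))
  G <- as.matrix(designMatrix(st))
  q <- ncol(designMatrix(per[[1]]$fir))
  # zeros off the subject blocks
  expect_true(all(G[seq_len(n1), -(seq_len(q))] == 0))
  expect_true(all(G[-(seq_len(n1)), seq_len(q)] == 0))
  # G'G is block diagonal and matches the dense product oracle
  GtG <- as.matrix(Matrix::crossprod(designMatrix(st)))
  expect_equal(GtG, t(G) %*% G, tolerance = 1e-12)
  expect_true(all(GtG[seq_len(q), -(seq_len(q))] == 0))
  # per-subject voxel columns are z-scored
  z1 <- st@Z[seq_len(n1), ]
  expect_lt(max(abs(colMeans(z1))), 1e-10)
  sds <- apply(z1, 2, sd)
  expect_equal(unname(sds[sds > 1e-8]), rep(1, sum(sds > 1e-8)),
               tolerance = 1e-10)
  # single subject: Z equals its (z-scored) data, G unchanged
  st1 <- stackSubjects(per[1], zscore = FALSE)
  expect_equal(st1@Z, per[[1]]$Y)
  expect_equal(unname(as.matrix(designMatrix(st1))),
               unname(designMatrix(per[[1]]$fir)))
})
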