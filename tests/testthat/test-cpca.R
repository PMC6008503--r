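# build a StackedDesign directly from matrices (test scaffolding)
stackedFrom <- function(Z, G, nBins = 1L, tr = 1) {
  q <- ncol(G)
  new("StackedDesign", Z = Z, G = methods::as(Matrix::Matrix(G, sparse = TRUE),
                                              "CsparseMatrix"),
      columns = data.frame(subject = "s1", condition = "c",
                           bin = rep(seq_len(nBins), length.out = q)),
      rows = data.frame(subject = "s1", scan = seq_len(nrow(Z))),
      tr = tr, nBins = nBins, binTimes = (seq_len(nBins) - 0.5) * tr)
}

test_that("with an identity design CPCA reduces to plain PCA", {
  set.seed(20)
  Z <- matrix(rnorm(15 * 8), 15)
  st <- stackedFrom(Z, diag(15))
  m <- fitCpca(st, 3, rotate = FALSE)
  sv <- svd(Z)
  expect_equal(singularValues(m)[1:3], sv$d[1:3], tolerance = 1e-8)
  L <- componentLoadings(m)
  Lexp <- sv$v[, 1:3] %*% diag(sv$d[1:3])
  for (j in 1:3)
    expect_equal(abs(L[, j]), abs(Lexp[, j]), tolerance = 1e-8)
})

test_that("exact low-rank task structure is recovered with full variance", {
  set.seed(21)
  G <- matrix(rnorm(40 * 6), 40)
  C0 <- matrix(rnorm(6), 6) %*% t(matrix(rnorm(10), 10)) +
    matrix(rnorm(6), 6) %*% t(matrix(rnorm(10), 10))  # rank 2
  st <- stackedFrom(G %*% C0, G)
  m <- fitCpca(st, 2, rotate = FALSE)
  expect_length(singularValues(m), 2L)
  expect_equal(sum(varianceFractions(m)$unrotated), 1, tolerance = 1e-8)
  # model reconstructs GC at the retained rank
  rec <- componentScores(m) %*% t(componentLoadings(m))
  expect_equal(rec, unname(G %*% C0), tolerance = 1e-8)
})

test_that("fitCpca matches a dense normal-equations + full-SVD oracle", {
  set.seed(22)
  for (rep in 1:5) {
    n <- sample(10:30, 1); v <- sample(5:30, 1); q <- sample(3:8, 1)
    Z <- matrix(rnorm(n * v), n)
    G <- matrix(rnorm(n * q), n)
    k <- min(3L, q, v)
    st <- stackedFrom(Z, G)
    m <- fitCpca(st, k, rotate = FALSE)
    # independent dense implementation
    C <- solve(t(G) %*% G) %*% t(G) %*% Z
    sv <- svd(G %*% C)
    expect_equal(singularValues(m)[seq_len(k)], sv$d[seq_len(k)],
                 tolerance = 1e-8)
    L <- componentLoadings(m); S <- componentScores(m)
    for (j in seq_len(k)) {
      expect_equal(abs(L[, j]), abs(sv$v[, j] * sv$d[j]), tolerance = 1e-7)
      expect_equal(abs(S[, j]), abs(sv$u[, j]), tolerance = 1e-7)
    }
    expect_equal(m@regWeights, C, tolerance = 1e-8)
  }
})

test_that("varimax rotation matches a 2D grid-search maximizer", {
  set.seed(23)
  L <- matrix(rnorm(12 * 2), 12)
  res <- varimaxRotate(L, kaiser = FALSE)
  angles <- seq(0, 90, by = 0.05) * pi / 180  # criterion has period 90 deg
  crit <- vapply(angles, function(a) {
    R <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2)
    varimaxCriterion(L %*% R, kaiser = FALSE)
  }, numeric(1))
  best <- angles[which.max(crit)]
  got <- acos(min(abs(res$rotation[1, 1]), 1)) %% (pi / 2)
  expect_lt(min(abs(got - best), abs(pi / 2 - abs(got - best))),
            1 * pi / 180)
  expect_gte(varimaxCriterion(res$loadings, kaiser = FALSE),
             max(crit) - 1e-6)
})

test_that("varimax never decreases the criterion and fixes its optimum", {
  set.seed(24)
  for (rep in 1:5) {
    L <- matrix(rnorm(30 * 4), 30)
    r1 <- varimaxRotate(L, kaiser = FALSE)
    expect_gte(varimaxCriterion(r1$loadings, kaiser = FALSE),
               varimaxCriterion(L, kaiser = FALSE) - 1e-12)
    # total squared loading mass preserved by orthogonality
    expect_equal(sum(r1$loadings^2), sum(L^2), tolerance = 1e-10)
    # already-optimal loadings: rotation is identity up to sign/permutation
    r2 <- varimaxRotate(r1$loadings, kaiser = FALSE)
    P <- abs(r2$rotation)
    expect_equal(unname(apply(P, 1, max)), rep(1, 4), tolerance = 1e-4)
  }
  expect_error(varimaxRotate(matrix(1:4, 4, 1)), "2 components")
})

test_that("rotation leaves the reconstruction invariant, scores orthogonal unrotated", {
  set.seed(25)
  Z <- matrix(rnorm(40 * 12), 40)
  G <- matrix(rnorm(40 * 6), 40)
  st <- stackedFrom(Z, G)
  m0 <- fitCpca(st, 3, rotate = FALSE)
  m1 <- fitCpca(st, 3, rotate = TRUE)
  expect_equal(componentScores(m0) %*% t(componentLoadings(m0)),
               componentScores(m1) %*% t(componentLoadings(m1)),
               tolerance = 1e-8)
  expect_equal(crossprod(componentScores(m0)), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(crossprod(m1@rotation), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
  # rotated variance fractions still partition the retained variance
  vf <- varianceFractions(m1)
  expect_equal(sum(vf$rotated), sum(vf$unrotated), tolerance = 1e-10)
})

test_that("variance fractions over all rank components sum to one", {
  set.seed(26)
  st <- stackedFrom(matrix(rnorm(30 * 10), 30), matrix(rnorm(30 * 10), 30))
  m <- fitCpca(st, 2, rotate = FALSE)
  d <- singularValues(m)
  expect_equal(sum(d^2 / sum(d^2)), 1, tolerance = 1e-8)
})

test_that("predictor weights recover planted HDR shapes in noiseless data", {
  shape <- c(8L, 8L, 8L)
  nets <- defaultNetworks(shape)[3]
  cfg <- gripSimConfig(nControls = 1L, nPatients = 0L, volumeShape = shape,
                       nTrials = 12L, networks = nets, noiseSd = 0,
                       driftOrder = 0L, subjectAmpSd = 0)
  s <- simulateSubject(cfg, "control", 31L)
  p <- subjectYfir(s, cfg, residual = FALSE)
  st <- stackSubjects(list(`sub-01` = p), zscore = FALSE)
  m <- fitCpca(st, 1, rotate = FALSE)
  pw <- predictorWeights(m, st)
  for (cc in cfg@forceLevels) {
    w <- pw$weight[pw$condition == cc][order(pw$bin[pw$condition == cc])]
    expect_gt(abs(cor(w, nets[[1]]@hdr[, cc])), 0.99)
  }
})

test_that("degenerate predictor weights: zero scores and duplicated subjects", {
  set.seed(27)
  cfg <- tinyCfg(nControls = 1L, nPatients = 0L, shape = c(5L, 5L, 4L),
                 nTrials = 4L)
  s <- simulateSubject(cfg, "control", 41L)
  p <- subjectYfir(s, cfg)
  st <- stackSubjects(list(`sub-01` = p, `sub-02` = p))  # identical twice
  m <- fitCpca(st, 2)
  pw <- predictorWeights(m, st)
  w1 <- pw$weight[pw$subject == "sub-01"]
  w2 <- pw$weight[pw$subject == "sub-02"]
  expect_equal(w1, w2, tolerance = 1e-6)
  # all-zero scores give all-zero weights
  mz <- m
  mz@scores[] <- 0
  expect_true(all(predictorWeights(mz, st)$weight == 0))
})

test_that("scree elbow rule handles canonical spectra", {
  # one dominant value: elbow after the first
  expect_equal(scree(c(4, 1, 1, 1, 1))$suggested, 1L)
  # equal values: no elbow, fall back to the configured default
  s <- scree(rep(2, 6), fallback = 3L)
  expect_equal(s$suggested, 3L)
  expect_match(s$rule, "fallback")
  # exact rank edge counts as an infinite drop
  expect_equal(scree(c(5, 3, 1e-14, 1e-15))$suggested, 2L)
  # fractions are normalized squared values
  expect_equal(scree(c(3, 4))$fractions, c(16, 9) / 25)
  expect_equal(scree(7)$suggested, 1L)
})
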