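# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: labeling is a plain R flood fill, TFCE is a
# literal per-threshold sum, and the mixed-ANOVA oracle is written from
# cell means.

# small simulation config for fast tests
tinyCfg <- function(nControls = 3L, nPatients = 3L, shape = c(8L, 8L, 8L),
                    nTrials = 10L, ...) {
  gripSimConfig(nControls = nControls, nPatients = nPatients,
                volumeShape = shape, nTrials = nTrials, ...)
}

# unpack a simulated subject into (Y, fir)
subjectYfir <- function(s, cfg, residual = TRUE) {
  nScans <- dim(s$bold)[4]
  Y <- t(matrix(s$bold, prod(dim(s$bold)[1:3]), nScans))
  fir <- buildFirDesign(s$events, nScans, cfg@tr, cfg@nBins,
                        conditions = cfg@forceLevels)
  if (residual) {
    N <- buildNuisance(s$motion, nScans, driftOrder = cfg@driftOrder)
    Y <- residualize(Y, N)
  }
  list(Y = Y, fir = fir)
}

cohortStacked <- function(cohort, cfg) {
  stackSubjects(lapply(cohortSubjects(cohort), subjectYfir, cfg = cfg))
}

# flood-fill connected components on a 3D logical array (R reference)
oracleLabel <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  m <- rowSums(abs(offs))
  offs <- offs[m > 0 & m <= switch(as.character(connectivity),
                                   "6" = 1, "18" = 2, "26" = 3), ,
               drop = FALSE]
  lab <- array(0L, d)
  cur <- 0L
  idx <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    p0 <- idx[r, ]
    if (lab[p0[1], p0[2], p0[3]] > 0L) next
    cur <- cur + 1L
    queue <- list(p0)
    lab[p0[1], p0[2], p0[3]] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (o in seq_len(nrow(offs))) {
        q <- p + offs[o, ]
        if (any(q < 1L) || any(q > d)) next
        if (mask[q[1], q[2], q[3]] && lab[q[1], q[2], q[3]] == 0L) {
          lab[q[1], q[2], q[3]] <- cur
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
  }
  lab
}

# literal TFCE: midpoint-rule sum over thresholds of extent^E * h^H * dh,
# positive tail only; mirrors the documented integration scheme
oracleTfcePos <- function(v, H, E, dh, connectivity = 26L) {
  d <- dim(v)
  v <- pmax(v, 0)
  out <- array(0, d)
  vmax <- max(v)
  if (vmax <= 0) return(out)
  for (h in seq(dh / 2, vmax, by = dh)) {
    lab <- oracleLabel(v >= h, connectivity)
    if (!any(lab > 0)) next
    sizes <- tabulate(lab[lab > 0])
    inc <- ifelse(lab > 0, sizes[pmax(lab, 1L)]^E * h^H * dh, 0)
    out <- out + inc
  }
  out
}

oracleTfce <- function(v, H, E, dh, connectivity = 26L) {
  oracleTfcePos(v, H, E, dh, connectivity) -
    oracleTfcePos(-v, H, E, dh, connectivity)
}

# brute-force balanced two-within one-between mixed ANOVA from cell means;
# equal group sizes assumed (classical weighted formulas)
oracleMixedAnova <- function(d) {
  d$subject <- factor(d$subject); d$group <- factor(d$group)
  d$bin <- factor(d$bin); d$force <- factor(d$force)
  ka <- nlevels(d$bin); kb <- nlevels(d$force)
  subs <- levels(d$subject)
  n <- length(subs)
  g <- nlevels(d$group)
  mean_of <- function(...) {
    f <- interaction(...)
    tapply(d$y, f, mean)
  }
  grand <- mean(d$y)
  mS <- tapply(d$y, d$subject, mean)
  mG <- tapply(d$y, d$group, mean)
  mA <- tapply(d$y, d$bin, mean)
  mB <- tapply(d$y, d$force, mean)
  mGA <- tapply(d$y, interaction(d$group, d$bin), mean)
  mGB <- tapply(d$y, interaction(d$group, d$force), mean)
  mAB <- tapply(d$y, interaction(d$bin, d$force), mean)
  mGAB <- tapply(d$y, interaction(d$group, d$bin, d$force), mean)
  mSA <- tapply(d$y, interaction(d$subject, d$bin), mean)
  mSB <- tapply(d$y, interaction(d$subject, d$force), mean)
  grpOf <- tapply(as.character(d$group), d$subject, `[`, 1)
  ss <- list()
  ss$group <- ka * kb * sum((n / g) * (mG - grand)^2)
  ss$subjWithin <- ka * kb * sum((mS - mG[grpOf[subs]])^2)
  ss$bin <- n * kb * sum((mA - grand)^2)
  gaDev <- outer(seq_len(g), seq_len(ka),
                 function(i, j) mGA[paste(levels(d$group)[i],
                                          levels(d$bin)[j], sep = ".")] -
                   mG[i] - mA[j] + grand)
  ss$groupBin <- (n / g) * kb * sum(gaDev^2)
  # subject x bin error: deviations of subject-bin means
  saDev <- 0
  for (s in subs) for (a in levels(d$bin)) {
    saDev <- saDev + (mSA[paste(s, a, sep = ".")] - mS[s] -
      mGA[paste(grpOf[s], a, sep = ".")] + mG[grpOf[s]])^2
  }
  ss$errBin <- kb * saDev
  ss$force <- n * ka * sum((mB - grand)^2)
  gbDev <- 0
  for (gg in levels(d$group)) for (b in levels(d$force)) {
    gbDev <- gbDev + (mGB[paste(gg, b, sep = ".")] - mG[gg] - mB[b] + grand)^2
  }
  ss$groupForce <- (n / g) * ka * gbDev
  sbDev <- 0
  for (s in subs) for (b in levels(d$force)) {
    sbDev <- sbDev + (mSB[paste(s, b, sep = ".")] - mS[s] -
      mGB[paste(grpOf[s], b, sep = ".")] + mG[grpOf[s]])^2
  }
  ss$errForce <- ka * sbDev
  abDev <- 0
  for (a in levels(d$bin)) for (b in levels(d$force)) {
    abDev <- abDev + (mAB[paste(a, b, sep = ".")] - mA[a] - mB[b] + grand)^2
  }
  ss$binForce <- n * abDev
  gabDev <- 0
  for (gg in levels(d$group)) for (a in levels(d$bin)) for (b in levels(d$force)) {
    gabDev <- gabDev +
      (mGAB[paste(gg, a, b, sep = ".")] -
         mGA[paste(gg, a, sep = ".")] - mGB[paste(gg, b, sep = ".")] -
         mAB[paste(a, b, sep = ".")] +
         mG[gg] + mA[a] + mB[b] - grand)^2
  }
  ss$groupBinForce <- (n / g) * gabDev
  ssTot <- sum((d$y - grand)^2)
  ss$errBinForce <- ssTot - Reduce(`+`, ss[c(
    "group", "subjWithin", "bin", "groupBin", "errBin", "force",
    "groupForce", "errForce", "binForce", "groupBinForce")])
  dfe <- list(group = g - 1, subjWithin = n - g,
              bin = ka - 1, groupBin = (g - 1) * (ka - 1),
              errBin = (n - g) * (ka - 1),
              force = kb - 1, groupForce = (g - 1) * (kb - 1),
              errForce = (n - g) * (kb - 1),
              binForce = (ka - 1) * (kb - 1),
              groupBinForce = (g - 1) * (ka - 1) * (kb - 1),
              errBinForce = (n - g) * (ka - 1) * (kb - 1))
  Fv <- c(group = (ss$group / dfe$group) / (ss$subjWithin / dfe$subjWithin),
          bin = (ss$bin / dfe$bin) / (ss$errBin / dfe$errBin),
          `group:bin` = (ss$groupBin / dfe$groupBin) /
            (ss$errBin / dfe$errBin),
          force = (ss$force / dfe$force) / (ss$errForce / dfe$errForce),
          `group:force` = (ss$groupForce / dfe$groupForce) /
            (ss$errForce / dfe$errForce),
          `bin:force` = (ss$binForce / dfe$binForce) /
            (ss$errBinForce / dfe$errBinForce),
          `group:bin:force` = (ss$groupBinForce / dfe$groupBinForce) /
            (ss$errBinForce / dfe$errBinForce))
  Fv <- setNames(as.numeric(Fv),
                 c("group", "bin", "group:bin", "force", "group:force",
                   "bin:force", "group:bin:force"))
  list(ss = ss, df = dfe, F = Fv)
}

# textbook Greenhouse-Geisser epsilon written from covariance entries
oracleGgEpsilon <- function(S) {
  k <- nrow(S)
  sbar <- mean(S)
  sii <- mean(diag(S))
  si. <- rowMeans(S)
  num <- (k * (sii - sbar))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(si.^2) + k^2 * sbar^2)
  num / den
}
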