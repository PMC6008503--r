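simWeights <- function(nPerGroup = c(control = 4, patient = 4), ka = 6,
                       kb = 2, effect = function(g, a, b) 0, sd = 1,
                       seed = 1) {
  set.seed(seed)
  out <- expand.grid(bin = seq_len(ka), force = paste0("f", seq_len(kb)),
                     subject = sprintf("s%02d",
                                       seq_len(sum(nPerGroup))),
                     stringsAsFactors = FALSE)
  grp <- rep(names(nPerGroup), nPerGroup)
  names(grp) <- sprintf("s%02d", seq_len(sum(nPerGroup)))
  out$group <- grp[out$subject]
  subjEff <- stats::rnorm(sum(nPerGroup), 0, sd)  # random subject level
  names(subjEff) <- names(grp)
  out$weight <- mapply(effect, out$group, out$bin, out$force) +
    subjEff[out$subject] + stats::rnorm(nrow(out), 0, sd)
  out
}

test_that("mixed ANOVA matches the brute-force cell-means oracle", {
  d <- simWeights(c(control = 2, patient = 2), ka = 2, kb = 2,
                  effect = function(g, a, b)
                    0.5 * (g == "patient") + 0.3 * a +
                    0.7 * (b == "f2") * a, seed = 2)
  rep <- mixedAnova(d)
  ora <- oracleMixedAnova(data.frame(subject = d$subject, group = d$group,
                                     bin = d$bin, force = d$force,
                                     y = d$weight))
  for (ef in names(ora$F)) {
    expect_equal(rep$F[rep$effect == ef], unname(ora$F[ef]),
                 tolerance = 1e-10, label = ef)
  }
  # the 6x2x2 layout agrees too, with unequal groups against aov directly
  d6 <- simWeights(c(control = 5, patient = 3), ka = 6, kb = 2, seed = 3)
  rep6 <- mixedAnova(d6)
  expect_equal(nrow(rep6), 7L)
  expect_true(all(rep6$df1[rep6$effect == "bin"] == 5))
  expect_true(all(rep6$df2[rep6$effect == "bin"] == (8 - 2) * 5))
})

test_that("ANOVA F values are location and scale invariant; eta2p bounded", {
  d <- simWeights(seed = 4)
  r0 <- mixedAnova(d)
  d2 <- d; d2$weight <- 3.7 + d$weight
  expect_equal(mixedAnova(d2)$F, r0$F, tolerance = 1e-9)
  d3 <- d; d3$weight <- -2.5 * d$weight
  expect_equal(mixedAnova(d3)$F, r0$F, tolerance = 1e-9)
  expect_true(all(r0$etaSqP >= 0 & r0$etaSqP <= 1))
  expect_true(all(r0$epsilon >= 1 / r0$df1 | is.na(r0$epsilon)))
})

test_that("incomplete designs are rejected rather than imputed", {
  d <- simWeights(seed = 5)
  expect_error(mixedAnova(d[-1, ]), "incomplete|unbalanced")
  d$group[1] <- "patient"  # subject with two group labels
  expect_error(mixedAnova(d), "exactly one group")
})

test_that("Greenhouse-Geisser epsilon matches closed forms and the textbook formula", {
  # compound symmetry: sphericity holds exactly
  S <- 0.4 + diag(0.6, 5)
  expect_equal(ggEpsilon(S), 1)
  # rank-1 covariance: maximal violation
  v <- c(1, 2, 0.5, 3)
  expect_equal(ggEpsilon(outer(v, v)), 1 / 3, tolerance = 1e-10)
  # random PSD covariance vs the direct textbook expression
  set.seed(6)
  for (i in 1:5) {
    A <- matrix(rnorm(36), 6)
    S6 <- crossprod(A) + diag(6) * 0.1
    expect_equal(ggEpsilon(S6), oracleGgEpsilon(S6), tolerance = 1e-10)
  }
  expect_error(ggEpsilon(matrix(c(1, 2, 0, 1), 2)), "symmetric")
})

test_that("epsilon bounds drive the GG-adjusted degrees of freedom", {
  d <- simWeights(seed = 7)
  r <- mixedAnova(d)
  w <- r[r$effect == "bin", ]
  expect_true(w$epsilon >= 1 / 5 && w$epsilon <= 1)
  expect_equal(w$df1GG, w$df1 * w$epsilon)
  expect_true(w$pGG >= 0 && w$pGG <= 1)
})

test_that("BH step-up adjustment matches hand-computed examples", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFdr(0.2), 0.2)
  expect_equal(bhFdr(rep(1, 5)), rep(1, 5))
  expect_error(bhFdr(c(0.5, 1.2)), "0, 1")
  set.seed(8)
  p <- runif(20)
  adj <- bhFdr(p)
  expect_true(all(adj >= p - 1e-12))
  expect_true(all(adj <= 1))
  # monotone in the sorted order
  o <- order(p)
  expect_true(all(diff(adj[o]) >= -1e-12))
})

test_that("simple effects isolate the bins carrying a planted force effect", {
  d <- simWeights(c(control = 10, patient = 10), sd = 0.3,
                  effect = function(g, a, b)
                    0.9 * (b == "f2") * (a %in% c(2, 3)), seed = 9)
  se <- simpleEffects(d, "force")
  expect_equal(se$bin[se$pFdr < 0.05], c("2", "3"))
  expect_equal(nrow(se), 6L)
  # null: equal condition means leave no bin significant
  d0 <- simWeights(c(control = 10, patient = 10), sd = 0.3, seed = 10)
  expect_true(all(simpleEffects(d0, "force")$pFdr > 0.05))
  # with one bin the adjusted p equals the raw p
  d1 <- d[d$bin == 1, ]
  se1 <- simpleEffects(d1, "force")
  expect_equal(se1$pFdr, se1$p)
})

test_that("group simple effects find planted between-group differences", {
  d <- simWeights(c(control = 12, patient = 12), sd = 0.3,
                  effect = function(g, a, b)
                    1.0 * (g == "control") * (a == 4), seed = 11)
  se <- simpleEffects(d, "group")
  expect_equal(se$bin[se$pFdr < 0.05], "4")
  expect_gt(se$estimate[se$bin == "4"], 0)  # controls higher
})
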