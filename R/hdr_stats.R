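# Mixed-design ANOVA on predictor weights: within-subject factors
# Poststimulus Time (FIR bin) and Force, between-subject factor Group.
# Sphericity is handled by Greenhouse-Geisser epsilon; both uncorrected
# and GG-adjusted p values are always reported, making the sphericity
# check explicit output rather than a silent judgment.

orthonormalContrasts <- function(k) {
  C <- stats::contr.helmert(k)
  sweep(C, 2, sqrt(colSums(C^2)), "/")
}

#' Greenhouse-Geisser epsilon from a within-factor covariance
#'
#' Computed from the double-centered covariance matrix: with eigenvalues
#' `lambda` of the double-centered matrix, `epsilon = (sum lambda)^2 /
#' ((k - 1) * sum lambda^2)`, clipped to its theoretical range
#' `[1/(k - 1), 1]`. Equals 1 under compound symmetry (sphericity holds)
#' and `1/(k - 1)` under maximal violation.
#'
#' @param covariance symmetric k x k covariance of the k repeated measures.
#' @return epsilon in `[1/(k - 1), 1]`.
#' @export
ggEpsilon <- function(covariance) {
  S <- as.matrix(covariance)
  k <- nrow(S)
  if (k < 2L || ncol(S) != k) stop("covariance must be k x k with k >= 2")
  if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S))))
    stop("covariance must be symmetric")
  Ce <- diag(k) - 1 / k
  Sc <- Ce %*% S %*% Ce
  tr <- sum(diag(Sc))
  denom <- (k - 1) * sum(Sc^2)
  if (denom < .Machine$double.eps) return(1)  # degenerate: no within variance
  min(max(tr^2 / denom, 1 / (k - 1)), 1)
}

# epsilon for a within effect from orthonormal contrast scores, pooled
# within groups (the multi-sample GG estimator)
effectEpsilon <- function(cellMatrix, M, groups) {
  scores <- cellMatrix %*% M
  d <- ncol(M)
  if (d == 1L) return(1)
  g <- as.factor(groups)
  Sp <- matrix(0, d, d)
  for (lev in levels(g)) {
    x <- scores[g == lev, , drop = FALSE]
    xc <- sweep(x, 2, colMeans(x))
    Sp <- Sp + crossprod(xc)
  }
  Sp <- Sp / (nrow(scores) - nlevels(g))
  tr <- sum(diag(Sp))
  denom <- d * sum(Sp^2)
  if (denom < .Machine$double.eps) return(1)
  min(max(tr^2 / denom, 1 / d), 1)
}

#' Mixed-design ANOVA on predictor weights
#'
#' Fits the two-within (Poststimulus Time x Force), one-between (Group)
#' univariate mixed ANOVA on per-subject cell means via the standard
#' error-strata decomposition, and reports for every effect the F ratio,
#' degrees of freedom, p value, partial eta squared
#' (`SS_effect / (SS_effect + SS_error)`), and for within effects the
#' Greenhouse-Geisser epsilon with GG-adjusted degrees of freedom and p.
#' Group x within interactions share their within effect's epsilon.
#'
#' @param weights data.frame with one row per subject x bin x force cell:
#'   columns `subject`, `group`, `bin`, `force`, and the dependent value.
#' @param dv name of the dependent column (default `"weight"`).
#' @return data.frame with one row per effect and attributes `epsilons`.
#' @export
mixedAnova <- function(weights, dv = "weight") {
  d <- data.frame(
    subject = factor(weights$subject),
    group = factor(weights$group),
    bin = factor(weights$bin),
    force = factor(weights$force),
    y = weights[[dv]]
  )
  tab <- table(d$subject, d$bin, d$force)
  if (any(tab != 1L))
    stop("design is incomplete or unbalanced: every subject needs exactly ",
         "one value per bin x force cell")
  subGroup <- unique(d[, c("subject", "group")])
  if (anyDuplicated(subGroup$subject))
    stop("each subject must belong to exactly one group")

  fit <- aov(y ~ group * bin * force + Error(subject / (bin * force)),
             data = d)
  sm <- summary(fit)
  pull <- function(stratum, effects) {
    tabl <- sm[[stratum]][[1]]
    rn <- trimws(rownames(tabl))
    err <- which(rn == "Residuals")
    out <- lapply(effects, function(ef) {
      i <- which(rn == ef)
      if (!length(i)) return(NULL)
      data.frame(effect = ef, df1 = tabl$Df[i], df2 = tabl$Df[err],
                 ss = tabl$`Sum Sq`[i], ssError = tabl$`Sum Sq`[err],
                 F = tabl$`F value`[i], p = tabl$`Pr(>F)`[i],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }
  rep0 <- rbind(
    pull("Error: subject", "group"),
    pull("Error: subject:bin", c("bin", "group:bin")),
    pull("Error: subject:force", c("force", "group:force")),
    pull("Error: subject:bin:force", c("bin:force", "group:bin:force"))
  )
  rep0$etaSqP <- rep0$ss / (rep0$ss + rep0$ssError)

  # Greenhouse-Geisser epsilons from per-subject cell matrices
  kb <- nlevels(d$bin); kf <- nlevels(d$force)
  d <- d[order(d$subject, d$bin, d$force), ]
  subjects <- levels(d$subject)
  cells <- matrix(d$y, nrow = length(subjects), byrow = TRUE)  # bin-major
  grp <- subGroup$group[match(subjects, subGroup$subject)]
  Mb <- orthonormalContrasts(kb)
  Mf <- orthonormalContrasts(kf)
  binMeans <- cells %*% (kronecker(diag(kb), matrix(1 / kf, kf, 1)))
  forceMeans <- cells %*% (kronecker(matrix(1 / kb, kb, 1), diag(kf)))
  eps <- c(
    bin = effectEpsilon(binMeans, Mb, grp),
    force = effectEpsilon(forceMeans, Mf, grp),
    `bin:force` = effectEpsilon(cells, kronecker(Mb, Mf), grp)
  )
  withinOf <- c(bin = "bin", `group:bin` = "bin",
                force = "force", `group:force` = "force",
                `bin:force` = "bin:force", `group:bin:force` = "bin:force")
  rep0$epsilon <- unname(eps[withinOf[rep0$effect]])
  rep0$df1GG <- rep0$df1 * ifelse(is.na(rep0$epsilon), 1, rep0$epsilon)
  rep0$df2GG <- rep0$df2 * ifelse(is.na(rep0$epsilon), 1, rep0$epsilon)
  rep0$pGG <- pf(rep0$F, rep0$df1GG, rep0$df2GG, lower.tail = FALSE)
  rownames(rep0) <- NULL
  attr(rep0, "epsilons") <- eps
  rep0
}

#' Paper-style formatting of an ANOVA report
#'
#' @param report output of [mixedAnova()].
#' @return character vector, one formatted line per effect, e.g.
#'   `"bin: F(5,195) = 9.31, p < 0.001, eta2p = 0.19"`.
#' @export
formatAnova <- function(report) {
  pTxt <- ifelse(report$p < 0.001, "p < 0.001",
                 sprintf("p = %.3f", report$p))
  sprintf("%s: F(%g,%g) = %.2f, %s, eta2p = %.2f",
          report$effect, report$df1, report$df2, report$F, pTxt,
          report$etaSqP)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p values, monotone and capped at 1.
#'
#' @param pvalues numeric vector of p values in \[0, 1\].
#' @return adjusted p values, same length.
#' @export
bhFdr <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Simple main effects per poststimulus bin
#'
#' Follow-up contrasts for a within-effect interaction: at each
#' poststimulus bin, either a paired t test between the two force levels
#' (within subjects) or a two-sample t test between groups (on
#' force-averaged values). Both raw and Benjamini-Hochberg adjusted p
#' values are reported; the FDR family is the set of bins tested.
#'
#' @param weights data.frame as in [mixedAnova()].
#' @param contrast `"force"` (paired within subjects) or `"group"`
#'   (between subjects).
#' @param dv dependent column name (default `"weight"`).
#' @param varEqual for the group contrast, pool variances as the ANOVA does
#'   (default TRUE); FALSE gives Welch.
#' @return data.frame: bin, estimate, t, df, p, pFdr.
#' @export
simpleEffects <- function(weights, contrast = c("force", "group"),
                          dv = "weight", varEqual = TRUE) {
  contrast <- match.arg(contrast)
  d <- data.frame(subject = factor(weights$subject),
                  group = factor(weights$group),
                  bin = factor(weights$bin),
                  force = factor(weights$force),
                  y = weights[[dv]])
  bins <- levels(d$bin)
  rows <- lapply(bins, function(b) {
    db <- d[d$bin == b, ]
    if (contrast == "force") {
      lv <- levels(db$force)
      if (length(lv) != 2L) stop("force contrast needs exactly 2 levels")
      wide <- merge(db[db$force == lv[1], c("subject", "y")],
                    db[db$force == lv[2], c("subject", "y")],
                    by = "subject", suffixes = c(".1", ".2"))
      tt <- t.test(wide$y.2, wide$y.1, paired = TRUE)
      est <- unname(tt$estimate)
    } else {
      agg <- stats::aggregate(y ~ subject + group, data = db, FUN = mean)
      lv <- levels(agg$group)
      if (length(lv) != 2L) stop("group contrast needs exactly 2 levels")
      tt <- t.test(agg$y[agg$group == lv[1]], agg$y[agg$group == lv[2]],
                   var.equal = varEqual)
      est <- unname(diff(rev(tt$estimate)))
    }
    data.frame(bin = b, estimate = est, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$pFdr <- bhFdr(out$p)
  out
}
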