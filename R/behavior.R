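# Behavioral composite scoring and brain-behavior correlation. The three
# motor measures (grip strength, Nine-Hole Peg Test, Box and Block Test,
# each as % of the unaffected hand) are summarized by the first principal
# component; regional activity within significant clusters is then
# correlated with the composite.

#' Behavioral composite score by PCA
#'
#' Standardizes (z-scores) the measures and takes the first principal
#' component as the single impairment score. The component is oriented so
#' that higher composite values mean better motor performance (the sum of
#' PC1 loadings on the raw measures is positive; all measures are scored
#' higher = better). The orientation is reported explicitly because the
#' sign of a principal component is otherwise arbitrary.
#'
#' @param measures numeric matrix/data.frame, patients x measures (>= 3
#'   patients, >= 2 measures; the motor battery has 3).
#' @return list: `scores` (per patient), `varianceExplained` (PC1 fraction),
#'   `loadings` (PC1 loadings on the standardized measures),
#'   `orientation` = `"higher = better performance"`.
#' @export
compositeScore <- function(measures) {
  X <- as.matrix(measures)
  if (nrow(X) < 3L) stop("need at least 3 patients")
  if (ncol(X) < 2L) stop("need at least 2 measures")
  sds <- apply(X, 2, sd)
  if (any(sds < .Machine$double.eps^0.5))
    stop("zero-variance measure: ",
         paste(colnames(X)[sds < .Machine$double.eps^0.5], collapse = ", "))
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  load1 <- pc$rotation[, 1]
  flip <- if (sum(load1) < 0) -1 else 1
  ve <- pc$sdev[1]^2 / sum(pc$sdev^2)
  list(scores = as.vector(pc$x[, 1]) * flip,
       varianceExplained = ve,
       loadings = load1 * flip,
       orientation = "higher = better performance")
}

#' Correlate regional network activity with the behavioral composite
#'
#' Pearson correlation with a two-sided test between a per-patient regional
#' activity scalar (e.g. mean predictor-weight-based activity over a
#' significant within-network cluster) and the composite score.
#'
#' @param regionalActivity numeric, one value per patient.
#' @param composite numeric composite scores, same patients in the same
#'   order.
#' @return list: `r`, `p`, `n`, `conf` (95% CI when n >= 4).
#' @export
brainBehaviorCorrelation <- function(regionalActivity, composite) {
  x <- as.numeric(regionalActivity); y <- as.numeric(composite)
  if (length(x) != length(y)) stop("inputs differ in length")
  if (length(x) < 4L) stop("need at least 4 paired observations")
  if (sd(x) < .Machine$double.eps^0.5 || sd(y) < .Machine$double.eps^0.5)
    stop("constant input vector")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       conf = as.vector(ct$conf.int))
}
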