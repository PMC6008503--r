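---
title: "Task-based functional connectivity by constrained PCA: models and methods"
author: "fmricpca"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Task-based functional connectivity by constrained PCA: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmricpca)
```

# The analysis problem

Event-related task fMRI of a two-group motor study — patients performing
visually cued isometric hand grips with the affected hand, controls with
the dominant hand, at two force levels — yields one 4D BOLD volume per
subject plus trial timing, motion parameters, behavioral motor scores and
lesion masks. The scientific questions this package addresses are:

1. Which whole-brain functional networks carry the task-related BOLD
   variance shared across all subjects, and what estimated hemodynamic
   response (HDR) does each network express per subject and condition?
2. Do the groups differ in how strongly they express those networks, as a
   function of poststimulus time and grip force?
3. Within each network's dominant voxels, where exactly do the groups
   differ, under permutation-based family-wise error control?
4. Does regional activity in the differing clusters relate to the degree
   of behavioral motor impairment?

# The model

## FIR design

Each trial of condition $c$ is modeled by a finite impulse response (FIR)
basis: one free indicator per poststimulus scan. The onset scan is the
first full scan starting at or after stimulus onset; indicators occupy
that scan and the following $n_{bins}-1$ scans. With the study's TR of
3.25 s and 6 bins the modeled window is $6 \times 3.25 = 19.5$ s. The FIR
basis makes no assumption about HDR shape, so both the primary response
and the poststimulus undershoot are estimable quantities rather than
modeling residue.

**Bin time labels.** Scans integrate signal over a TR, so bin $k$ is
labeled at the scan midpoint $(k - \tfrac12)\,\mathrm{TR}$ by default
(1.6, 4.9, 8.1, 11.4, 14.6, 17.9 s at TR 3.25); an onset-anchored
convention $(k-1)\,\mathrm{TR}$ is available via
`buildFirDesign(..., binAnchor = "onset")`. The midpoint convention is
the default because it locates each estimate at the center of the
interval it summarizes.

## Nuisance removal and stacking

Per subject, task-unrelated variance is removed by least squares in a
fixed order: rigid-body motion parameters first, then polynomial drift
and intercept. Residualized voxel time series are z-scored per voxel
within subject (mean 0, SD 1) so no subject's variance scale dominates
the decomposition, then subjects are stacked along the scan axis. The FIR
designs enter a block-diagonal matrix $G$ with subject-specific columns,
which is what makes the downstream predictor weights subject- and
condition-specific while the spatial components stay shared.

## Constrained PCA

With stacked data $Z$ ($N$ scans $\times$ $V$ voxels) and design $G$
($N \times q$), the multivariate regression $C = (G'G)^{-1} G' Z$ yields
the predicted, task-related matrix $GC$, and its SVD
$GC = U D V'$ isolates independent sources of task-driven variance.
Component $k$ accounts for the fraction $d_k^2 / \sum_j d_j^2$ of
task-related variance.

**Rotation.** Varimax rotation is computed on the *orthonormal* spatial
basis $V$ (Kaiser row-normalized by default), not on the singular-value
scaled loadings. Rotating $VD$ directly lets the dominant component's
scale freeze the criterion, and — more seriously — mixing through $D$
re-entangles components that the rotation is meant to separate; on
synthetic data with known networks this cost roughly half the spatial
recovery. With rotation $R$ from $V$, the model stores

$$\text{loadings} = (V R)\,\Delta, \qquad
  \text{scores} = U D R \Delta^{-1}, \qquad
  \Delta_k = \lVert D R e_k \rVert,$$

so that $\text{scores} \cdot \text{loadings}' = U D V'$ exactly for any
orthogonal $R$, the rotated column sums of squares $\Delta_k^2$ partition
the retained task-related variance, and $R = I$ reduces to the familiar
unrotated pair $(VD,\, U)$. Each component is sign-oriented so its
largest-magnitude loading is positive (networks may still carry genuinely
negative loadings — deactivations — which are reported, never discarded),
and rotated components are ordered by explained variance.

**Component count.** The scree suggestion is the largest index
$k \le 20$ at which the spectrum still drops noticeably
($d_k / d_{k+1} \ge 1.15$, the last visible drop before the flat tail;
an effectively zero $d_{k+1}$ counts as an infinite drop). Equal-value
spectra have no elbow and fall back to a configured default. The
suggestion is advisory — the retained count is an explicit analysis
choice, as it is in practice.

## Predictor weights and subject-level maps

Regressing each component's score column onto $G$ gives one weight per
(subject, condition, poststimulus bin, component): the estimated HDR
shape of that network for that subject and condition. Because scores are
counter-rotated consistently with the loadings, weights and loadings
refer to the same rotated components.

For voxelwise group inference a subject-level image per component is
needed. The default is the **beta-projection map**: the subject's FIR
coefficient rows of $C$ contracted with the component's unit-normalized,
cohort-mean predictor-weight profile — the subject's beta map projected
onto the network's HDR shape. An alternative (`"scoreRegression"`,
regressing the subject's data rows on the subject's score rows) is
selectable but noisy: each subject's score-block norm is about
$1/\sqrt{n_{subjects}}$, and dividing by it amplifies residual noise to
the point where strong planted group differences become undetectable.
That empirical comparison is why beta-projection is the default.

# Inference

## Mixed ANOVA on predictor weights

Per network, the per-subject cell means (6 poststimulus bins $\times$ 2
force levels) enter a two-within, one-between mixed ANOVA
(Poststimulus Time $\times$ Force $\times$ Group) via the classical
error-strata decomposition. Every effect is reported with $F$, degrees of
freedom, $p$, partial eta squared
$\eta_p^2 = SS_{effect} / (SS_{effect} + SS_{error})$, and — for within
effects — the Greenhouse–Geisser epsilon
$\varepsilon = (\sum_i \lambda_i)^2 / ((k{-}1) \sum_i \lambda_i^2)$
(eigenvalues of the double-centered covariance; multi-sample estimate
pooled within groups via orthonormal contrasts), together with
GG-adjusted degrees of freedom and $p$. Both corrected and uncorrected
results are always present, making the sphericity check explicit output
rather than an undocumented judgment. Group-by-within interactions share
their within effect's epsilon.

Simple main effects follow an interaction up per poststimulus bin: a
paired $t$ test between force levels, or a two-sample $t$ test between
groups on force-averaged values (pooled variance by default, matching
the ANOVA error term; Welch selectable). The FDR family is the set of
bins tested in one follow-up (6 by default) and both raw and
Benjamini–Hochberg adjusted $p$ values are reported, since displaying
uncorrected trends alongside corrected findings is standard practice in
this literature.

## Within-network permutation inference

Group differences inside a network are tested only over that network's
most extreme voxels: `topFractionMask()` selects exactly
$\lceil f \cdot V \rceil$ voxels (analysis default $f = 0.10$, display
overlays $f = 0.05$) under a selectable sign rule (absolute value by
default; positive or negative for networks dominated by activations or
deactivations), ties broken by voxel index order for bit-exact
reproducibility.

The voxelwise statistic is the pooled-variance two-sample $t$ on the
subject-level maps. Threshold-free cluster enhancement integrates
$e(h)^{E} h^{H}\, dh$ over cluster-forming thresholds (midpoint rule;
defaults $H = 2$, $E = 0.5$, 26-connectivity, $dh = \max/100$ — the
standard published parameterization). The integration step is fixed from
the *observed* map and reused for all permutations, otherwise a
per-permutation $dh$ would rescale the null. Both tails are enhanced
separately; the null is the distribution of the maximum absolute
enhanced statistic over the mask across group-label permutations, which
controls family-wise error over the two-sided, whole-mask family.
Corrected $p$ values are $(1 + \#\{\text{null} \ge \text{obs}\}) /
(1 + n_{perm})$ — the identity labeling is part of the null, so $p > 0$
always. When fewer distinct label splits exist than requested
permutations, all splits are enumerated (with a warning) and
$p = \#\{\text{null} \ge \text{obs}\} / n_{splits}$. The default scheme
uses 5000 permutations and a stored seed, so every run is reproducible.

## Lesion overlap and Dice

Lesion masks are summed voxelwise into an overlap map. Spatial
correspondence between lesions and networks is quantified by the Dice
coefficient $2|A \cap B| / (|A| + |B|)$ between each network's extreme-10%
mask and the overlap map binarized at $\ge 1$ patient (the binarization
is a documented config choice; a weighted variant is not provided because
the coefficient is defined on sets). Images whose lesioned hemisphere is
right are mirrored about the midsagittal plane first
(`flipMidsagittal()`), identifying the left–right voxel axis from the
affine and updating the affine so world coordinates are preserved up to
reflection; the flip is an exact involution.

## Behavioral composite and brain–behavior correlation

The three motor measures (grip strength, Nine-Hole Peg Test, Box and
Block Test, each as % of the unaffected hand) are z-scored and summarized
by the first principal component. Because a principal component's sign is
arbitrary, the composite is explicitly oriented so that **higher scores
mean better motor performance** (positive loading sum on the raw
measures, which are all scored higher-is-better), and the orientation is
part of the output — descriptions of such scores in the literature are
not always internally consistent about direction, so the package makes
the convention explicit rather than implicit. Regional activity (mean
subject-level map value over the significant within-network cluster,
falling back to the full analysis mask when nothing survives) is related
to the composite by a Pearson correlation with a two-sided test.

# The synthetic-data generator

The generator is first-class, tested code: it is the source of ground
truth for every recovery and calibration claim the package makes. It
emulates the target study design — 24 controls + 17 patients, 50 visually
cued isometric grips per subject at two force levels in randomized
balanced order, 3 s holds, ISI uniform on 3–7 s, TR 3.25 s — and plants:

* four spatially separated networks (bilateral dorsal-attention, early
  visual, left-lateralized sensorimotor with premotor extension, midline
  default-mode) as Gaussian blobs with width about a fifth of the grid,
  so each network covers a few percent of the volume, the typical extent
  of a task network relative to the brain;
* per-network HDR ground truth **directly as FIR bin amplitudes** (not a
  canonical HRF), so recovery tests compare the estimator's native
  quantities; latencies are staggered (visual earliest, attention next,
  motor peaking later with an undershoot, DMN deactivating slowest) as
  event-related grip responses show, which also keeps the planted time
  courses distinguishable (pairwise $|r| \le 0.82$);
* group structure: patients express the motor network at 0.6 and the DMN
  deactivation at 0.5 of the control amplitude;
* a force effect: the low-force curve is a scaled-down copy of the
  high-force curve (motor network scale 0.7);
* between-subject amplitude jitter (multiplicative, SD 0.2), AR(1) voxel
  noise ($\phi = 0.3$) with marginal SD 0.5 — planted peak responses about
  twice the voxel noise SD, the regime in which the desk-scale
  decomposition is well-posed — and quadratic polynomial drift;
* behavioral measures coupled to each patient's realized sensorimotor
  amplitude (slope 0.8 on the standardized jitter) plus independent
  per-measure noise, and per-patient lesion blobs confined to the
  sensorimotor (left) hemisphere.

Scan count per run is derived from the event schedule plus a tail of
`nBins + 2` scans, since total scan duration follows from the design
rather than being an independent constant.

What the generator does **not** emulate: MR physics, spatially
correlated (smoothed) noise, physiological confounds, registration error,
inter-subject anatomical variability, or realistic lesion-induced signal
dropout. Passing recovery tests therefore demonstrates that the
estimator chain is correct and well-calibrated under the stated
statistical structure — not that real acquisitions at real SNR will
yield networks this cleanly.

# Numerical choices

* **Rank and SVD.** The SVD of $GC$ is computed through the smaller Gram
  matrix; singular values below $10^{-7} d_1$ are treated as numerical
  zeros. Ill-conditioned $G'G$ falls back to a pseudo-inverse with a
  condition-number warning.
* **Degenerate inputs.** Constant voxels survive z-scoring as zeros;
  empty event tables give all-zero designs; FIR windows running off the
  scan axis are truncated with a warning; rank-deficient nuisance
  matrices project onto their span with a warning; empty masks, constant
  loading maps, all-positive maps under a negative sign rule,
  zero-variance behavioral measures and constant correlation inputs are
  explicit errors rather than silent results.
* **Ties.** Top-fraction masks break loading ties by voxel index order;
  greedy component matching resolves by maximum absolute correlation
  first.
* **Determinism.** Every stochastic step (simulation, permutation) takes
  a seed; per-subject seeds derive arithmetically from the master seed;
  RNG state is saved and restored around simulation calls so library use
  does not disturb a session's RNG.

# Validation problem sizes

The shipped test suite validates against independent oracles at sizes a
desk machine handles comfortably: dense normal-equations + full-SVD
agreement on random problems up to $30 \times 30$ (tolerance $10^{-8}$);
full-cohort network recovery (41 subjects, $12^3$ voxels, 50 trials)
over 10 seeds requiring every planted map matched at $|r| > 0.9$ with the
scree suggesting 4; mixed-ANOVA agreement with a brute-force cell-means
oracle to $10^{-10}$ and type-I calibration from 1000 null simulations of
the 6 × 2 × 2 design at the study's group sizes; TFCE equality with a
literal per-threshold labeling oracle and exhaustive 3-vs-3 permutation
enumeration; family-wise error calibration from 500 null simulations at
a reduced 200-permutation scheme; and brain–behavior sign recovery over
200 seeds of a reduced single-network, patients-only cohort ($6^3$
voxels, 16 trials) run through the full estimation chain.

# Known limitations

* Orthogonal rotation cannot represent genuinely oblique (spatially
  correlated) networks; overlap between true networks biases recovered
  maps toward orthogonality.
* Per-voxel z-scoring compresses between-subject amplitude differences
  (a planted 1.67-fold group ratio reappears as roughly 1.4–1.5-fold in
  predictor-weight peaks at the documented SNR); group *contrasts*
  remain valid, but absolute amplitude ratios are conservative.
* The mixed ANOVA requires complete balanced within-cells; missing cells
  are an error by design, not imputed.
* The permutation engine supports two-group label exchange only — no
  exchangeability blocks, variance smoothing, or one-sample sign-flip
  designs.
* TFCE integration uses a finite step ($dh = \max/100$); enhanced values
  carry the corresponding discretization error, which cancels in rank
  comparisons against a null computed with the same step.
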