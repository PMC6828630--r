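---
title: "Methods: chemometric evaluation of IMS preprocessing and ROI annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemometric evaluation of IMS preprocessing and ROI annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Imaging mass spectrometry (IMS) acquires a full mass spectrum at every pixel
of a tissue section. Before any multivariate analysis, the pixel spectra are
usually transformed and/or normalized, and the choice among the many common
options (TIC, median, mean, RMS or maximum-peak normalization; log or square
root transformation, alone or combined) visibly changes every downstream
result: which anatomical structures appear in PCA score images, how cleanly
regions of interest (ROIs) can be segmented, and how stable per-ion
intensities are within a region. `imschemo` implements an objective way to
choose: preprocess, discover candidate ROIs with image PCA, annotate them by
region-based active-contour segmentation in score space, and then score every
preprocessing method by the cross-validated predictive quality (Q2Y) of an
OPLS-DA model that predicts the ROI class of each pixel from its spectrum.
The preprocessing that best supports class prediction is the one that best
separates biological from technical variance.

# Data model

A dataset is a `pixels x peaks` intensity matrix plus a pixel-to-grid
coordinate index (an `ims_cube`). Coordinates are 0-based with `x` indexing
columns; imzML's 1-based convention is shifted at the file boundary. Tissue
outlines are not rectangular, so grid positions without a spectrum are
represented as `NA` in every reconstructed image and excluded from all
statistics, means and segmentation perimeters. Columns are generic "peaks":
the package is agnostic about whether the upstream data were profile binned
or centroided, and does no peak picking of its own. Processed-mode imzML is
rebinned onto a uniform axis by summation (`bin_width` in Da) because all
downstream linear algebra requires a common axis.

# Preprocessing

Transformations act elementwise: `sqrt(x)`, `ln(x + c)`, `log10(x + c)` with
offset `c = 1` by default so zeros map to zero and within-spectrum order is
preserved. Normalizations divide each spectrum by a per-spectrum scale: sum
(TIC), mean, median of the strictly positive intensities, root mean square,
or maximum. The median is taken over positive values because sparse spectra
otherwise have median zero, which is not a usable scale; rows whose scale is
zero or undefined are left unchanged and flagged rather than producing
NaNs. Combined specifications such as `"ln-median"` apply the transformation
first and normalize the transformed values; the reverse order exists as an
explicit option but is not the default. Scales normalize to a unit statistic
(TIC sums to 1, and so on) rather than to a dataset-average statistic: PCA
and OPLS-DA are invariant to that global constant because both mean-center.

# Image PCA

PCA is computed on the mean-centered (never variable-scaled) matrix by a
deterministic full SVD — no randomized solver — because the interesting
anatomy can sit as deep as the 20th-odd component and reproducibility of
score images matters more than speed at these sizes. Each loading is signed
so its largest-magnitude element is positive. `r2x` reports each component's
fraction of total centered variance. Score vectors fold back into score
images via the coordinate index; a stack of score images (optionally
standardized to unit score variance so that high-variance components do not
dominate distances) is the multichannel feature image handed to
segmentation. The default of 25 retained components covers the depth at
which thin-structure information typically appears; requests beyond
`min(n - 1, p, 30)` are capped.

# Active-contour segmentation

ROIs are segmented one at a time with the vector-valued Chan-Vese model: for
a binary mask the energy is

    E(mask) = mu * Perimeter(mask)
            + (1/C) * sum_c [ sum_inside (u_c - c1_c)^2
                            + sum_outside (u_c - c2_c)^2 ]

with `c1`/`c2` the inside/outside channel means, equal channel weights, no
area term, and the perimeter counted as 4-neighbour edges between in- and
out-pixels (off-tissue pixels excluded everywhere). The minimizer prefers
regions that are piecewise-constant in feature space with short boundaries —
robust to noise and independent of edge gradients, which is what makes a
1-2 pixel wide layer segmentable at all.

The update scheme is a deterministic checkerboard coordinate descent: with
the means frozen, every pixel of one parity whose flip strictly lowers the
energy is flipped, then the means are recomputed, then the other parity.
Because 4-neighbours always have opposite parity, the per-pixel flip gains
are exact and additive, and refitting the means can only lower the energy
further — so the energy trace is non-increasing by construction, without any
step-size or reinitialization machinery. The evolution stops at a fixed
point or after `n_iterations` (default 30, sensible range 5-50). The
smoothing factor `mu` is in squared feature units per boundary edge; its
conventional range 0.1-0.3 assumes unit-variance channels, hence the
standardized score stack default. Segmentation is equivariant to affine
channel rescaling when `mu` is rescaled by the squared scale factor.

Refinement fills interior holes (background components, 4-connectivity, not
touching the border) and drops connected components below `min_object_px`.
Masks may overlap; the class map gives a pixel its label only when exactly
one mask claims it, and treats ambiguous or unclaimed pixels as
missing-class observations that are excluded from model fitting but still
receive predicted scores. The "overlap ratio" against a reference mask is
reported as Jaccard (intersection over union), with Dice available as well,
since the literature uses the term for either.

# OPLS-DA and the Q2Y ranking

The class map yields an indicator Y-block (one column per class, one row per
assigned pixel, in pixel order). Both blocks are centered, not scaled. Each
orthogonal component is obtained by fitting one bilinear PLS2 component on
the current X and projecting its X-loading onto the orthogonal complement of
the column space of `X'Y`; by construction the resulting orthogonal scores
satisfy `t_o' Y = 0` exactly (to numerical precision), and X is deflated.
Predictive components are then standard NIPALS PLS2 components on the
filtered X. Defaults: `K - 1` predictive components for `K` classes, one
orthogonal component.

Q2Y uses deterministic venetian-blind cross-validation: row `i` of the
assigned-pixel block goes to fold `((i - 1) mod n_blocks) + 1`, with
`n_blocks = 7` by default. Held-out rows are centered with training means
only, orthogonal-filtered with training weights, and predicted;
`Q2Y = 1 - PRESS/SS` accumulates over folds, reported cumulatively per
predictive component. Setting `n_blocks = n` gives leave-one-out. The
component-selection helper keeps the leading components whose individual Q2Y
gain exceeds a cutoff (default 0.01); lowering the cutoff trades possible
overfitting for sensitivity to small classes carried by later components.
`evaluate_preprocessing()` fits one model per preprocessing spec on
identically-labelled pixels with identical folds and sorts by Q2Y; since the
fold rule and all numerics are deterministic, identical inputs give
bit-identical tables.

# Diagnostics

Per-ROI noise profiles list each peak's mean and sample SD (n-1), sorted by
mean. The heteroscedasticity index is the Spearman rank correlation between
mean and SD: Pearson would be dominated by the heavy right tail of
intensities, while the rank version is invariant to monotone rescaling and
captures exactly the "variance grows with signal" structure that motivates
the ln transform. RSD is SD over absolute mean for one peak within one ROI.
The score-plot confidence oval is the Hotelling T2 ellipse at the
`F(2, n - 2)` critical value, with the fraction of observations strictly
outside. Box-plot statistics use mean-centered intensities, type-7
(linear-interpolation) quartiles and Tukey 1.5 IQR whiskers — stated so the
numbers are bit-stable across runs.

# The phantom

Every claim above is exercised against a synthetic dataset with known ground
truth. Four concentric curved bands on a 96 x 96 grid emulate cerebellar
anatomy — white matter innermost, then granular layer, a 2-pixel Purkinje
cell band (the sensitivity challenge), and molecular layer outermost; curved
rather than straight bands so that boundary smoothing is meaningfully
exercised and rigid seed shifts still overlap the truth. Each region has a
deterministic peak signature (120 peaks at realistic TOF count magnitudes,
1e3 to 1e5): a block of strong peaks shared by WM and GL emulating
sulfatides, an ML-specific block emulating ceramide-1-phosphate, GL-specific
blocks emulating PI 38:3/38:2, and a PCL-exclusive block emulating PI 38:4
with more than fivefold regional contrast.

The noise model is `g_i * mu[r(i), j] * exp(sigma_mult * eps) +
|sigma_add * eta|`: a per-pixel log-normal gain (`sigma_gain = 0.25`)
emulating matrix and ionization artifacts, multiplicative log-normal
measurement noise (`sigma_mult = 0.3`) producing the heteroscedastic
SD-proportional-to-mean structure of real MALDI data, and a half-normal
additive floor. The floor defaults to 1e-4 of the strongest signature
(about 1% of the weakest), the regime of a detector noise floor sitting far
below every analyte peak: a substantially larger floor would re-introduce a
mean-dependent trend in the log-domain SDs of weak peaks and the phantom
would no longer represent the multiplicative-noise regime the method
addresses. All randomness flows from one seed through a saved-and-restored
RNG state. What the phantom does *not* emulate: peak shapes and m/z
profiles, isotopes, detector saturation, spatial noise correlation, or
partial-volume mixing at layer boundaries — so passing tests demonstrate the
machinery, not performance on any particular real tissue.

Seed degradation (`perturb_seeds()`) emulates rough hand-drawn outlines by
eroding each true region and shifting it randomly. Erosion uses the largest
disc radius not exceeding the requested one that keeps the seed non-empty,
so the 2-pixel PCL band degrades to a shifted band rather than erroring; a
shift that pushes a seed entirely off the grid is an error asking for a
smaller perturbation.

# Numerical choices and degenerate inputs

* NIPALS convergence: relative score change below 1e-12, max 500 iterations;
  a vanishing weight vector raises an error advising fewer components.
* Flip threshold in contour evolution: energy gain must exceed 1e-12 to
  avoid cycling on exact ties; a collapse to an empty or full mask returns
  the last valid mask with a warning.
* Constant matrices are rejected by PCA (zero variance); zero-variance
  variables get `NA` correlation in S-plots; zero-mean peaks are an error
  for RSD; degenerate score covariance is an error for the Hotelling
  ellipse.
* TSV dialect: m/z at 4 decimals (beyond instrument precision, so
  round-trips are exact for axes generated at that precision), intensities
  at 15 significant digits, LF newlines — byte-reproducible given identical
  input.

# Problem sizes used by the test-suite

Unit tests run on quarter-size phantoms (48 x 48) where full-size geometry
is not the point; the acceptance checks use the reference 96 x 96 phantom,
10 generator seeds for the stochastic properties, and the exhaustive
2^16-mask comparison on a fixed 4 x 4 instance for the Chan-Vese energy.
These sizes were chosen to exercise every claim at full fidelity while
keeping a complete run in the minutes range on one CPU.

# Known limitations

* One ROI per contour evolution (as when seeding regions individually), not
  multiphase Chan-Vese; overlapping evolved masks are resolved to
  missing-class rather than competed.
* The venetian-blind fold rule uses pixel row order as its deterministic
  proxy; spatially autocorrelated noise can make CV slightly optimistic
  compared to spatially blocked folds.
* Orthogonal-component counts are fixed per evaluation (default 1) rather
  than selected per spec, so the ranking compares like with like; per-spec
  selection is available but changes comparability.
* The component-gain cutoff emulates the behaviour of commercial software
  descriptively; it is a knob, not a significance test.
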