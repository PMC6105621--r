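---
title: "Interhemispheric connectivity and lesion markers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interhemispheric connectivity and lesion markers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemiconn)
```

## The problem

After a unilateral stroke, the lesioned hemisphere loses part of its
spontaneous coupling with the intact hemisphere: seed-based resting-state
functional connectivity (rs-FC) maps computed from the affected primary
sensory (S1) or motor (M1) cortex tend to show mostly ipsi-lesional
connectivity, while maps from the intact hemisphere, or from healthy
controls, are bilaterally symmetric. hemiconn implements the full marker
pipeline that quantifies this: anatomical markers (lesion volume and a
weighted corticospinal-tract lesion load), a functional marker (an
interhemispheric laterality index of suprathreshold connectivity), and the
cohort-level statistics that relate both to clinical impairment scores
(NIHSS, Chedoke-McMaster limb stages).

Because raw patient fMRI for such studies is rarely shareable, the package
ships a synthetic phantom generator whose connectivity structure is planted
at known values, so every stage is testable end to end, plus the printed
eight-patient characteristics table of a published cohort as a worked
example for the statistics.

## Subject-level model

The BOLD run is preprocessed in a fixed order: discard the first `k = 5`
volumes (steady-state), grand-mean scale the 4-D run to 10000, smooth
spatially with a 6 mm FWHM Gaussian, and high-pass filter with a
Gaussian-weighted running-line detrend (`sigma = 100` s). Each of the four
seeds (S1 and M1, affected and non-affected side) is built by thresholding
its probabilistic ROI map at 10% (inclusive) and binarizing; the seed signal
is the unweighted voxel mean.

Per voxel, connectivity is estimated by OLS on a design with an intercept,
the seed series, and nine nuisance regressors: CSF, WM and global mean
signals (tissue maps thresholded at 80% probability) and six motion
parameters. The seed coefficient's t statistic is mapped to a Z statistic by
matching upper-tail log probabilities (accurate far beyond |t| = 8, capped
at |Z| = 38 so perfect fits stay finite). Voxels inside the lesion mask are
excluded from the analysis mask before any statistic, cluster extent or
laterality count.

### Cluster inference

Suprathreshold voxels (`Z > 2.3` at the subject level, `Z >= 3` at the group
level, following the conventional strict/inclusive reading of those
thresholds) are grouped by 26-connectivity. Cluster-wise family-wise error
probabilities come from Gaussian-random-field theory in two steps: the
expected number of clusters is the 3-D Euler-characteristic density at the
forming threshold times the RESEL count (mask volume divided by the product
of per-axis smoothness FWHMs, estimated from the variance of spatial
differences of the standardised GLM residuals), and the null cluster extent
follows an exponential law in a power of the extent.

The classical asymptotic extent law, $P(N \ge k) = \exp(-\beta k^{2/3})$
with $\beta$ tied to the mean extent, is a high-threshold approximation. At
the moderate forming thresholds actually used for cluster inference the mean
cluster is only a few voxels and that law assigns $P(N \ge 1) < 1$ and a
grossly heavy far tail; with it, the empirical family-wise error on
simulated null fields is essentially zero rather than the nominal 5%. We
therefore anchor the law at one voxel, $P(N \ge k) = \exp(-\beta (k^{q}-1))$,
and calibrated the constants by Monte Carlo on null smooth Gaussian fields
across grids of 24-40 voxels, forming thresholds 2.0-3.0 and kernel FWHMs of
2-3 voxels, giving $q = 0.70$ and $\beta = 2.52\, \bar n^{-1.077}$ where
$\bar n = E(n)/E(m)$ is the expected cluster extent. The calibration
settings deliberately exclude the validation setting; `grf_fwe_calibration()`
re-measures the family-wise error out of sample (500 null 32^3 fields of
FWHM 2 at `Z > 2.3`), where the rate sits near nominal (0.03-0.07 across
seeds). The expected-cluster-count and expected-suprathreshold-volume
formulas agree with simulation within a few percent and are used untouched.

The group model is a per-voxel one-sample OLS across subjects' Z maps
(t with n - 1 degrees of freedom, a variance floor guarding degenerate
voxels), not a Bayesian mixed-effects model; outputs carry that provenance
tag.

### Laterality

For the affected-side seed, the laterality index counts suprathreshold
voxels inside the affected-side ROI mask ($n_{AD}$) and inside the homotopic
contralateral mask ($n_{NAND}$):

$$LI = \frac{n_{AD} - n_{NAND}}{n_{AD} + n_{NAND}} \in [-1, 1],$$

+1 meaning purely intra-hemispheric connectivity, 0 symmetry. By default the
input is the GRF-surviving mask; `li_input = "voxelwise"` uses the plain
`Z > z_thr` mask instead, since published descriptions do not always say
which fed the counts. ROI masks must be disjoint; `split_hemispheres()`
assigns midline-crossing masks to hemispheres at the mid-sagittal plane
before counting. Because cluster survival is thresholded, LI responds to
planted asymmetry in a threshold-like rather than smoothly graded way;
the monotone trend across coupling levels is the meaningful signal.

### Weighted tract lesion load

For each voxel where the lesion intersects the positive-probability tract,

$$wLL = \sum_{n=1}^{n_{max}} \tfrac{1}{10}\, I(n) \cdot V_{voxel},$$

with $I(n)$ the tract probability in percent. The printed formula lists a
separate "weighting factor" alongside $I(n)$; the text derives the weight
from the voxel probability, so we read the two as the same quantity stated
twice and implement the weight as $(1/10) I(n)$ — dimensionally a weighted
volume in mm^3. The alternative reading (probability applied twice) is
available as `weighting = "squared"`. The 1/10 factor (a decile convention
of the source atlas) is kept configurable only through that switch; voxels
with zero tract probability never count toward $n_{max}$.

## The phantom generator

`make_phantom_anatomy()` builds a 32 x 32 x 24 grid of 3 mm voxels (roughly
a 10 cm two-hemisphere "brain", small enough that a full subject pipeline
runs in ~3 s on one CPU): an ellipsoidal brain with a CSF shell, GM ribbon
and WM core (smooth probability maps), four bilateral Gaussian-bump ROI
pairs (S1-like, M1-like, occipital and parietal satellites; left and right
maps are exact mirror images by construction), and a tract descending
through the left white matter with a Gaussian cross-section.
`make_lesion()` places an ellipsoidal lesion, with an optional bisection
search of the radius until a requested fraction of lesion voxels falls
inside the suprathreshold tract.

`simulate_bold()` uses a shared-latent-factor model: each homotopic ROI pair
shares a latent signal with side-specific parts,
$x_{side} = \sqrt{c}\, z + \sqrt{1-c}\, u_{side}$, so the planted
inter-hemispheric correlation of the noiseless regional signals is exactly
the coupling $c$ — a closed form the tests use as an oracle. Voxel loadings
taper with the ROI probability map; a per-hemisphere factor, a global
factor, a slow sinusoidal drift, an optional linear leak of the six
motion columns, and white noise complete the series. CSF and WM compartments
receive their own signals so nuisance regression has something real to
remove. Everything is a pure function of (spec, seed). Default conditions —
150 volumes at TR 2.3 s, symmetric coupling 0.8, noise SD 2 at signal
amplitude 5 — correspond to a comfortably detectable resting-state effect;
asymmetry experiments lower the affected S1 pair's coupling only.

What the phantom does *not* model: hemodynamic response shape,
physiological (cardiac/respiratory) noise spectra, scanner drift families
beyond a single sinusoid, field-strength differences, registration error, or
lesion-induced signal dropout. Passing tests therefore demonstrate that the
pipeline recovers planted connectivity structure under realistic noise, not
that it is robust to every artifact of real acquisitions.

`simulate_cohort()` draws lesion volumes and laterality indices uniformly
and generates each clinical score as a linear model plus Gaussian noise,
with Chedoke components clipped to [1, 7] and NIHSS floored at 0; default
coefficients keep clipping essentially inactive so the analytic variance
decomposition (`cohort_population_r2()`) is exact for the recovery tests.

## Cohort statistics

Pearson correlations use pairwise deletion (each cell computed on the rows
complete for that pair), two-sided p from the t(n-2) transform, and flag
|r| > 0.6 as large. The hierarchical regression fits cumulative OLS blocks
on listwise-complete rows, reports per block R^2 (unadjusted and adjusted —
published prose sometimes quotes the adjusted value, so both are emitted),
the R^2 change with
$F_{change} = (\Delta R^2/q) / ((1 - R^2_2)/(n - p_2 - 1))$, and variance
inflation factors from regressing each final-block predictor on the others.
No multiple-testing correction is applied by default (none is conventional
in this table format).

### The bundled example cohort

`example_stroke_cohort()` returns the printed characteristics of eight
chronic-stroke patients used in the worked examples. In the source the
numeric columns are typeset without delimiters, so the table was
reconstructed by enumerating digit splits and validating against the
source's own correlation table; the lesion-size column reproduces those
correlations to within about 0.01 (the residual is the source's own
rounding/internal inconsistency — its printed r of 0.844 implies a simple
R^2 of 0.712 while its regression prose reports 66.1%). The lesion-load
column does not reproduce the source's functional ("wCST") correlation row
under any digit reading, which is consistent with that column being a raw
overlap volume rather than the weighted load used in the correlation table;
`wcst_ll()` emits both quantities for exactly this reason. Correlations
involving the bundled `wcst_ll` column should therefore not be expected to
match the published functional row.

## Numerical choices and degenerate inputs

- Thresholds are inclusive (`>=`) everywhere a probability map is compared
  to a cutoff; cluster forming is strict (`>`) at the subject level and
  inclusive at the group level.
- Smoothing uses half-sample symmetric reflection at boundaries; the
  convolution matrix is doubly stochastic, so constants and the global sum
  are both preserved exactly.
- The high-pass subtracts a per-timepoint Gaussian-weighted line fit and
  restores each voxel's temporal mean; an affine-in-time series is
  annihilated to numerical precision.
- The smoothness estimator converts the variance $v$ of spatial differences
  of standardised residuals through $FWHM = \sqrt{4\log 2 / v}$, which
  degrades gracefully to ~1.18 voxels on white noise instead of collapsing;
  masks, not bounding boxes, define the difference pairs.
- Grid mismatches (shape or voxel size) between any mask/map and its
  reference image are hard errors; there is no implicit resampling.
- Empty seeds (including seeds fully covered by a lesion), empty tissue
  masks, all-subthreshold maps with no ROI counts, rank-deficient designs
  and zero-variance correlation columns all raise informative errors rather
  than returning numbers.
- Mirroring at ingest flips images only; clinical scores are never flipped.

## Problem sizes used in the validation experiments

The packaged experiments run at the study's own scale where that is cheap
(full 32^3-grid phantoms with 150 volumes for the laterality experiment;
500 null fields for the family-wise-error measurement; 200 simulated
cohorts of n = 100 for regression recovery) and at a reduced 24 x 24 x 18 /
60-volume scale for the quick end-to-end pipeline checks, a size chosen so
the default test run stays interactive while still exercising every stage.

## Known limitations

- The GRF extent-law constants are Monte-Carlo calibrated for the
  threshold/smoothness regime of resting-state cluster inference
  (forming thresholds ~2-3, FWHM >= 2 voxels); far outside that regime the
  asymptotic law may be preferable.
- The group model is OLS, not mixed-effects: with very few subjects the
  group Z has few degrees of freedom, and inclusive `Z >= 3` thresholding is
  conservative for n below ~5.
- The laterality index counts voxels, not Z mass; a Z-weighted variant is
  deliberately out of scope.
- The phantom's "brain" is an ellipsoid on a coarse grid; coverage
  percentages and RESEL counts are not comparable to human-scale images.
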