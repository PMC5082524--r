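---
title: "Methods: simulating and analysing a scene localiser at the individual level"
author: "sceneloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing a scene localiser at the individual level}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sceneloc)
```

## What this package computes

`sceneloc` implements, end to end, the statistical workflow used to
characterise scene-selective BOLD responses at the *individual-subject*
level across four regions of interest — parahippocampal gyrus (PHG),
retrosplenial cortex (RSC), transverse occipital sulcus (TOS) and
hippocampus (HC):

1. a block-design first-level GLM per subject (double-gamma HRF,
   Gaussian-weighted running-line high-pass, OLS, contrast Z maps at three
   smoothing levels),
2. voxel-wise thresholding of each subject's scenes > objects map at
   Z = 2.3 / 3.1 / 3.9 intersected with subject-space anatomical ROIs,
3. probabilistic overlap maps (voxel-wise counts of activating subjects in
   template space) with peak, percentage and peak-distance statistics, and
   an anterior/posterior split of hippocampal peaks,
4. group-level one-sample inference with sign-flip permutation
   cluster-extent FWE control, paired effect sizes on percent signal
   change, and Cochran's Q over the subject-by-region scene-preference
   matrix.

Because the raw data of such a study are not available, the package ships
a first-class synthetic cohort generator whose output has exactly the
statistical structure the analyses assume, together with the planted
ground truth needed for recovery and calibration tests.

## The acquisition and design being emulated

The localiser run is 40 contiguous 16-s blocks (640 s): fixation at block
positions 1, 14, 27 and 40, and 36 stimulus blocks arranged as three
category orders — (objects, scenes, scrambled), (scrambled, scenes,
objects), (scenes, objects, scrambled) — each presented four times, so
every category fills 12 blocks. Each block holds 16 one-second trials
(200 ms stimulus + 800 ms ISI). Volumes are acquired at TR = 3 s; the
simulated series covers the post-discard run, `ceiling(640 / 3) = 214`
volumes. One described source lists *four* block orders in a figure
caption while enumerating three in the text; the generator follows the
three enumerated orders (3 orders x 4 repeats x 3 blocks = the stated 36
experimental blocks; four orders would give 48) and exposes the order
list as an argument.

## Signal model of the synthetic cohort

For subject $s$, voxel $v$ and volume time $t$:

$$y_{sv}(t) = B\,\Big(1 + \sum_c a_{sc}\,w_v^{(c)}\,\tilde r_c(t)\Big)
  + d_v \cos(2\pi t/128 + \phi_v) + \varepsilon_{sv}(t)$$

* $B$ — baseline intensity, 1000 arbitrary units.
* $\tilde r_c$ — the condition's HRF-convolved boxcar scaled to unit
  peak-to-peak, so that $a_{sc}$ *is* the planted effect on the
  percent-signal-change scale ($a_{sc}$ = amplitude_pct / 100).
* $w_v^{(c)}$ — a Gaussian blob (FWHM 8 mm, truncated at 3 sigma, unit
  peak) centred on the subject's planted centre for each ROI; scenes and
  objects use the same centres with different amplitudes, scrambled is
  the implicit baseline (amplitude 0).
* drift — a single 128-s cosine whose amplitude (uniform on
  [0.5, 1] x 10 units) and phase are drawn *per voxel*. A spatially
  uniform drift phase would push an identical bias into every voxel's
  contrast and invalidate the across-voxel binomial calibration of the
  null; per-voxel phases make the residual drift behave as independent
  structured noise. The 128-s period sits above the high-pass cutoff, so
  the filter attenuates but does not remove it — deliberately, so the
  filter has work to do.
* $\varepsilon$ — temporally white Gaussian noise, SD 50 units (5% of
  baseline).

Subject variability enters through: jittered effect centres (isotropic
Gaussian, SD 4 mm, clamped to the nearest in-ROI voxel centre), amplitude
draws (scenes 3 +/- 1 %, objects 1.5 +/- 0.5 %, truncated at 0), and a
rigid head offset encoded in the subject-to-template affine.

Three deliberate idealisations:

* **Whole-voxel offsets.** Subject affines are translations by whole
  voxels (up to +/- 4 mm per axis), so nearest-neighbour resampling
  between subject and template space is exactly invertible. Sub-voxel
  registration error is a preprocessing concern that is out of scope
  here; keeping the transform lossless lets recovery tests interrogate
  the statistics rather than the interpolator.
* **Unilateral planting.** ROI masks are bilateral, but effects are
  planted only at the (right-hemisphere) consensus centre of each ROI. A
  mirrored equal-amplitude blob would make the cross-subject overlap peak
  an exact two-voxel tie between hemispheres, resolved arbitrarily by the
  documented raster tie-break; a single planted centre keeps "where is
  the true peak?" well-posed.
* **White noise in time.** No AR structure, physiological noise, motion
  or susceptibility effects — so first-level OLS is exactly correctly
  specified and the null calibration below has an analytic reference.
  Consequences for interpretation: passing tests show the *pipeline* is
  correct and calibrated, not that OLS without prewhitening would be
  well-calibrated on real autocorrelated fMRI noise.

## First-level model

* **HRF**: difference of two gamma densities parameterised by mean lag and
  SD — response lag 6 s, undershoot lag 16 s, both SDs 3 s, undershoot
  ratio 1/6, sampled at 0.1 s and normalised to unit peak. The literature
  names the double-gamma family without parameters; these are the common
  convention, and the sampled kernel peaks near 4.5-5 s.
* **Regressors** are built as unit boxcars over each condition's blocks at
  0.1-s resolution, convolved with the HRF, and evaluated at the exact
  volume times $t = k \cdot TR$ (block onsets are not TR-aligned; no
  slice-timing offset is modelled). The regressor's peak-to-peak height is
  recorded and used as the percent-signal-change scaling factor.
* **High-pass**: at every time point a straight line is fitted by
  weighted least squares with Gaussian weights (SD 50 s) centred there,
  and the fitted value subtracted; the series grand mean is added back so
  that the constant-column beta remains a meaningful baseline for percent
  scaling. Whether the original filter preserved the mean is not
  documented anywhere; the add-back is this package's documented
  convention. The same filter is applied to data and design columns.
* **GLM**: voxel-wise OLS with residual variance SSR / dof. No
  prewhitening (the upstream FILM settings are unstated); this matches
  the white-noise generator exactly and is flagged as a caveat for real
  data. Exact fits (noise-free voxels) are detected by comparing SSR
  against the floating-point scale of the data and treated as
  zero-variance.
* **t to Z**: matched quantile mapping computed in log-tail space,
  `qnorm(pt(|t|, dof, log.p), log.p)`, so |t| up to ~40 maps to finite Z
  with the tail probability preserved exactly. Zero-variance voxels give
  Z = 0 when the contrast is (numerically) zero and are capped at
  +/- 8.2 when an exact fit carries a real effect.
* **Smoothing** (0 / 2 / 5 mm FWHM) is separable Gaussian convolution of
  the data volumes with zero padding, kernel truncated at 4 sigma and
  normalised to unit sum; 0 mm is the identity. Smoothing the data and
  refitting matches the convention of smoothing before analysis.
* **Percent signal change**: `100 * (beta_cond - beta_scrambled) * height
  / baseline`, averaged over ROI voxels. Note the ROI average is *diluted*
  relative to the planted peak amplitude because the 8-mm blob covers only
  part of each ROI; tests that check amplitude recovery therefore evaluate
  at the planted centre voxel.

## Individual-level localisation

Thresholding is strict and one-sided (Z > threshold); the boundary case
affects only measure-zero events but is documented. Clusters are
connected components under 26-connectivity by default (6 and 18 are
available), labelled via a vectorised neighbour-edge list and graph
components. All in-ROI peaks are reported as voxel-centre world
coordinates; ties are broken by the smallest linear index in raster order
(x fastest, then y, then z), a deterministic and documented rule.
Individual-level maps are uncorrected voxel-wise thresholds — no
cluster-extent pruning at this level. The hippocampal long axis is split
at a configurable y (default -21 mm, the conventional uncal-apex level;
the exact level is not stated in the described work), with the boundary
counting as anterior; the split value is echoed into all outputs.

## Overlap mapping

Each subject's unsmoothed binarised map is resampled to template space
through that subject's affine (nearest neighbour — exact here, see the
whole-voxel idealisation) and summed voxel-wise. Overlap percentages are
reported relative to the number of subjects with *any* significant in-ROI
voxel at that threshold, rounded half away from zero to match printed
whole-number percentages. Peak-to-peak distances are Euclidean in
template mm, reported to 0.1 mm.

## Group level

Mixed-effects weighting schemes of the FLAME type require per-subject
variance maps that this pipeline deliberately does not model, and
Gaussian-random-field cluster p-values are out of scope. Both are
replaced by fully specified standards: a one-sample
OLS t across subjects' 5-mm-smoothed contrast maps (t -> Z as above;
zero-variance voxels capped at +/- 8.2), and cluster-extent FWE control by
sign-flip permutation — valid under symmetric errors, which the generator
guarantees. Thresholding is performed on the equivalent t scale
(`t_form = qt(pnorm(z_form))` at the group dof) so observed and permuted
statistics are treated identically; a cluster is retained iff its
permutation p-value `(1 + #{null max >= size}) / (n_perm + 1)` is at most
alpha. `n_perm` defaults to 199 so that the p-value grid contains 0.05
exactly (10/200).

Two discreteness facts matter and are verified by the calibration
experiments:

* On *unsmoothed white noise* the null maximum cluster extent concentrates
  on a few small integers (sizes 3-5 on the default calibration grid), so
  the exact test is conservative — the attained FWE level falls to
  roughly half the nominal alpha purely through ties. The null
  calibration experiment therefore draws its noise maps at the 5 mm
  smoothness the group stage actually operates at, where null extents are
  tens of voxels, tie mass is negligible, and the attained level sits at
  the nominal 0.05. Both regimes are available via `smooth_fwhm_mm`.
* Exact-voxel recovery of a planted consensus location by the overlap
  *argmax* is intrinsically hard on a 2 mm grid under an 8 mm effect
  blob: the activation probability 2 mm from the centre is 0.84 of the
  centre's on the Z scale, so adjacent voxels are nearly indistinguishable
  with 20 subjects, and count ties resolve by raster order. A Monte-Carlo
  of the exact probability model bounds per-replicate success near 50-55%
  under the recovery conditions (3% planted scene amplitude, 5% noise),
  and `overlap_recovery_experiment()` measures exactly that. The
  recovery experiment is still informative — the peak is always in the
  immediate neighbourhood of the planted centre, and the companion
  monotonicity check (activation frequency non-increasing in threshold)
  holds in every run — but a >= 95% exact-voxel requirement is not
  achievable under these conditions and the corresponding assertion is
  expected to fail, with the measured rate reported honestly.

Cochran's Q over the subject x region scene-preference matrix uses the
defining sums with df = k - 1 (reports of this statistic sometimes print
df = k; k - 1 is correct) and defines Q = 0, p = 1 when every row is
constant. Exact scene/object PSC ties score 0 in the preference matrix.
Paired t and Cohen's d (mean/SD of differences) are reported per ROI
without multiplicity correction, matching the reporting convention being
emulated. Printed effect sizes in the source material are mutually
inconsistent with both d = t/sqrt(n) and d = mean/SD of differences, so
no numeric d value is used as a test target.

## Template geometry

The template is a desk-scale stand-in for a 2 mm standard space: a
40 x 48 x 40 grid (default; all analyses also run on 30 x 36 x 30) with
the origin placed so world coordinates span negative and positive values,
mimicking template-style mm coordinates. ROIs are bilaterally mirrored
analytic shapes at fixed documented coordinates — spheres for PHG
(+/-18, -16, -8; r 5 mm), RSC (+/-10, -30, 12; r 4 mm) and TOS
(+/-24, -32, 18; r 4 mm), and a y-elongated tube for HC (x = +/-24,
z = -16, y in [-28, -4], r 3.5 mm) so the anterior/posterior split is
meaningful. Construction fails loudly if the grid cannot hold all four
masks disjointly. These shapes reproduce the *relational* facts the
analyses rely on (disjointness, bilaterality, an elongated HC) and none
of the anatomy.

## Problem sizes

The shipped experiments use sizes chosen to make every statistical claim
measurable with tight Monte-Carlo error while staying desk-scale: unit
tests run on 6-16 voxel grids; the calibration and recovery experiments
use 30 x 36 x 30 grids with cohorts of 10-20 subjects, 200 replicates for
FWE calibration and 20 seeded replicates for recovery; the narrative
analysis scripts use 12 subjects. All of them are driven by explicit
seeds, and full-cohort generation is a pure function of the cohort spec.

## Known limitations

* OLS without temporal autocorrelation modelling is only exactly valid
  for the white-noise generator, not for real fMRI noise.
* Nearest-neighbour resampling is exact only because subject offsets are
  whole voxels; with general affines it would introduce boundary effects
  the tests do not cover.
* The overlap consistency statistics inherit the integer-count
  granularity discussed above; with small cohorts the percentage of
  active subjects at the peak is a coarse quantity.
* The generator makes no attempt at realistic anatomy, physiological
  noise, motion or slice timing; conclusions from synthetic runs are
  about the statistical machinery.
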