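# sceneloc

Individual-level consistency of scene-selective fMRI activations:
simulation and analysis of a block-design functional localiser targeting
the scene-processing network — parahippocampal gyrus (PHG), retrosplenial
cortex (RSC), transverse occipital sulcus (TOS) and hippocampus (HC).

Group-average maps say little about how *often* and how *consistently*
single subjects activate a region. This package implements the workflow
that answers those questions: per-subject GLMs thresholded at several
voxel-wise criteria and smoothing levels, intersected with
subject-specific anatomical ROIs; probabilistic overlap maps whose value
at each voxel counts the subjects activating there; and group-level
inference to compare against. Because raw data for such studies are
rarely deposited, the package includes a first-class synthetic BOLD
cohort generator with planted, spatially jittered scene-selective
effects and full ground truth, so every statistical claim is testable by
parameter recovery and calibration experiments. It is aimed at
neuroimaging methodologists and at anyone teaching or stress-testing
localiser analysis pipelines.

## The model

Per subject, the voxel-wise time series is modelled as

    y_v = X beta_v + e_v,     X = [r_scenes, r_objects, r_scrambled, 1]

where each regressor is a 16-s boxcar over that condition's blocks
convolved with a double-gamma HRF (response lag 6 s, undershoot lag 16 s,
SD 3 s, ratio 1/6) and sampled at the volume times (TR = 3 s, 214
volumes over the 640-s run: 36 stimulus blocks + 4 fixation blocks of
16 s). Data and design are high-passed by Gaussian-weighted running-line
fitting (sigma = 50 s). Contrast statistics

    t_v = c'beta_v / sqrt(sigma2_v c'(X'X)^-1 c),   Z_v = Phi^-1(T_dof(t_v))

are converted to the normal scale in log-tail space. Individual maps are
binarised at Z > 2.3 / 3.1 / 3.9 (smoothing 0 / 2 / 5 mm FWHM); the
overlap map is the voxel-wise sum of the subjects' binarised unsmoothed
maps in template space. Group inference is a one-sample t over subject
contrast maps with sign-flip permutation cluster-extent FWE control
(cluster-forming Z = 2.3, alpha = 0.05), plus paired t / Cohen's d on
ROI percent signal change and Cochran's Q (df = k - 1) over the
subject-by-region scene-preference matrix.

## Worked example

The `analysis/` directory is a numbered workflow over a 12-subject
synthetic cohort (run from the repository root, in order):

```sh
Rscript analysis/01_simulate.R      # cohort ground truth + schedule
Rscript analysis/02_first_level.R   # GLMs, Z maps, PSC, overlap counts
Rscript analysis/03_localisation.R  # activation frequencies
Rscript analysis/04_overlap.R       # overlap consistency statistics
Rscript analysis/05_group.R         # group Z, permutation FWE, Q test
```

Stage 3 prints the proportion of subjects with significant scenes >
objects clusters per ROI (columns: 0, 2, 5 mm smoothing):

```
  PHG  Z=2.3   1.00  1.00  0.92
  PHG  Z=3.9   0.17  0.25  0.67
  HC   Z=2.3   1.00  1.00  0.92
  HC   Z=3.9   0.25  0.25  0.58
```

— at the liberal threshold virtually every subject activates PHG and HC,
while the stringent threshold separates the regions, and the proportions
are non-increasing in the threshold in every ROI (asserted in the
script). Stage 4 locates each ROI's overlap peak and its distance to the
group peak, e.g.

```
  HC   Z=2.3  peak  4/12 active ( 33%) at (24, -14, -16),  3.5 mm from
              group peak; 100% of HC peaks anterior
```

meaning 4 of the 12 activating subjects share the modal hippocampal
voxel, 3.5 mm from the group-level peak, with all individual peaks
anterior to the long-axis split at y = -21. Stage 5 ends with

```
  HC   peak Z  3.21 at (22, -12, -14) [FWE-significant cluster];
       scenes vs objects t(11) = 3.02, d = 0.87
scene preference per ROI: PHG 11/12, RSC 12/12, TOS 10/12, HC 9/12
Cochran's Q = 5.00, df = 3, p = 0.172
```

— every ROI carries a significant group-level scene preference, and the
proportion of scene-preferring subjects does not differ detectably
between regions. Outputs (TSV tables, NIfTI maps, JSON provenance) land
under `results/`.

The same machinery is available as a single call:
`run_pipeline(validate_config(list(n_subjects = 6)))`.

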