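Package: sceneloc
Title: Individual-Level Consistency of Scene-Selective fMRI Activations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of block-design functional localiser
    experiments targeting the scene-processing network (parahippocampal
    gyrus, retrosplenial cortex, transverse occipital sulcus, hippocampus).
    Provides a synthetic multi-subject BOLD cohort generator with planted,
    spatially jittered scene-selective effects; first-level voxel-wise GLM
    fitting with double-gamma haemodynamic response modelling,
    Gaussian-weighted high-pass filtering and spatial smoothing;
    ROI-constrained thresholding, connected-component clustering and peak
    extraction; probabilistic activation-overlap mapping with consistency
    statistics; and group-level one-sample inference with sign-flip
    permutation cluster-extent family-wise error control, plus Cochran's Q
    and paired effect-size summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
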