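Package: myeloFlow
Title: Flow-Cytometric Ki-67 Proliferation and Bcl-2 Anti-Apoptotic Indices
    in Myeloid Bone-Marrow Populations
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Hierarchical gating of bone-marrow flow-cytometry data for
    CD34+ blast, erythroid, myeloid (granulocytic) and monocytic populations,
    with Ki-67 proliferation and Bcl-2 anti-apoptotic indices computed under
    four positivity-gating strategies (control-anchored polygonal and
    rectangular gates, and fixed 40/100 fluorescence-unit thresholds).
    Includes FCS 3.0/3.1 event-file reading and writing (including the
    Beckman Coulter LMD dialect), spillover compensation, backbone-marker
    tube merging with nearest-neighbour imputation, acquisition QC rules,
    normality-dependent cohort statistics, and a calibrated synthetic
    bone-marrow cohort generator with per-event ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, ggplot2, xml2, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'panel.R'
    'fcs-io.R'
    'fixtures.R'
    'synthetic.R'
    'gating.R'
    'positivity.R'
    'merge.R'
    'stats.R'
    'pipeline.R'
    'gatingml.R'
    'myeloFlow-package.R'
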