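Package: strokeIR
Title: Perfusion Mapping, Lesion Volumetry and Mitochondrial Assays for
    Mouse Stroke Ischemia-Reperfusion Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis chain for preclinical middle cerebral
    artery occlusion (MCAO) studies in mice: per-voxel burst-replenishment
    kinetic fitting of dynamic contrast-enhanced ultrasound (CEUS) with
    automatic area-at-risk segmentation by relative hypoperfusion
    threshold; edema-corrected (Gerriets) lesion volumetry normalized to
    the area at risk; mitochondrial calcium-retention-capacity and
    substrate-inhibitor-titration respirometry trace analysis; and the
    cohort-level nonparametric statistics (median/IQR summaries,
    Mann-Whitney, Kruskal-Wallis, chi-square on neuroscore categories,
    lesion-CRC correlation, covariate-adjusted lesion-vs-AAR comparison,
    a-priori sample size). A synthetic-data module generates every input
    with known ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'ceus-perfusion.R'
    'cohort-stats.R'
    'io.R'
    'lesion-volumetry.R'
    'methods-accessors.R'
    'mito-assays.R'
    'synthetic-cohort.R'
    'pipeline.R'
    'strokeIR-package.R'
    'synthetic-ceus.R'
    'synthetic-traces.R'
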