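Package: vlsmap
Title: Voxel-Based Lesion-Symptom Mapping with Permutation Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Voxel-based lesion-symptom mapping (VLSM) for cohorts of
    fuzzy lesion probability maps registered to a common template.
    Associates per-voxel tumor probability with severe neurocognitive
    deficit via one-sided two-sample t maps and relative-risk maps,
    with permutation inference: strict family-wise control from the
    minimum-statistic null, a power-favouring extreme-percentile
    variant (Perm95), per-voxel permutation p-values with
    Benjamini-Hochberg q-values, and exhaustive enumeration for small
    cohorts. Includes severity grading of neuropsychological test
    scores, atlas-parcel coverage summaries and heatmaps, a synthetic
    lesion-cohort generator with planted effects for validation, and a
    reproducible end-to-end pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
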