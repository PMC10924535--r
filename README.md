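# vlsmap

Voxel-based lesion-symptom mapping (VLSM) with permutation inference, for
cohorts of fuzzy lesion probability maps registered to a common template.

## What it does

In brain-tumor cohorts, each patient's lesion segmentation is warped to a
template, so every brain voxel carries a distribution of tumor
probabilities across patients. To ask *which locations are associated with
severe deficit in a neurocognitive domain* (attention/executive function,
language, memory, visuospatial abilities, visuomotor speed), subjects are
split into an **affected** group (severe deficit, worst test z-score
< −2) and a **control** group (everyone else), and at every voxel the two
groups' tumor-probability distributions are compared:

- a one-sided pooled two-sample **t map**,
  t = (x̄_control − x̄_affected)/SE, where excess tumor probability in the
  affected group gives t < 0;
- a **relative-risk map**, RR = (a/n_a)/(c/n_c), after binarizing each
  fuzzy mask at a threshold (default 0.03).

Inference is by permutation of the exchangeable group labels:

- **min-stat** — null histogram of the per-permutation *minimum* t over
  the brain (maxT-type strict family-wise error control);
- **Perm95** — null histogram of the per-permutation *5th percentile* of
  the voxelwise t values, trading strict FWE control for power at
  realistic sample sizes;
- **per-voxel** — uncorrected per-voxel permutation p-values (the usual
  companion of RR) with Benjamini–Hochberg q-values.

Small designs are enumerated exhaustively (all C(N, n_a) assignments)
instead of sampled. Significant voxels are mapped onto labelled atlases as
percentage parcel involvement, ranked, and assembled into parcel × domain
heatmap matrices.

A synthetic cohort generator (spherical, Gaussian-smoothed lesions with a
planted effect region driving simulated test scores) provides ground truth
for every stage, so the whole pipeline is testable without patient data.

## Worked example

```r
library(vlsmap)

cfg <- sim_config(grid_shape = c(24, 24, 24), seed = 1)  # 100 subjects
sim <- simulate_cohort(cfg)                 # fuzzy lesions + ground truth
scores <- simulate_scores(sim$cohort, sim$truth, cfg)
assessments <- assess_scores(scores, subjects = sim$cohort$subject_ids)
groups <- build_groups(assessments, "language",
                       subjects = sim$cohort$subject_ids)
groups
#> Groups [language]: 28 affected vs 72 control

fit <- vlsm(sim$cohort, groups, statistic = "t", inference = "perm95",
            n_permutations = 1000, seed = 1)
fit
#> Voxel-based lesion-symptom map
#>   statistic: t   inference: perm95
#>   groups: 28 affected vs 72 control [language]
#>   valid voxels: 5232 of 5232 in brain mask
#>   significant voxels at alpha=0.05: 921
#>   significant voxels at alpha=0.2: 1022

atlas <- make_atlas(sim$cohort$space, 24, seed = 3)
cov <- parcel_coverage(fit$masks$alpha_0.2, atlas, domain = "language")
head(top_parcels(cov, 5)[, c("parcel", "class", "parcel_voxels",
                             "coverage_percent")])
#>       parcel       class parcel_voxels coverage_percent
#> 1  parcel_01    cortical           417         49.40048
#> 2  parcel_02 subcortical           318         38.99371
#> 8  parcel_08    cortical           221         37.55656
#> 24 parcel_24    cortical           270         35.55556
#> 6  parcel_06    cortical           311         31.83280
```

28 of 100 subjects are graded severe in the language domain and form the
affected group. The Perm95 test finds 921 voxels significant at the
statistical threshold (p < 0.05) and 1022 at the exploratory clinical
threshold (p < 0.2); the top-ranked parcel has about half of its voxels
inside the significant set. `plot(fit)` renders an axial montage of
−log10 p with the significant voxels marked, `save_map(fit$p, "p.nii.gz")`
writes any map as NIfTI with a JSON sidecar, and `run_pipeline()` executes
all five domains end to end into a directory of artifacts whose rerun is
byte-identical under the same seed.

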