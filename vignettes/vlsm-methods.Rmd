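---
title: "Voxel-based lesion-symptom mapping with permutation inference: methods"
author: "vlsmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-based lesion-symptom mapping with permutation inference: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vlsmap)
```

## The problem

In cohorts of brain-tumor patients, neurocognitive function (NCF) is
assessed in distinct domains — attention/executive function, language,
memory, visuospatial abilities, visuomotor speed — and the question is which
brain locations, when lesioned, are associated with deficit in each domain.
Voxel-based lesion-symptom mapping (VLSM) answers this at voxel resolution:
after registering every patient's lesion segmentation to a common template,
each voxel carries a *distribution of tumor probabilities across patients*
(segmentations become fuzzy, [0, 1]-valued, after warping), and at each
voxel the distributions of the deficit ("affected") and non-deficit
("control") groups are compared.

`vlsmap` implements this analysis end to end for fuzzy lesion cohorts:
severity grading of test scores, group construction, voxelwise statistics,
permutation inference with several family-wise strategies, and atlas-parcel
summaries — plus a synthetic cohort generator with a planted, known effect
so every stage can be validated without patient data.

## Grouping: severe deficits only

Per-test z-scores are banded as severe ($z < -2$), mild/moderate
($-2 \le z \le 0$) and normal ($z > 0$); tests without norms may carry a
subjective grade in the same three bands. A domain's severity is the *worst*
of its tests, and a subject is "affected" in a domain if and only if that
worst severity is severe; everyone else — including mild/moderate deficits —
is a control. Restricting "affected" to severe deficits buys a cleaner
group contrast at some cost in sensitivity, since the normal/mild boundary
is far less reliable than the severe one.

Two boundary conventions are ours (the bands above are open intervals and
leave the boundaries undefined): $z = -2$ and $z = 0$ are both assigned
mild/moderate, i.e. resolved *away* from the affected group, consistent
with the principle that only unambiguous severe deficits define caseness.
Subjects with no administered test in a domain are unassessable there and
are excluded from that domain's analysis with a warning (not silently
dropped, and never imputed).

## Voxelwise statistics

Writing $x_v^{(a)}$, $x_v^{(c)}$ for the tumor probabilities of affected
and control subjects at voxel $v$:

* **t map** — the pooled-variance two-sample statistic
  $t_v = (\bar{x}_v^{(c)} - \bar{x}_v^{(a)}) / s_v\sqrt{1/n_a + 1/n_c}$,
  signed so excess tumor probability in the affected group gives $t_v < 0$;
  the alternative of interest is one-sided (negative). Fuzzy probabilities
  enter as-is — no thresholding. We default to the pooled (Student) form,
  the classical default when nothing is known about variance structure; a
  Welch option (`var_equal = FALSE`) is available, and the permutation
  null makes the choice non-critical because whatever statistic is chosen
  is recomputed under relabeling. Voxels with zero pooled variance
  (typically: no lesion mass in any subject) are invalid and excluded
  everywhere downstream; they are stored as `NaN` in outputs.
* **Relative risk (RR)** — each subject's fuzzy mask is binarized at a
  threshold (default 0.03, a value low enough to count any appreciable
  registered tumor mass as "tumor present"); with $a$ of $n_a$ affected and
  $c$ of $n_c$ control subjects tumor-positive at $v$,
  $\mathrm{RR}_v = (a/n_a)\,/\,(c/n_c)$. We use the ratio of
  *proportions*, not raw counts: counts are incomparable between groups of
  different size. Probability exactly at the threshold counts positive
  (closed lower bound; stated because it is otherwise ambiguous).
  $c = 0 < a$ yields $+\infty$, a defined and valid value; $a = c = 0$
  leaves the voxel invalid.

## Permutation inference

Under the voxelwise null the group labels are exchangeable, so relabeling
subjects (preserving group sizes) and recomputing the whole statistic map
builds an empirical null without distributional assumptions. Three
strategies are provided:

* **min-stat (maxT-type)** — per permutation, record the *minimum* t over
  valid voxels. Comparing each observed $t_v$ with this histogram gives
  strong family-wise error (FWE) control, but at moderate $n$ the null
  minima are so extreme that little can reach significance.
* **Perm95** — per permutation, record the *5th percentile* of the
  voxelwise t values instead of the minimum (the 95th percentile of
  extremeness for a left-tailed statistic; `percentile_q` exposes the
  percentile on the t scale). This deliberately relaxes strict FWE control
  to regain power at realistic sample sizes; its family-wise error lies
  between the min-stat and uncorrected rates, which is exactly what the
  null-calibration study (`fwe_study()`) measures.
* **per-voxel** — each voxel compared only with its own permutation
  distribution (the usual companion of the RR statistic), with
  Benjamini–Hochberg q-values for FDR control across voxels
  (`stats::p.adjust`).

Numerical conventions, all deliberate:

* Monte-Carlo p-values use the $(1 + \#\{\text{more extreme}\})/(B + 1)$
  correction, so $p > 0$ always and the test is exactly valid. When
  $\binom{N}{n_a}$ is small (default limit 20000) the full assignment
  enumeration replaces sampling; the identity assignment is part of the
  enumeration and the divisor is the assignment count.
* Ties count toward the extreme tail ($\le$ left / $\ge$ right), and
  $+\infty \ge +\infty$ holds, so tied or infinite RR values are handled
  conservatively.
* Percentiles interpolate linearly between order statistics
  (`quantile type 7`); nearest-rank is available (`interpolate = FALSE`).
* A permutation that renders a voxel's t undefined (zero pooled variance
  under that relabeling, while the total variance is positive) contributes
  no count at that voxel in per-voxel mode and is dropped from that
  permutation's whole-brain summary — a rare, conservative degeneracy.
* Significance is strict: $p < \alpha$, with $\alpha \in \{0.05, 0.2\}$ by
  default (the conventional statistical threshold and the more exploratory
  "clinically significant" one).

## Parcel summaries

Significant voxels are mapped onto integer-labelled cortical/subcortical
atlases; a parcel's involvement is
$100\,\lvert \mathrm{sig} \cap \mathrm{parcel} \rvert / \lvert
\mathrm{parcel} \rvert$ percent. Ranking is by coverage percent with ties
broken by parcel size (larger first) then label; the top 15 is the
conventional report, and heatmap matrices take the union of each domain's
top parcels (40 for cortical atlases, all for subcortical). Voxels outside
every parcel are kept in a residual row so that voxel counts are conserved
and auditable. Coverage ranking is purely geometric; it does not attempt
to weight small-but-critical parcels.

## The synthetic generator

`simulate_cohort()` emulates the data contract of a registered glioma
cohort, not tumor biology:

* brain mask: an ellipsoid with semi-axes $0.45\times$ the grid (a
  deterministic template stand-in);
* one spherical lesion per subject, radius uniform in a range whose
  default is 3–7 voxels at the reference $32^3$ grid and scales with
  `min(grid)/32` elsewhere, keeping lesions at the glioma-realistic
  ~1–10% of brain volume at any resolution;
* Gaussian smoothing ($\sigma = 1.5$ voxels, separable convolution) and
  peak rescaling produce fuzzy [0, 1] values like warped segmentations;
* a spherical *effect region* (default: radius `min(grid)/5`, offset
  0.18·grid along x) is the planted ground truth: affected subjects'
  lesion centres fall inside it with probability `effect_strength`
  (default 0.9), otherwise — and for controls always — uniformly in the
  mask. At `effect_strength = 0` the two groups' lesion processes are
  identical, so ground-truth labels are exchangeable and the global null
  holds exactly;
* scores: for each of 5 domains × 2 tests,
  $z = \varepsilon - \delta\cdot\mathrm{overlap}$ with
  $\varepsilon \sim N(0, 0.5^2)$ and overlap the mean lesion probability
  in the domain's effect region. The slope $\delta$ defaults to
  $2.5/0.25$ (involvement above 25% drives the deterministic part past
  the severe cutoff); `calibrate_deficit_shift()` instead derives
  $\delta$ from the generator's own geometry so that a target fraction
  (default 60%) of affected subjects is expected to be graded severe.
  Other defaults chosen once as study conditions: 100 subjects, 40
  affected, 24 Voronoi parcels.

Scores are coupled to lesion *overlap*, not to the group label — so
score-derived groups are exchangeable only when lesions carry no location
signal at all; the null-calibration studies therefore group by the
generator's truth labels, which are independent of lesion placement when
`effect_strength = 0`.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: anatomy-shaped, multifocal or infiltrative
lesion growth; spatially correlated registration error; covariate
structure (age, volume, histology); domain-specific test batteries. The
validation shows the *inference machinery* is correct and calibrated under
a known truth, not that any particular clinical map is correct.

## Validation design and problem sizes

The test suite validates every statistic against independent oracles
(closed-form t on printed examples, `t.test` in double loops, full
assignment enumeration on 2v2/3v3/4v4 cohorts, a textbook BH
implementation) and then measures operating characteristics at sizes
chosen to make the suite fast while keeping Monte-Carlo error quantifiable:
type-I error over 200 simulated 40-subject cohorts on $16^3$ grids with
199 permutations; p-value validity via a one-sided Kolmogorov bound
(permutation p-values are discrete and conservative, so only
anti-conservative deviation counts against them); and effect recovery on a
100-subject $24^3$ cohort with 1000 permutations.
`scripts/acceptance.R` recomputes the same quantities from scratch.

## Known limitations

* **Mislocalization by lesion extent.** Lesions are spatially extended, so
  any voxel within lesion reach of a deficit-driving region genuinely
  differs between groups. The recovered significance mask is therefore the
  effect region *dilated by the lesion kernel*: in our recovery runs the
  $\alpha = 0.2$ Perm95 mask captures nearly the whole planted region
  (sensitivity ≈ 1) while flagging a surrounding halo that caps voxel
  specificity near 0.9 against the undilated region. This is a property of
  lesion data, not of the inference; it is the classical spatial
  autocorrelation caveat of lesion-symptom mapping.
* Perm95 controls family-wise error only loosely by construction; its FWE
  sits far above the min-stat rate under the null (measured by
  `fwe_study()`), which is the accepted price of its power. Use min-stat
  when strict FWE control is required.
* No covariate adjustment (lesion volume, age) and no spatial modelling
  (cluster inference, TFCE); per-voxel tests treat voxels independently.
* Sub-voxel geometry, anisotropic voxels and surface-based analysis are
  out of scope; statistics are computed in voxel space.
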