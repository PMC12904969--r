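---
title: "Regional volumetry and hierarchical FDR: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional volumetry and hierarchical FDR: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphofdr)
```

`morphofdr` implements the statistical core of a deformation-based
morphometry (DBM) association study: probability-weighted regional
volumetry, covariate-adjusted per-region linear models, and a
tree-structured multiple-testing procedure over a hierarchical brain
atlas.  This vignette is the package's own account of the methods: what
is computed, under which assumptions, which parameters matter, and
where the design was genuinely open.

## From deformation fields to regional volumes

The package's entry point on the imaging side is the *local volume
ratio* (LVR) map: one voxel grid per subject, in a common reference
space, whose value at voxel $x$ is the ratio of the subject's local
tissue volume to the reference brain's.  Upstream steps — brain
extraction, affine and non-linear registration, the derivation of the
LVR map from the deformation field, and the manual ICV segmentation —
are out of scope; `morphofdr` consumes LVR maps (and the ICV covariate)
as given.

A region $R$ with probabilistic map $p_R$ has subject volume

$$V_R = v \sum_x p_R(x)\,\mathrm{LVR}(x),$$

with $v$ the voxel volume in mm³ (`region_volume()`).  Two properties
follow immediately and are property-tested: linearity in the LVR map,
and exact recovery of the reference atlas volume $v\sum_x p_R(x)$ when
$\mathrm{LVR} \equiv 1$.  Boundary voxels are used exactly as stored in
the probability map; no interpolation or resampling is attempted, and a
grid mismatch is an error rather than a resample.

Superordinate regions are defined by a `region_tree`: a rooted
hierarchy whose leaves are the elementary areas and nuclei carrying
probabilistic maps.  Their volumes are computed by *summing child
volumes* bottom-up (`aggregate_volumes()`) rather than by constructing
merged parent maps.  For disjoint child maps the two are identical; for
overlapping probabilistic maps the child-sum convention counts each
child's probability mass independently.  We chose it because it makes
hierarchical conservation (every internal node equals the sum of its
children, hence of its leaves) hold exactly by construction — a
property the testing procedure's aggregate family method relies on.

The tree is stored as a JSON array of `{name, parent, is_elementary,
map_ref}` records; a flat parent-pointer format is unambiguous to
parse and trivially diffable.  Hemispheres are ordinary subtrees with
no special lateralisation logic.  The bundled `toy_hierarchy()` (39
regions, 21 elementary, 6 levels, bilateral) mimics the *structure* of
cytoarchitectonic atlas hierarchies — brain over
telencephalon/brainstem/cerebellum, down through lobes and gyri to
areas — without claiming anatomical fidelity or region counts; real
atlas distributions are deliberately not redistributed here.

## Per-region models

All models are ordinary least squares with the region volume (mm³) as
response (`fit_region_models()`):

* **group**: volume ~ group + site + age + ICV, over all subjects;
* **factors**: volume ~ f1 + f2 + site + age + ICV, within the
  psychopathic group — one joint model, so each PCL-R factor is tested
  after adjustment for the other;
* **total**: as above with the PCL-R total score.

Assumptions are the usual ANCOVA ones: linear covariate effects, no
interactions (none are fitted), homoscedastic errors, and a site effect
that is purely additive.  Tests are two-sided throughout; direction is
carried by the sign of $t$.  Numerical choices:

* Site enters as treatment-coded dummies with the *largest* site as
  reference.  Inference on the group/score coefficients is invariant to
  the coding (tested to 1e-10), so this is presentation only.
* Covariates are entered uncentred; centring only moves the intercept.
* Subjects with any missing required covariate are dropped listwise
  with a message and a recorded count.
* A rank-deficient design raises an error naming the collinear
  columns; it is never silently repaired.
* The group difference is also reported as a percentage,
  $100\,\hat\beta_{\text{group}}$ divided by the *adjusted control
  mean*: the average model prediction with the group indicator set to
  control and all other covariates at their observed values.  A
  percentage needs a denominator and this one is stable, uses the
  fitted model only, and keeps the sign of the coefficient (asserted as
  an invariant).

Summary-statistic utilities (`anova_from_summary()`,
`cohens_d_from_summary()`, `corr_pvalue()`) reconstruct one-way
ANOVA F statistics, Cohen's d and correlation p-values from printed
group moments, so published cohort tables can be checked without raw
data.  They operate on rounded inputs, so agreement with published
values is expected only to print precision (the acceptance tests use
2% relative tolerance).  One known inconsistency is deliberately not
asserted: the emulated study's printed PCL-R-total F across sites
(19.264) is irreconcilable with a one-way ANOVA rebuilt from the same
row's printed means/SDs/ns (≈24.4); the utilities take no side.

## The hierarchical testing procedure

Hypotheses (regions) are arranged in the atlas tree; a *family* is the
set of children sharing a parent.  A family's p-value is either

* **Simes**: $p_{\text{Simes}} = \min_j p_{(j)} N / j$ over the sorted
  member p-values — exact under independence, sensitive to strong
  focal effects; or
* **aggregate**: the family's volumes are summed per subject and the
  regional model is fitted to the sum — more sensitive to diffuse
  effects spread over the family.  Because internal volumes are child
  sums, this equals testing the parent's own volume column.

Defaults follow the use-case the package was built for: aggregate
families for the group comparison, Simes for the score regressions,
initial threshold $q_0 = 0.05$.

`run_hierarchy()` proceeds top-down.  The root is a family of size one
and must pass $p_{\text{root}} \le q_0$ before any descent.  Within
each family of children of a discovered node, Benjamini–Hochberg is
applied (step-up; boundary ties are rejected together).  In **strict**
mode the threshold shrinks below each tested family by its discovered
fraction, $q_l = q_{l-1}\cdot\#\text{discoveries}/\#\text{children}$;
zero discoveries terminate descent with no rescue rule.  In
**relaxed** mode the threshold stays at $q_0$ on every level, but a
region is still only considered if its whole path from the root is
discovered; relaxed discoveries are therefore always a superset of
strict ones (tested).

Three readings of the procedure were genuinely open and are fixed here:

* *Threshold propagation.*  The level-wise reduction is applied
  path-locally: each family inherits the threshold propagated along
  its own ancestry.  When discovery fractions are balanced this
  coincides with a single per-level threshold, and it is the only
  reading that stays consistent when one level mixes families with
  different ancestries.
* *Internal Simes p-values* are computed bottom-up: an internal node's
  p is Simes over its children's (family) p-values, recursively from
  the leaves.  The alternative — Simes over the pooled set of all
  descendant elementary p-values — is noted but not implemented.
* *Per-factor runs.*  For the joint factor model the hierarchical
  procedure runs separately per factor; the two factors answer
  different questions and are reported as separate trees.

The report (`tidy()` on the result, or the TSV written by
`write_report()`) records per region the family p-value, the threshold
its family was tested at, discovery flags for itself and its parent,
and its path to the root, so every discovery is auditable.

## What the simulator emulates — and what it does not

`simulate_cohort()` / `simulate_volumes()` generate data with exactly
the structure the models assume.  The defaults are the emulated
study's conditions, fixed once: three sites with matched
psychopathic/control groups of 12/12, 10/10, 17/17; age
$\mathcal N(33, 9.5^2)$ years clipped to the 18–60 inclusion range;
ICV $\mathcal N(1600, 120^2)$ cm³ clipped at 4 SD; per-site PCL-R
factor means/SDs from the published cohort description
(`cohort_reference_summaries()`), factors bivariate normal with
correlation 0.27, clipped to the instrument ranges (0–16, 0–18),
rounded to the integer score grid, totals floored at the inclusion
cutoff of 20.  Elementary volumes follow

$$V = b_r\,\frac{\mathrm{ICV}}{\overline{\mathrm{ICV}}}
      + b_r s_{\text{site}} + b_r a\,( \text{age}-\overline{\text{age}})
      + \beta\,x + \varepsilon,$$

with baselines $b_r$ a deterministic 2000–10000 mm³ ramp over the
leaves, site shifts ±1% of baseline, an age drift of −0.2%/year,
planted effects $\beta$ per unit of the (centred) predictor on every
leaf below the named subtree, and exchangeable Gaussian noise
(`noise_sd` 150 mm³, inter-region correlation `region_corr`, default
0).  No per-region volume scales or residual SDs were published for
the emulated study; these are order-of-magnitude choices a morphometry
practitioner would call plausible, recorded in the config, and none of
the procedure's error-rate properties depend on them (the models are
scale-equivariant).

The simulator deliberately does **not** model realistic brain
geometry, registration error, scanner artifacts, anatomically
structured covariance, or item-level PCL-R ratings.  Passing tests
therefore demonstrate that the *statistics* behave as designed under
the assumed data-generating process — exact type-I error for the
per-region tests, FDR control and power propagation through the tree —
not that any particular anatomical finding in real cohorts is correct.
`simulate_lvr_maps()` adds small blocky voxel phantoms (disjoint
probabilistic blocks with a 0.5-probability shell, ≤32³ grids) to
exercise the volumetry path against known reference volumes.

Every generator takes a mandatory seed; fixed offsets (+1 for volumes,
+2 for maps) keep the streams of a study draw distinct while the whole
study remains reproducible from one integer.

## Error control and power of the whole pipeline

Two experiment functions run the pipeline at study scale:

* `null_fdp_experiment()` — replicate null cohorts of 39 psychopathic
  subjects (12/10/17), independent region noise, factor-2 analysis,
  strict Simes procedure at $q_0 = 0.05$ on the toy hierarchy.  Under
  this complete null a replicate contains a false discovery exactly
  when the root gate opens; the leaf p-values are exactly uniform
  (normal errors, exact t tests) and Simes is exact under independence
  at every level, so the procedure's true mean false discovery
  proportion equals $q_0$ *exactly*.  Empirical means must therefore
  be judged with their Monte-Carlo standard error
  ($\approx \sqrt{q_0(1-q_0)/n_{\text{rep}}}$); the test suite runs
  2000 replicates and the acceptance script 6000, sizes chosen to make
  that standard error small (±0.005 and ±0.003) while keeping the
  suite fast on one CPU.
* `recovery_experiment()` — a factor-2 deficit planted on the 5-leaf
  left frontal subtree, with the effect size *calibrated at run time*:
  a pilot set of cohorts estimates the sampling distribution of the
  factor-2 coefficient's standard error, the noncentral t distribution
  at the design's residual df (32 for the 7-column factor design at
  n = 39) gives the noncentrality for per-leaf power 0.9 at
  $\alpha = 0.05$, and the planted β is their product.  The success
  criterion is recovery of the planted subtree root in at least 80% of
  500 replicates, with strict-mode discoveries forming a
  root-connected subtree in every replicate.

## Known limitations

* The toy hierarchy stands in for real cytoarchitectonic atlases; no
  anatomical claims attach to it.
* Aggregate family p-values double-count probability mass where child
  maps overlap (a direct consequence of the child-sum convention).
* Simes exactness — and hence the exact-level behaviour of the tree
  procedure — assumes independent member p-values; under positive
  dependence Simes is conservative, and the simulator's
  `region_corr` parameter exists precisely to stress that robustness.
* Only complete-case analysis is offered for missing covariates.
* Mixed-effects, robust or interaction models are out of scope; the
  site effect is additive by design.
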