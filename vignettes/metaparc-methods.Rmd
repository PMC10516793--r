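---
title: "metaparc: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{metaparc: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaparc)
```

This vignette is the package's methods record: what the estimators assume,
what every tunable parameter means, where the design was genuinely open and
which choice was made, and what the synthetic validation does and does not
show about real data.

## 1. The data model

A coordinate database (`coord_db`) is a list of experiments, each with a
unique ID, an n × 3 matrix of activation foci in MNI world millimetres,
an optional subject count, and (optionally) a row of nonnegative term
frequencies over a shared vocabulary.  This is the information content of
BrainMap- or Neurosynth-style corpora after querying; the package operates
entirely on such pre-extracted files (Sleuth-style foci text plus a
tab-separated study × term table) and never contacts a live service.

Grids follow the NIfTI s-form convention: the affine maps *zero-based*
voxel offsets to world mm.  Public voxel indices, however, are **1-based**,
because everything else in R is; the conversion is internal.  `mm_to_voxel`
rounds half away from zero — banker's rounding would make points at exact
half-voxel offsets alternate sides depending on parity, which is
indefensible for coordinate snapping.  Out-of-grid points are flagged, not
clamped.

Hemisphere splitting assigns world x < 0 to the left mask and x > 0 to the
right.  Voxels exactly on the midline are excluded from both by default
(`midline = "left"` reassigns them): on a grid whose voxel centers hit
x = 0 exactly, any silent assignment would bias one hemisphere's voxel
count, so the default makes the ambiguity explicit.  Probabilistic masks
are thresholded *inclusively* (a voxel at exactly the 25% default threshold
is kept) and values on a 0–100 scale are rescaled to probabilities.

Talairach-space foci files are rejected rather than converted: no
conversion model is bundled, and silently mixing coordinate spaces is the
classic failure mode of coordinate meta-analysis.

## 2. MACM / ALE co-activation profiles

### Kernel

Each focus is modeled as a discretized isotropic 3D Gaussian probability
mass.  Two kernel modes exist (`kernel_spec()`):

* **`sample_size`** (default): FWHM(n) = sqrt(5.7² + 11.6²/n) mm, a
  template-registration component plus a between-subject component that
  shrinks with the square root of the subject count — the standard
  empirical spatial-uncertainty model of the ALE literature.  Experiments
  without a subject count fall back to the fixed FWHM.
* **`fixed`**: a single FWHM, default 12 mm.

The kernel is truncated at 3.5 standard deviations and its mass
renormalized to sum to 1 over the truncated support.  Truncation bounds
compute and makes the normalization testable; at 3.5 σ the discarded mass
is below 1e-4, far below the differences the profiles are clustered on.
Foci whose support crosses the grid edge lose the out-of-grid mass (the
map is what is observable on the grid); a focus whose *center* is off-grid
triggers a warning.

### Modeled activation and union

Within one experiment, per-focus kernels are combined by the voxel-wise
**maximum**, not the sum: an experiment reporting the same peak twice (or
a dense cluster of peaks) should not count more than once per voxel.
Across experiments the ALE score is the probabilistic union
`1 − Π(1 − MA_i)`, unthresholded — the parcellation is meant to see the
full quantitative co-activation pattern, and significance thresholding
would discard exactly the graded structure k-means clusters on.

### Nearest-experiment filtering

The spatial filter associates each seed voxel with its n nearest
experiments, where an experiment's distance is the minimum Euclidean
distance from the voxel center to any of its foci, computed in world mm
(anisotropy-safe).  Ties are broken by ascending experiment ID so
selection is reproducible.  Experiments with zero foci get distance +Inf
and are flagged.  The default filter bank is 20–200 in steps of 2
(91 sizes).

Because the selected experiment sets are nested as n grows, the
implementation computes, per seed voxel, prefix sums of log(1 − MA) over
the distance-ordered experiments; this reproduces the compositional
definition (selection → MA maps → union) exactly, which a test asserts at
1e-12.

## 3. Parcellation and model selection

Profile rows enter k-means raw (unstandardized); `row_norm = TRUE` offers
unit-norm rows for users who want direction-only similarity.  Raw values
are the default because the unthresholded ALE magnitudes *are* the signal
being clustered.

k-means uses `stats::kmeans` (Hartigan–Wong) with a configurable number of
random restarts, default 50, under a recorded seed; all stage seeds derive
deterministically from one run seed.  Hartigan–Wong with many restarts was
chosen over hand-rolling a k-means++ initializer: the established,
battle-tested implementation with restart diversity is preferable to a
custom initialization whose only advantage is fewer restarts.  Degenerate
inputs (fewer distinct rows than k) reduce to the number of distinct rows
with a warning.

Labels are aligned across filter sizes by the permutation maximizing
confusion-matrix agreement, found by exhaustive search (exact for k ≤ 8;
8! permutations is trivial).  Alignment is two-pass: first to the smallest
filter size, then to the modal labeling, so "deviance" is measured against
the consensus rather than an arbitrary anchor.

### Stability criteria

For each candidate k, computed over the selected filter range:

* **deviants** — fraction of (voxel, filter) entries whose aligned label
  differs from the voxel's modal label; 0 iff the aligned stack is
  constant.
* **VI** — mean variation of information between consecutive filter
  sizes, in nats (`H₁ + H₂ − 2I`); a metric on partitions, zero iff equal
  up to relabeling.
* **silhouette** — mean silhouette width (Euclidean), via
  `cluster::silhouette`; singleton clusters score 0 with a warning.
* **ratio** — mean between-centroid distance over mean
  point-to-own-centroid distance; +Inf is flagged if all points coincide
  with their centroids.
* **hierarchy index** — fraction of voxels whose (k−1)-solution label is
  not their k-cluster's dominant parent (plurality; ties take the lower
  parent ID with a warning).  Zero for perfectly nested solutions.

The filter range is the contiguous window (default width 25 sizes, capped
at the bank length) minimizing summed deviants aggregated over all k, ties
to the earlier window.  The published studies this windowing emulates used
widths of 25–27 sizes; the exact windowing rule there is not public, so
the transparent minimum-sum rule is used.

### Choosing k: two deliberate deviations

The obvious voting rule — rank the k values under each criterion, take the
best **median** rank, score the hierarchy index of the smallest k as 0
(nothing to violate) — turned out to be structurally broken, and the
package deviates from it twice:

1. **The hierarchy index is NA at the smallest candidate k.**  Scoring an
   undefined criterion as perfect hands k_min an unconditional top rank.
   Worse, in *any* nested-filter design the deviants and VI criteria lean
   toward small k (a 2-cluster solution has fewer cluster boundaries to
   flicker), so a free third vote makes k_min nearly unbeatable.  Each
   criterion is therefore ranked over the k values where it is defined,
   and each k is scored over its available criteria.  A criterion missing
   for *every* k is dropped with a warning.
2. **Mean rank (Borda count) instead of median rank.**  With five ordinal
   voters the median throws away two of them per comparison and produces
   frequent ties that the ties-to-smaller-k rule then resolves toward
   k_min.  The Borda count uses all criteria, is the textbook rank
   aggregation rule, and keeps the same tie-break (smaller k).

Both deviations were adopted after the median/zero-hierarchy rule
repeatedly rejected planted cluster structure that the separation criteria
identified clearly; the recovery study in the test suite documents the
behavior of the final rule.

The consensus parcellation takes each voxel's modal label over the
selected range; modal ties take the label at the median filter size (the
most representative single filter), with a warning.  Per-cluster counts of
fully consistent voxels are reported.

## 4. Decoding

The decoder follows the Neurosynth convention.  A study carries a term iff
its frequency strictly exceeds `term_freq_threshold` (default 0.001, the
convention of coordinate-map decoders).  A study activates a mask iff any
focus lies within `activation_radius_mm` of a mask voxel center
(default 10 mm, the sphere convention; radius 0 means "focus maps into the
mask").  From the 2×2 table, the forward probability, reverse posterior,
and Bayes factor follow the equations in the README; the prior defaults to
p = 0.5, which deliberately equates term base rates so posteriors are
comparable across terms.

The chi-square test is Pearson's without Yates correction (df = 1),
matching decoder practice; terms with a zero margin are skipped and
flagged rather than forced through.  FDR is Benjamini–Hochberg, applied
within one region's term list only.  Ranking keeps the `top_k = 10`
highest posteriors **before** dropping non-significant terms — the
reported lists are "top-10, then post-hoc exclusion", so a region can
legitimately end with fewer than ten (or zero) terms.  The exclusion list
(anatomical/technical terms) ships empty; e.g.
`exclusion_list = c("thalamus", "fmri", "bold")` reproduces the common
practice of stripping non-psychological vocabulary.  Posterior ties are
ordered alphabetically so results are invariant to study and term order.

### Systems-level decoding

Per seed cluster: every cluster ∪ region pair mask is decoded (FDR within
each pair), survivors tagged with the region's atlas ID; the regions alone
are decoded as the quasi-null (FDR within each region).  The strict
pipeline intersects the two term sets, then removes (term, region) pairs
the cortical decoding already explains.  Three set-algebra invariants are
asserted on every run: survivors ⊆ pair terms; no survivor (term, region)
appears cortically; the strict common set and the lenient set partition
the pair vocabulary.

**Percentage denominator.**  The reported percentage for a term-system is
`100 · n_surviving / n_connected`, where `n_connected` is the number of
functionally connected regions supplied for that cluster.  Published
worked examples are internally inconsistent on this denominator (some use
the connected-region count, others an unexplained smaller total), so the
package fixes the one rule that is always well-defined and *also* reports
the raw counts and region IDs so any alternative denominator can be
recomputed from the output.

Connected-region lists are an input (e.g. from `coverage_select` applied
to an external connectivity map at its inclusive ≥ 80% coverage rule);
computing resting-state connectivity itself is out of scope.  Per-term
system maps are volumetric label images in which surviving regions keep
their atlas labels and the seed cluster gets the reserved label
`max(atlas) + 1`; surface formats are out of scope.

## 5. The synthetic generator

`make_synthetic_db()` emulates, at desk scale, the joint structure the
pipeline is meant to detect:

* a 24 × 28 × 24 grid at 4 mm (an MNI-like FOV at coarse resolution);
* a 180-voxel box seed split into `k_true = 3` balanced azimuthal wedges;
* an 18-region cortical-shell atlas (Voronoi cells of the shell,
  deterministic given the seed);
* 600 experiments with 5–12 foci each, 20% unstructured null experiments,
  focus jitter σ = 2 mm;
* per planted system: 2 **hit** targets every system experiment
  co-activates (two foci each, plus three seed-wedge foci) and 4 **joint**
  regions that are listed as functionally connected but receive foci with
  probability `joint_hit_prob = 0`;
* one planted term per system, present with probability 0.6 in its
  system's experiments versus a 0.05 base rate, plus 15 background terms;
  frequencies are drawn uniformly in (0.005, 0.05) when present.

The wedge layout is load-bearing: wedges are mutually adjacent and
geometrically symmetric, so no particular 2-cluster merge is preferred and
the stability criteria can discriminate the true k.  (An earlier slab
layout made one merge artificially stable and defeated selection — a
data-design lesson, not an estimator bug.)  Hit-target centroids of
different systems are separated by far more than 4 jitter σ, which a test
asserts; jittered foci are clamped to the grid.

The two planted-signal switches implement the validation controls:
`joint_hit_prob = 1` with `seed_signal = FALSE` produces the cortical-only
negative control (the quasi-null captures the planted term everywhere and
the strict and lenient sets are empty for it), and `permute_annotations()`
destroys all activation–term association while preserving term margins,
giving the FDR-calibration null.

**What the generator does not emulate:** spatial autocorrelation of real
co-activation networks, heterogeneous study sizes and reporting styles,
correlated term vocabularies (real terms are synonyms and hypernyms of
each other), filter-size-dependent network reorganization, and hemispheric
structure.  Passing the recovery suites therefore shows the estimators are
correct and well-calibrated on data satisfying their assumptions — not
that a particular real-world parcellation is right.

## 6. Problem sizes in the validation suites

The test suite runs the full pipeline at deliberately desk-scale settings:
filter bank 20–60 step 4 (11 sizes), k = 2…5, window 7, 8 k-means
restarts, decoder radius 5 mm (≈ one voxel at the 4 mm grid, the analog of
the 10 mm default at standard 2 mm resolution) — chosen once as a
realistic small study; the parcellation-recovery suite repeats it over 20
generator seeds, and the calibration suite decodes 200 annotation
permutations.  The `activation_radius_mm` default of 10 mm is kept for
real-resolution data; on a 4 mm synthetic grid it would swallow the whole
seed box and flatten all contrasts, which is worth knowing when applying
the decoder to coarse grids generally.

## 7. Known limitations

* ALE significance testing (null distributions, cluster-level FWE) is out
  of scope by design — profiles stay unthresholded for parcellation.
* `align_labels` is exact but exhaustive; it is not meant for k > 8.
* The full-scale default bank (91 filter sizes at N_B ≈ 26,000 reference
  voxels) is memory- and CPU-heavy in plain R; the implementation is
  vectorized but not parallel.
* The hierarchy index compares consecutive *consensus* solutions; it does
  not attempt a full dendrogram consistency analysis.
* Talairach inputs, live database queries, LDA topic fitting, and surface
  (CIFTI/GIFTI) outputs are out of scope; topic tables and connected-region
  lists are user-supplied inputs.
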