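# metaparc

Coordinate-based meta-analysis in R: connectivity-based parcellation of a
seed brain region from meta-analytic co-activation profiles, and Bayesian
reverse-inference decoding of the resulting parcels — including a
set-algebraic *systems-level* decoding of seed–cortex region pairs.

## Who this is for

Neuroimaging researchers who work with coordinate databases (BrainMap- or
Neurosynth-style corpora: per-experiment activation foci in MNI space plus
study-by-term annotations) and want to

1. subdivide a seed region (e.g. the thalamus) into parcels with distinct
   whole-brain co-activation patterns, with data-driven selection of the
   spatial-filter range and of the number of clusters, and
2. characterize each parcel functionally, either alone or jointly with its
   functionally connected cortical regions.

No proprietary corpus is required: a synthetic-database generator with
planted cluster structure and planted term–system associations makes every
stage runnable and testable end to end.

## The method in brief

**MACM profiles.** For a seed voxel *v*, the *n* experiments whose foci lie
nearest to *v* (minimum Euclidean distance, mm) are selected; each
experiment's foci are modeled as discretized 3D Gaussian probability masses
combined into a modeled-activation (MA) map, and the voxel-wise
probabilistic union across the selected experiments

    ALE(x) = 1 − Π_i (1 − MA_i(x))

gives *v*'s unthresholded co-activation profile over N_B reference
(gray-matter) voxels.  Repeating this for every filter size in a bank
(default 20–200 in steps of 2, i.e. 91 sizes) yields one N_S × N_B
connectivity matrix per filter size.

**Parcellation.** Profiles are clustered by k-means (k = 2…8 by default)
at every filter size; labels are aligned across filter sizes by optimal
permutation.  The contiguous filter range with the fewest *deviants*
(voxels disagreeing with their modal assignment) is selected, and the
optimal k is chosen by rank-voting over five stability criteria: deviant
fraction, variation of information between consecutive filter sizes, mean
silhouette, inter/intra-cluster distance ratio, and the hierarchy index.
The final parcellation is the modal labeling over the selected range.
Parcels can be compared against a reference atlas with the Jaccard index.

**Reverse-inference decoding.** For a region mask and every term in the
annotation vocabulary, a 2×2 activation/term contingency table gives
P(activation | term) and P(activation | ¬term); with a uniform prior
p = 0.5,

    P(activation | term, p)  =  p·P(a|t) + (1−p)·P(a|¬t)
    P(term | activation, p)  =  p·P(a|t) / P(activation | term, p)
    Bayes factor             =  posterior odds / prior odds,

with a two-way chi-square test (no continuity correction) and
Benjamini–Hochberg FDR within the region's term list.  The ten
highest-posterior terms are kept and non-significant ones dropped post hoc.

**Systems-level decoding.** Each seed parcel is merged with every
functionally connected cortical region into pair masks; the pairs are
decoded, as are the regions alone (a quasi-null model).  Intersecting the
two term sets and removing region-tagged associations that the cortical
decoding already explains leaves the term–region associations that exist
only *jointly* with the seed parcel.  Each term-system is summarized by the
percentage of connected regions retained and the mean Bayes factor; a
lenient supplementary set (pair terms minus cortical terms) and a term→topic
aggregation are also reported.

## Worked example

A desk-scale study: simulate a 600-experiment database with three planted
seed clusters, parcellate, decode one parcel, then run the systems-level
decoding against each cluster's connected regions.

```r
library(metaparc)

sim <- make_synthetic_db(synth_config(seed = 1))
fit <- run_parcellate(sim$db, sim$seed_mask, sim$reference_mask,
                      bank = filter_bank(20, 60, 4), k_range = 2:5,
                      filter_window = 7, seed = 101, restarts = 8)
fit
#> MACM connectivity-based parcellation
#>   selected k: 3 (candidates  2-5 )
#>   selected filter range: 36 - 60 experiments
#>   cluster sizes: 60, 59, 61
```

The rank vote behind `k* = 3` (from `summary(fit)`; lower mean rank wins —
k = 2 is slightly more stable, but k = 3 dominates the separation criteria):

```r
#>      k deviants vi silhouette ratio hierarchy mean_rank
#> [1,] 2        1  1          3     4        NA      2.25
#> [2,] 3        2  2          1     1         2      1.60
#> [3,] 4        4  4          2     3         1      2.80
#> [4,] 5        3  3          4     2         3      3.00
```

k-means label ids are arbitrary, so align them to a reference before
joining parcels with per-cluster metadata:

```r
aligned <- align_labels(sim$truth$voxel_labels, fit$parcellation$labels)
cl_masks <- setNames(lapply(1:3, function(c)
  brain_mask(sim$grid, sim$seed_mask$voxels[aligned == c])), 1:3)

decode_roi(sim$db, cl_masks[["1"]],
           decoder_config(activation_radius_mm = 5), roi_id = "cluster 1")
#> Reverse-inference decoding of 'cluster 1' : 1 significant term(s)
#>      term posterior forward  chi2   p_value     q_fdr bayes_factor significant
#>  system_1    0.6115  0.7388 43.32 4.643e-11 8.357e-10        1.574        TRUE
```

The planted term `system_1` ranks first: studies activating parcel 1 carry
it far more often than chance (posterior 0.61 against the 0.5 prior,
Bayes factor 1.57, FDR-significant).  Systems-level decoding then isolates
the regions whose term association exists only jointly with the parcel:

```r
conn <- setNames(lapply(sim$truth$systems,
                        function(s) s$connected_regions), 1:3)
run_systems_decode(sim$db, cl_masks, sim$atlas, conn,
                   decoder_config(activation_radius_mm = 5))
#> Systems-level decoding of 3 cluster(s)
#>   cluster 1: 4 surviving region-term association(s), 0 lenient term(s)
#>   cluster 2: 4 surviving region-term association(s), 0 lenient term(s)
#>   cluster 3: 4 surviving region-term association(s), 0 lenient term(s)
#>
#> Top term-systems:
#>  cluster_id     term n_regions  region_ids percentage mean_bf
#>           1 system_1         4     3,4,5,6       66.7    1.37
#>           2 system_2         4  9,10,11,12       66.7    1.38
#>           3 system_3         4 15,16,17,18       66.7    1.45
```

Each planted system is recovered exactly: the four regions co-annotated
with the term only via the seed parcel survive (66.7% of the six connected
regions), while the two always-co-activated targets are explained by the
cortical-only quasi-null and excluded.

A command-line front end over the same workflows
(`simulate`, `parcellate`, `decode`, `systems-decode`) lives at
`inst/cli/metaparc.R`.

## Vignette

`vignettes/metaparc-methods.Rmd` documents the model, every tunable
parameter with its default and rationale, the synthetic generator's design,
numerical edge-case policies, and known limitations.
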