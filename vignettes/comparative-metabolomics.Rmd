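---
title: "Comparative metabolomics with chemocomp: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative metabolomics with chemocomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemocomp)
```

## The problem

Untargeted LC-MS profiles of complex biological extracts — here motivated
by collections of a benthic marine cyanobacterium from several Pacific
and Indian Ocean regions — are heterogeneous: different instruments,
gradients and sample amounts. `chemocomp` implements an objective,
relational way to compare such profiles: reduce each run to integrated
MS¹ features, consolidate features across samples into a *bucket table*
(samples × features, cells = integration values), and then ask two
questions of that table. How do the samples relate to one another
(hierarchical clustering, validated by the cophenetic correlation)? And
which features drive the differences between groups of samples
(univariate selection)? Features of interest are then dereplicated
against a user-supplied reference table by exact adduct mass, and an
auxiliary MS² workflow groups fragmentation scans into analog families
that share a diagnostic fragment ion.

## MS¹ feature detection

Detection operates on centroided spectra and is deliberately simple and
deterministic so that its outputs are reproducible to the byte.

1. **Trace building** (`extract_eics`). Scans are visited in retention
   time order. Each peak joins the open trace whose running
   intensity-weighted mean m/z is within `mz_tol` (nearest centroid
   wins, ties to the lower-m/z trace), otherwise it opens a new trace.
   A trace accepts at most one peak per scan — a trace is a proper
   chromatogram with one intensity per time point; without this rule a
   single noise peak falling into the same scan and tolerance window
   carves a false valley through a genuine elution profile and splits
   it. Traces close after `max_gap_scans` scans of silence. The running
   (rather than fixed) centroid follows slow mass drift, but note the
   lag: with flat intensities the centroid trails a steadily drifting
   ion by half the accumulated drift, so a drift can outrun a tight
   tolerance even when successive steps are within it.
2. **Peak shaping** (`detect_features`). Within a trace, local maxima
   with height ≥ `min_height` become apices; boundaries extend outward
   until intensity falls below `edge_frac × apex`, the trace ends, or a
   local minimum separating two apices is reached (overlapping peaks are
   split at the minimum, which both sides include for integration).
   Peaks spanning fewer than `min_scans` points are rejected. The
   integration value is the trapezoidal area of intensity over rt — the
   feature m/z is the intensity-weighted mean over the peak's points.

Parameters, with defaults: `mz_tol` 0.01 Da (EIC association), `rt_tol`
0.2 rt-units (consolidation), `min_height` 0 (set it to ~10× your
baseline noise), `min_scans` 3, `max_gap_scans` 1, `edge_frac` 0.01.
Retention time may be minutes (default), seconds, or the 0-based scan
index — acquisition protocols differ in which of these is comparable
across runs, so the variant is user-selected.

## Consolidation and transformations

`consolidate` pools all per-sample features, orders them by area
(descending; ties by lower m/z then rt), and greedily grows consolidated
features: the largest unassigned feature seeds a column and absorbs, per
sample, the largest unassigned feature within `mz_tol` and `rt_tol` —
at most one per sample, since a bucket cell holds a single integration
value. The column key is the area-weighted mean (m/z, rt), rendered
`"mz@rt"`. Every feature is assigned exactly once, so column count never
exceeds feature count. The greedy scheme is deterministic but only
*idempotent on resolvable data*: when true features sit further apart
than the tolerances, re-consolidating the table reproduces its own
column structure; for features denser than the tolerance grid, merged
centroids can drift within tolerance of a neighbour, which is inherent
to single-pass greedy clustering and is why the simulator enforces a
minimum feature separation.

Transformations (`transform_bucket`): `raw`, `log10p1`
(`log10(x + 1)`, compresses the 4–6 decade dynamic range of electrospray
intensities), `tic` (row-normalization, removes loading differences) and
`presence_absence` (for externally produced node tables). Zero always
means "not detected", so all transforms map 0 to 0.

## Relating samples

Cosine distance, `1 − x·y/(‖x‖‖y‖)`, ignores overall signal scale —
appropriate when absolute intensities reflect extract amount more than
biology. Samples are clustered agglomeratively (UPGMA/average linkage by
default, the customary partner of cophenetic validation; single and
complete offered) and the dendrogram is exported as Newick with node
heights at half the merge distance, so leaf-to-leaf path lengths equal
merge distances. The *cophenetic correlation coefficient* — Pearson
correlation between the original distances and the merge heights at
which pairs first co-cluster — quantifies how faithfully the tree
represents the distance matrix; it is 1 exactly when the distances are
ultrametric, and undefined below three samples.

Feature selection defaults to a per-feature Kruskal–Wallis test with
Benjamini–Hochberg correction: intensity distributions are zero-inflated
and heavy-tailed, so a rank test is the safer default (one-way ANOVA is
available). Constant features are assigned statistic 0 and p 1 rather
than NA. One arithmetic consequence worth knowing: with 5 vs 5 samples
the smallest achievable rank-test p is about 0.008, so with ~50 features
no marker can clear a BH threshold of 0.05 regardless of effect size;
group sizes of 10 vs 10 are the smallest at which a completely separated
marker is discoverable at that threshold, and the package's tests use
that size.

"Prominence" (`prominent_features`) ranks features by summed integration
value across samples (or within groups), mirroring the practice of
scaling network nodes to summed precursor intensity; a max-based ranking
is offered for spiky features.

## Dereplication

`adduct_mz` computes theoretical ion m/z from monoisotopic atomic masses
(C = 12 exactly, H = 1.0078250319, N = 14.0030740, O = 15.9949146,
Na = 22.9897693, …) as `(M + Δ − z·mₑ)/|z|`. The electron-mass
correction (mₑ = 0.000549 Da) is an explicit flag because both
conventions circulate in practice: calibrated high-resolution ion masses
include it, while "calculated for the ion formula" values obtained by
summing atomic masses of the protonated species do not; at 4 decimal
places the 0.0005 Da difference is visible. Degrees of unsaturation use
`RDBE = C + 1 + (N − H − X)/2` for the standalone neutral formula;
embedded-substructure bookkeeping (where a fragment's implied
unsaturation differs from its standalone formula's) is deliberately not
attempted. Fragment matching allows integer hydrogen shifts
(`mass + k × 1.007825`) up to `max_h_shifts`, reflecting hydrogen
rearrangement during fragmentation; the smallest |k| wins, ties by mass
error. Matching tolerances are absolute Da rather than ppm by default
because the motivating MS² data are unit-resolution ion-trap spectra.

## The MS² analog-family workflow

`run_ms2_pipeline` composes four steps: (i) precursor binning —
precursor m/z rounded *half-up* to `bin_oom` decimal places (0 = unit
bins; half-up, not banker's rounding, so bin edges are predictable);
(ii) diagnostic-fragment filtering — keep bins where any scan shows a
peak within `fragment_tol` (default 0.5 Da) of the diagnostic m/z, e.g.
the m/z 168 core fragment that defines the analog family of interest;
(iii) within-bin average-linkage clustering of scans on cosine distances
over a fixed 1-Da fragment grid anchored at 0, cut at 0.15; (iv)
consensus spectra — fragment bins present in ≥ `consensus_min_fraction`
(default 0.5) of a cluster's scans are kept, with intensity-weighted
mean m/z and the mean of per-scan relative intensities, re-normalized to
max 1. The consensus formula is this package's choice; the upstream
literature describes consensus generation without fixing one. The whole
pipeline is a pure function of its inputs and parameters: reruns are
byte-identical.

## The synthetic data generator

No raw data accompany the motivating study, so the generator *is* the
test bed, and its defaults encode the study design: 5 groups ("regions")
× 3 samples, 30 shared + 10 group-specific features per group, Gaussian
elution profiles (σ = 3 scan intervals), apex intensities 10⁵–10⁶
against half-normal baseline noise of sd 10³ (signal-to-baseline ≥ 100,
comfortably above the SNR ≥ 10 regime the recovery properties assume),
5% per-sample feature dropout, 240 scans over 1–20 min, 10 random noise
peaks per scan, and 0.002 Da per-point mass jitter. Feature placement
enforces a minimum separation (0.05 Da in m/z unless 1 min apart in rt),
i.e. resolvable features; requests too dense to place are rejected. The
MS² generator plants `n_analogs` precursors sharing core fragments
(including the diagnostic 168.102) plus per-analog side-chain fragments,
among decoy precursors whose fragments avoid the diagnostic bin, with
replicate scans under multiplicative intensity jitter. A single RNG
stream seeded once, with a documented draw order, makes every dataset
byte-reproducible.

What the generator does *not* emulate — chromatographic tailing and
drift, matrix/ion-suppression effects, isotope envelopes and adducts,
mass-accuracy drift, centroiding artifacts. Passing recovery tests
therefore demonstrates the pipeline's correctness on its own model of
the data, not performance on real chromatography; on real data the
detection parameters carry the burden the generator's idealizations
remove.

## Numerical and degenerate-case conventions

Ties are broken deterministically everywhere (stated in each function's
documentation): nearest-then-lower-m/z in trace assignment,
area-then-m/z-then-rt in consolidation, lower-m/z in prominence ties.
Cosine distances are clamped to [0, 1] against floating-point overshoot.
All-zero sample rows are rejected (their direction is undefined), as are
empty reference rows filling neither or both of formula and neutral
mass. Blank bucket-table cells read as 0. Constant features test as
exact nulls. Errors are classed (`usage` / `validation` / `data`) and
the CLI maps them to exit codes 1, 1 and 2.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_ms1_dataset(sim_config(seed = 1))
feats <- lapply(sim$runs, detect_features,
                detection_params(min_height = 1e4))
tab <- consolidate(feats, mz_tol = 0.01, rt_tol = 0.2)
d <- cosine_distance_matrix(transform_bucket(tab, "log10p1"))
tree <- hierarchical_cluster(d)
cophenetic_coefficient(tree, d)
rank <- select_features(tab, sim$truth$groups)
head(rank)
```

Problem sizes throughout the test suite (15 samples × 240 scans for the
chemogeographic benchmark, 25 precursors × 4 scans for the MS² family,
200 null replicates of 20 × 200 tables for the type-I-error check) were
chosen as the smallest at which the properties of interest are
statistically meaningful.

## Known limitations

Profile-mode data must be centroided upstream; isotope envelopes are
neither deconvoluted nor grouped with their monoisotopic feature;
chromatographic alignment/warping across runs is not performed (the rt
tolerance must absorb inter-run shift); gap-filling by raw-data
re-integration is not attempted, so a missed detection is a true zero in
the bucket table; and no claim of output parity with any other feature
detector is made — the algorithm above is fully specified precisely so
its behaviour can be validated against ground truth instead.
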