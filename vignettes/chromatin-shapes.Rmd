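---
title: "Chromatin profile shapes around CAGE-defined TSS clusters: methods and design"
author: "chromtss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromatin profile shapes around CAGE-defined TSS clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and design decisions
behind `chromtss`. It is the reference for *why* the package computes what it
computes; the README shows *how* to run it.

## The analysis model

CAGE tag clusters give a global, annotation-free catalogue of transcription
start sites (RTSSs), each a short strand-aware interval with per-sample tag
counts. In any one cell line most RTSSs are silent, yet chromatin around
them is informative: activating marks appear not only at expressed RTSSs
but at a sizeable minority of repressed ones, and the *shape* of the signal
around the TSS — a central nucleosome-depleted dip, a ramp rising in the
transcript direction, a retained central nucleosome — distinguishes
functional configurations that signal intensity alone does not.

The pipeline therefore works on **profile shapes**. For each RTSS and mark,
mapped-read 5′ starts (replicates pooled) are shifted +100/−100 bp by mapped
strand — half the ~200 bp average fragment length — and counted in 100 bp
bins over ±3 kbp around the RTSS midpoint anchor, giving 60 bins. Profiles
are oriented so the index runs in the transcript direction; minus-strand
profiles are reversed. This orientation is required for asymmetric shapes
(transcript-direction ramps) to align across strands; a plotting convention
in genomic orientation would wash them out. Binning is half-open: a read
exactly at the anchor falls in the first downstream bin.

Profiles with fewer than 100 reads carry too little shape information and
are dropped. The rest are smoothed with a normalised 7-bin Gaussian kernel,
and 6 bins are trimmed from each end, 60 → 48 points. We use kernel
σ = 1.5 bins; the published pipeline states the 7-bin window and the
60 → 48 reduction but not σ, and a 7-bin window alone would naively imply
trimming only 3 bins per side — the printed 48 governs, and trimming 6
leaves every retained point with full kernel support, so a constant profile
maps to a constant profile exactly.

## Two-level clustering with correlation distance

Shape, not intensity, is the object of interest, so clustering uses the
Pearson-correlation distance *d*(x, y) = 1 − *r*(x, y), invariant under
positive affine transforms of either profile. A constant profile has
undefined correlation; we define *r* := 0 (distance 1) everywhere.

Level 1 clusters each mark's smoothed expressed-RTSS profiles with k-means,
k = 5, 200 passes: each pass starts from a uniformly random assignment
(conditioned on no empty cluster), iterates centroid-update (arithmetic
mean, not re-normalised, matching the classic `kcluster` semantics) and
minimum-distance reassignment until the assignment stabilises, repairing
empty clusters by seizing the point farthest from its own centroid. Because
the arithmetic mean is not the exact minimiser of summed correlation
distances, an iteration can pass through a better partition than the one it
converges to; a pass therefore keeps the best partition it visits, and the
best-of-passes solution is polished by Hartigan-style single-point moves
(first-improvement, ≤ 25 sweeps). On small instances this makes the
best-of-200 objective coincide with the exhaustive optimum over all
bipartitions, which the test suite verifies against a brute-force oracle.

Level 2 describes each expressed RTSS by its Pearson correlations to every
level-1 subprofile — 5 × marks features (60 for a 12-mark panel; 55 with a
mark dropped) — masking a mark's features to 0 when that mark's raw profile
holds fewer than 100 reads, and k-means-clusters the feature rows with
k = 10 and 1000 passes under the same distance. k = 5 and k = 10 are fixed
design constants, not selected from the data; a PCA of the feature matrix
can be inspected as a diagnostic but plays no role in fitting.

## Poised-RTSS selection

Repressed RTSSs (zero focal CAGE tags) with active chromatin are selected on
their pooled profile across the active-mark panel: (i) overlap with an
enrichment peak of any mark (with the same 500 bp extension used in the
overlap-enrichment stage — the published criteria do not state whether the
extension applies here, and consistency favours it); (ii) pooled signal
strictly above 1000 reads; (iii) correlation with the average pooled
repressed profile strictly above 0.5; (iv) that correlation significantly
larger than the correlation with the average pooled expressed profile,
p ≤ 0.05. The reference averages come from peak-overlapping repressed and
expressed RTSSs of the same dataset; totals use raw 60-bin profiles, and
correlations the smoothed 48-bin versions, consistent with clustering.

Criterion (iv) compares two dependent correlations sharing the RTSS profile
as common variable: Steiger's test in Williams' t form with df = n − 3 and
n = 48 smoothed bins treated as observations. Treating bins as independent
observations overstates the effective sample size when neighbouring bins are
correlated; we retain it as the field-standard form of this test, and the
acceptance suite verifies its null behaviour (p = 0.5 at equality,
one-sided type-I error ≈ 5%) against a trivariate-normal Monte-Carlo
simulation. Pol II is *not* part of the pooled active panel; it is profiled
separately over the expressed / poised / remaining-repressed groups, where
its central signal should be ordered expressed > poised > repressed.

The per-mark variant applies criteria (i)–(iv) to each active mark with the
signal threshold lowered to 100 and selects RTSSs passing in at least three
marks; agreement between the two procedures (reported as overlap fractions
and Jaccard) is the robustness check.

## Monte-Carlo tests

The overlap p-value uses the simplest defensible null we could state
exactly: every RTSS interval is repositioned uniformly within its own
chromosome, preserving interval lengths and per-chromosome counts; the
statistic is the number of peak-overlapping RTSSs, and the add-one
estimator (1 + #{perm ≥ obs}) / (1 + n_perm) with 100 permutations gives a
one-sided enrichment p bounded below by 1/101. The published analysis
delegated this to an external platform whose null is not specified; ours is
deliberately minimal and its calibration (fraction of p ≤ 0.05 under the
null within [0.01, 0.12], conservative because of count ties) is asserted in
the test suite. The CpG case/control test permutes case/control labels
across promoters preserving set sizes, with the statistic defined as the
difference of bp-overlap fractions (a ratio would behave poorly for small
control overlap); 1000 permutations by default.

## Expression-correlation validation

Window intra-correlation collects, for each gene TSS anchor and half-width
(50 bp – 150 kbp ladder), all member RTSSs with anchors inside the window
and averages Pearson correlations between their expression vectors over all
within-anchor pairs, pooled across anchors before averaging (a grand mean
over pairs; per-anchor means would up-weight sparse anchors). Counts are
transformed to tags-per-million then log(1 + x) by default — correlations on
raw counts are dominated by library size — with `transform = "raw"`
available. The random baseline is the mean over all pairs of 100 uniformly
drawn RTSSs.

## The synthetic-data generator

`simulate_dataset()` defines the package's reference study conditions:
2 chromosomes × 25 Mbp, 300 genes (14–30 kbp, ≥ 10 kbp apart), 2000 RTSSs,
100 samples, a 6-active-mark panel plus Pol II, 10 planted metaclusters,
10% of repressed RTSSs poised, read depth 500 per enriched RTSS and mark
(poised 300; Pol II 600/250), background 5 reads/kbp, negative-binomial
counts with size 5. These scales keep a full pipeline run around a minute
on one CPU while leaving every recovery margin dominated by genuine
sampling noise.

What it emulates, and how:

* **Expression**: focal-sample counts obey the classification contract
  exactly (expressed = threshold + NB, repressed = 0, intermediate strictly
  between); other samples draw NB counts whose log-means share a
  gene-neighbourhood factor (σ = 0.5) and a metacluster factor (σ = 0.7),
  inducing the neighbourhood and co-cluster expression correlation the
  validation stage measures.
* **Shapes**: a template library of five 60-bin shapes — symmetric peak
  with central dip, central peak without dip, downstream ramp, upstream
  ramp, flat. Expressed RTSSs draw per-mark templates from their
  metacluster's archetype; archetypes are words of a ternary code over
  {dip, downstream ramp, upstream ramp} with pairwise Hamming distance
  ≥ 3–4 across marks, so configurations are mutually distinguishable. The
  central-peak template is reserved for the poised configuration (retained
  central nucleosome, also used for Pol II), keeping the expressed-class
  average dip-shaped and the poised/repressed average centre-peaked.
* **Reads**: multinomial draws over the oriented bins, jittered within
  bins, mapped strand 50/50, then *un*-shifted by ∓100 bp so the pipeline's
  shift step is exercised rather than bypassed; uniform background; ±1 kbp
  peaks over enriched anchors, never merged.
* **Geometry**: metacluster labels are planted per gene neighbourhood, and
  enriched RTSSs either co-locate within a TSS cluster (offsets ≤ ~150 bp,
  which preserves profile shape) or keep ≥ 6.5 kbp from any other enriched
  anchor. Without this, read clouds of differently-shaped neighbours within
  the 6 kbp profile reach blend into chimeric profiles that mimic other
  archetypes — a real phenomenon (it is why isolated-RTSS analyses exist)
  but one that would make per-RTSS label recovery ill-posed as a test.

What it does **not** emulate: nucleotide sequence, mappability artefacts,
replicate structure, inter-mark depth differences, distance-decaying
expression correlation, or TSS-cluster fine structure. Passing recovery
tests on this generator therefore shows the pipeline correctly extracts
planted shape/label/poised structure at realistic depths and densities — it
does not show robustness to confounded neighbourhoods, which real data
exhibit and the isolated-RTSS utilities (`find_isolated()`) exist to probe.

## Numerical conventions

* Coordinates are 0-based half-open throughout; wiggle input (1-based) is
  converted on read. Peak sets are never merged on read.
* Isolation distance is edge-to-edge and inclusive (a 2000 bp gap is
  isolated); proximity for the `proximal` class is tested on the RTSS
  anchor.
* "Above" thresholds are strict (>); "at most" bounds are inclusive (≤),
  following the stated selection wording.
* Constant vectors correlate as 0 by convention wherever correlations are
  computed.
* k-means ties in reassignment resolve to the lowest cluster index; seeds
  are explicit arguments everywhere, and the pipeline derives per-stage
  seeds from a master seed by a polynomial string hash.

## Known limitations

* The dependent-correlations test treats profile bins as independent
  observations (see above); its p-values are calibrated under that
  assumption only.
* The Monte-Carlo overlap null ignores chromatin-domain structure (gaps,
  GC, mappability); against real data a circular-shift or annotation-aware
  null would be more conservative.
* Level-1 subprofiles are computed from smoothed profiles; displayed
  averages are smoothed as well.
* The per-gene planting of metacluster labels makes label recovery
  well-posed but also means the synthetic data cannot probe sub-gene
  heterogeneity of chromatin configurations.
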