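---
title: "Methods and design notes for xenofate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for xenofate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xenofate)
```

`xenofate` packages the quantitative chain behind xenograft brain-organoid
single-cell studies. This vignette explains each model and procedure, the
parameters that matter, what the synthetic-data generators do and do not
emulate, and the choices we made where the design was genuinely open.

## Species demultiplexing

With a dual human/mouse reference, each droplet's species identity is read
off its human-transcript ratio r = human UMIs / total UMIs. Pure droplets
sit at 0 or 1; ambient cell-free RNA pulls both modes inward by roughly
(ambient fraction) x (pool composition); balanced doublets sit near 0.5.
Classification uses two cut points, 0.2 and 0.8, with the band in between
labeled *unknown*.

Decisions made here:

* **Closed thresholds.** r &ge; 0.8 is human and r &le; 0.2 is mouse, so the
  boundary values themselves classify deterministically.
* **UMI-level ratio.** The ratio is computed over transcripts, not distinct
  genes; `human_ratio(level = "gene")` offers the gene-level variant.
* **QC before ratios.** Cells below `min_genes` = 200 detected genes or
  `min_umis` = 500 UMIs are dropped first. These are conventional droplet
  floors — the right values depend on chemistry and should be revisited per
  dataset. `qc_filter(x, 0, 0)` is the identity.
* **Bimodality diagnostic.** A 50-bin histogram smoothed with a 3-bin
  moving average; peaks are local maxima and the distribution is *bimodal*
  when two peaks are separated by a trough strictly below both. This is a
  reproducible, dependency-free check, not a mixture model.
* Unknown-band cells are discarded by default (`keep_unknown = FALSE`);
  they can be retained for re-examination.

## Pseudo-bulk comparison

Per-sample profiles are formed by **summing raw counts, then CPM, then
log2(x+1)** — summing first makes the profile insensitive to per-cell depth
(duplicating every cell changes nothing), which per-cell averaging of
normalized values does not guarantee. PCA is a centered, unscaled SVD.
Sample distance is 1 &minus; Pearson r on the log profiles with
average-linkage clustering: scale-free, and matching the correlation-heatmap
view commonly used for sample similarity. Reference mapping uses Spearman
correlation over shared genes (optionally the panel's top-variance genes),
making it invariant to monotone distortions between platforms; the best
match is the row-wise argmax.

## Differential expression

The test is a two-sided Wilcoxon rank-sum on log-normalized expression
(counts scaled to 10^4 per cell, log1p) — the default choice of the
single-cell ecosystem, implemented in-house so that both code paths are
testable:

* **Exact path** (both groups &le; 10 cells): every assignment of group-A
  ranks is enumerated; p is the probability of a rank-sum deviation at
  least as large as observed. With ties this uses midranks and is exact.
* **Normal path**: tie-corrected variance with a 0.5 continuity
  correction. On continuous data this tracks the exact tail to within 0.02
  for groups of 5 or more; on *heavily tied* tiny samples the exact tail is
  clumpy and no normal approximation is accurate — which is why the exact
  path is the default whenever it is affordable.

Fold change is log2((meanA+1)/(meanB+1)) on de-logged normalized group
means; the +1 pseudocount bounds it at zero expression and makes
"expressed in A only at normalized mean 3" exactly log2(4) = 2. The filter
triple is p_adj &lt; 0.05, PCT &gt; 0.1 and |log2FC| &gt; 0.25, with PCT
applied to the larger of the two group fractions (`pct_mode = "min"`
requires both). The fold-change filter is applied to |log2FC|, so both
directions are kept. BH adjustment is the step-up rule with enforced
monotonicity, returned in input order.

## Concordance and host alignment

Quadrant analysis classifies genes by the signs of their log2FCs in two
comparisons. Genes with either coordinate exactly zero go to an explicit
`axis` category rather than being tie-broken into a quadrant. The gene list
defaults to the union of the two comparisons' passing DEGs (genes
significant in either), configurable to intersection or all shared genes;
the correlation is Pearson (the relationship of interest is linear in
log2FC), with Spearman as an option.

The host-alignment score is the raw sum of log2FCs of a
region-characteristic gene set in a target comparison; only the sign is
interpreted. The sum is *not* normalized by set size by default — it is the
literal signed aggregate — but `per_gene_mean = TRUE` divides by the number
of scored genes for cross-set comparability.

Over-representation uses the upper-tail hypergeometric probability
P(X &ge; k) per set with BH across sets. No ontology structure is used;
collections are plain GMT files.

## Morphometry

Skeletons are standard 7-column SWC trees with a single soma root.

* **Sholl**: for each sphere radius (default step 5 um), the number of
  parent-child segments whose endpoint distances from the soma straddle the
  radius, counted once per segment per sphere. A sphere entered and
  re-exited *within* one segment (a grazing chord) is deliberately not a
  crossing; with outward-growing processes such chords are rare, and the
  once-per-segment rule keeps the count stable. 3D by default;
  `project_xy = TRUE` gives the 2D projected variant.
* **Branch statistics**: total length is the sum of parent-child Euclidean
  distances; primary branches are the soma's children; terminal branches
  are leaves; effective soma area is pi r^2 from the soma node radius (the
  only soma-size datum a skeleton carries).
* **Colocalization**: the skeleton is discretized into sub-segments of at
  most 0.5 um; a sub-segment is colocalized when its midpoint lies within
  eps (default 1 um) of any evidence point, and proximal when its midpoint
  is within 40 um *Euclidean* distance of the soma center (not path
  distance — the split is defined from the cell body). Fractions are
  length-weighted, so total = (prox x L_prox + dist x L_dist) / L exactly.
  Halving the step moves fractions by well under 1%. When scoring
  generator-planted coverage, eps should be smaller than the discretization
  step so that evidence for one sub-segment does not spill onto neighbors.

## Calcium signals

F0 is the mean over all samples strictly before the stimulus (the full
visible baseline), dF/F0 = F/F0 - 1, and a cell responds when some
post-stimulus sample strictly exceeds the 10% threshold; `min_consecutive`
adds a persistence requirement (default 1 sample — the criterion names no
debouncing). Response time is measured from the stimulus to the first
qualifying sample, so a noiseless instantaneous step responds at exactly
one sampling interval. Group activation is the mean of per-cell maximum
post-stimulus amplitudes, reported as fold versus the control group;
area-under-curve aggregation is not implemented because max amplitude is
the quantity the response figures report. Activity clustering is Pearson
correlation of dF/F0 series with average linkage on 1 - r; note that
correlation is amplitude-invariant, so groups separate only when their
*dynamics* (e.g. rise times) differ.

## Synthetic-data generators

The generators exist so every stage can be scored against known truth.
They are deterministic given their config (each carries a `seed`), and the
defaults are the study-like conditions the test-suite properties are stated
under.

* **Barnyard** (`simulate_barnyard`): skewed per-species abundance
  profiles; Poisson depth (default mean 5,000 UMIs, truncated at 1);
  ambient contamination modeled as *replacement* of a binomial fraction of
  each droplet's UMIs by draws from the pooled ambient profile. Replacement
  keeps depth fixed and makes the expected contaminated ratio closed-form:
  E[r | mouse singlet] = ambient_fraction x ambient human share. Doublets
  are 50/50 at singlet depth — the worst case for threshold classification.
  Not emulated: empty droplets, depth-dependent ambient, barcode swapping,
  unbalanced doublets.
* **Grouped counts** (`simulate_grouped_counts`): negative binomial with
  shared dispersion (default 0.5), log-normal gene baselines around 2
  counts/cell over a 1,000-gene genome — about 2,000 UMIs/cell, matching
  the reported average depth of this kind of graft dataset. Planted region
  and time programs (50 genes, |log2FC| = 1 each by default) are
  **sign-balanced**: half of each program is up in PFC (resp. 4MPT), half
  up in HIP (resp. earlier). One-sided programs would skew library sizes
  and induce spurious anti-regulated nulls after CPM-style normalization —
  a real composition artifact, but not the property under test. Not
  emulated: per-gene dispersion trends, batch effects, cell-type mixture
  within groups.
* **Reference panel**: independent Gaussian log-expression per reference;
  queries are a reference column plus noise, so the truth map is exact.
* **Skeletons**: `n_primary` branches leaving the soma, bifurcating at
  each level to `branching_depth`, nominal segment length with Gaussian
  positional jitter and outward-biased directions. Ground-truth length is
  recorded from the generated coordinates by an edge walk.
* **Traces**: baseline, linear ramp of `rise_time` seconds to
  baseline x (1 + amplitude), Gaussian noise. Stimulus at 10 s in the
  workflow, per-cell amplitude/rise overrides for planted group structure.

Because the generators plant clean, single-axis effects, a passing test
shows the *computation* is correct under the stated noise model — it does
not certify performance on real data with batch structure, ambient
spill-over across genes, or segmentation errors.

## Problem sizes and determinism

The test suite and the acceptance script use the generator defaults
(2,000-droplet demultiplexing runs; 5 x 100-cell groups over 1,000 genes
for DEG properties, 5 seeds; 100 seeded replicates for the alignment-sign
property; 50 random trees for the Sholl oracle; 1,000 draws for null
calibrations) — sizes at which the Monte-Carlo bands in the assertions are
comfortably stable and a full run stays fast on a laptop. All randomness
flows through explicit seeds; the acceptance script derives every
generator seed from its `--seed` argument.

## Interface

The package is organised as an analysis workflow: the numbered scripts in
`analysis/` are thin narrative drivers (simulate, demultiplex, compare,
test, score, measure) over the exported functions, writing plain TSV/CSV
outputs under `results/`; there is no separate command-line wrapper. File
formats are the field's plain-text standards: MatrixMarket triplets for
counts, TSV for tables and panels, GMT for gene sets, SWC for skeletons,
CSV (+ YAML sidecar) for traces.

## Known limitations

* The Wilcoxon engine treats cells as independent replicates; no
  pseudoreplication-aware or covariate-adjusted models.
* No ambient-RNA *correction* — the demultiplexer diagnoses contamination
  but does not subtract it.
* Sholl ignores node radii (centerline geometry only), and the effective
  soma area is exact only insofar as the SWC soma radius is.
* The bimodality check reports histogram peaks, not a fitted mixture; very
  small cell numbers can miss shallow modes.
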