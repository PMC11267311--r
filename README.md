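# xenofate

Cell-fate analytics for xenografted brain-organoid single-cell studies.

When human brain organoids are transplanted into rodent brain (e.g. into
prefrontal cortex, PFC, or hippocampus, HIP) and profiled by single-cell
RNA-seq against a dual human/mouse reference, every downstream claim rests
on a chain of quantitative steps: separating human from mouse droplets,
comparing samples at the pseudo-bulk level, calling differential expression,
asking whether graft programs align with the host region, and quantifying
astrocyte morphology and calcium physiology. `xenofate` implements that
chain as a tested R package, together with a synthetic-data module that
generates every input with known ground truth, so each stage can be
validated without access to any sequencing run or microscope.

## What the package computes

**Species demultiplexing.** For each droplet the human-transcript ratio
r = (human UMIs)/(total UMIs). Cells with r &ge; 0.8 are called human, r &le;
0.2 mouse, and the band in between *unknown* (ambient RNA pulls singlet
ratios off 0/1; 50/50 doublets land mid-band). A histogram-smoothing
diagnostic checks that the ratio distribution is bimodal.

**Pseudo-bulk comparison.** Per-sample profiles are raw-count sums scaled
to CPM and log2-transformed; samples are compared by centered PCA, by
average-linkage clustering on 1 &minus; Pearson r ("transcriptome
distance"), and mapped onto reference expression panels by Spearman
correlation with argmax best match.

**Differential expression.** An in-house two-sided Wilcoxon rank-sum test
on log-normalized expression (exact enumeration when both groups have
&le; 10 cells, tie-corrected normal approximation otherwise),
log2FC = log2((meanA+1)/(meanB+1)) on de-logged normalized group means,
Benjamini&ndash;Hochberg adjustment, and the standard filter triple
p_adj &lt; 0.05, PCT &gt; 0.1, |log2FC| &gt; 0.25.

**Concordance and host alignment.** Genes shared by two comparisons are
classified by the signs of their fold changes (quadrants I&ndash;IV;
I&cup;III dominance = concordant regulation), a region-characteristic gene
set gets the signed alignment score S = &Sigma; log2FC (S &gt; 0: the graft
resembles that host region), and gene-set over-representation uses the
upper-tail hypergeometric test with BH correction.

**Morphometry.** On SWC skeletons: Sholl profiles (segment crossings of
concentric spheres around the soma), branch statistics (total length,
primary/terminal branch counts, effective soma area &pi;r&sup2;), and
fiber&ndash;neurite colocalization as the fraction of skeleton length within
&epsilon; of evidence points, split proximal/distal at 40 &micro;m from the
soma center.

**Calcium signals.** &Delta;F/F0 against the pre-stimulus baseline, the
(F/F0 &minus; 1) &gt; 10% response criterion with response times, per-group
fold activation versus control, and correlation clustering of activity.

## Worked example

The `analysis/` directory is a numbered workflow over the package; running

```sh
Rscript analysis/01_simulate_data.R   # generate all inputs + ground truth
Rscript analysis/02_species_demux.R
...
Rscript analysis/07_calcium.R
```

writes every table under `results/`. Script 02 demultiplexes a simulated
mixed-species run (2,000 singlets, 2% doublets, 1% ambient contamination)
and prints:

```
human-ratio distribution: 3 peak(s) at 0.01, 0.49, 0.99; bimodal: TRUE
labels: 1000 human / 1000 mouse / 40 unknown; singlet accuracy 1.0000; 100% of doublets in the unknown band
```

i.e. singlet peaks sit at the ambient-shifted extremes, the mid-band peak
is the doublets, every singlet is labeled correctly and every doublet is
flagged unknown. Script 04 then recovers the planted differential
expression ("planted region program: 96% recovered, empirical FDR 7.7%"),
script 05 shows the two region contrasts agree in fold-change quadrants
(`I=27 II=5 III=25 IV=2, r = 0.946`) with alignment scores of +22.9 / &minus;23.4
for the PFC/HIP programs, and script 07 ends with

```
fold activation: dF_DA/dF_CONT = 3.2; dF_ACh/dF_CONT = 2.5
```

against planted fold ratios of 3.5 and 2.7 under measurement noise.

## Scope

Inputs start at the aligned count matrix / traced skeleton / extracted
trace: no read simulation or alignment, no image segmentation, no
clustering-based cell-type annotation, no pseudotime, and no ontology
handling (gene sets are user-supplied GMT files).
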