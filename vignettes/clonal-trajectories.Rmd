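---
title: "Reconstructing longitudinal clonal trajectories with clonetraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing longitudinal clonal trajectories with clonetraj}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`clonetraj` re-implements, as a tested and reusable pipeline, the analysis
stages needed to follow the subclonal evolution of a tumour sampled
repeatedly over many years — the setting of a chronic lymphocytic leukaemia
(CLL) patient observed across roughly two decades.  Four data modalities are
covered, each behind its own module:

1. **Bin-based copy-number calling** for low-coverage bulk and single-cell
   WGS (`make_bin_boundaries`, `normalize_ratios`, `gc_correct`,
   `segment_bins`, `mapd`, `filter_cells_by_mapd`, `clamp_log2`,
   `cluster_cells`, `region_fp_test`, `assign_subclone`, `cnv_pipeline`);
2. **Mosaic chromosomal aberration detection** from SNP-array LRR/BAF probe
   tracks (`preprocess_track`, `segment_baf_lrr`, `classify_mosaic`,
   `estimate_mosaic_fraction`, `focal_region_ttest`, `scan_mosaic`);
3. **Variant allele-frequency trajectory clustering** across bulk time
   points (`filter_annotations`, `filter_depth`, `pca_germline_filter`,
   `sota_cluster`, `prune_low_range`, `label_trajectory`,
   `maf_trajectory_pipeline`);
4. **Single-cell expression analysis**: the QC cascade, the iterative
   PCA/hierarchical clustering with Kruskal-Wallis gene selection and
   hypergeometric marker calling (`qc_filter`, `iterative_cluster`,
   `kw_test`, `marker_genes`, `composition_table`), and MST pseudotime with
   time-anchored reordering (`de_genes_by_time`, `embed_and_mst`,
   `order_cells`, `reorder_by_time`, `group_genes_along_path`).

Because the patient data underlying such studies are controlled-access, the
package ships a fully parameterized **synthetic patient generator** with
known ground truth (`make_default_clone_model`, `simulate_cell_bin_counts`,
`simulate_probe_track`, `simulate_maf_sites`, `simulate_expression`).  All
validation is property- and simulation-based against that ground truth.

# The synthetic patient

## Clone model

The default model (`make_default_clone_model()`) carries five CNV-defined
subclones on a six-chromosome toy genome (205 Mb total): a normal-like
clone; a clone with only the focal 13q14.3 deletion (2 Mb); a clone with
the focal plus the large 13q14.2–14.3 deletion (8 Mb); a clone combining
6q−, a 12q gain and the focal 13q deletion; and a clone with trisomy 12
only.  Mixture fractions are defined at seven sampling years (10, 14, 21,
23, 24, 26, 28 after presentation) and sum to one at every time point.  The
time course is qualitatively faithful to the disease history the model
emulates: the 6q−/12q+ clone dominates early and disappears after the late
cytotoxic therapy, while the trisomy-12 clone appears only from year 24
onward.

A toy genome replaces the human reference deliberately: coordinates stay
desk-scale, every bin's ground-truth copy number is known exactly, and no
external annotation download is needed.  Coordinates are 0-based half-open
in memory and 1-based inclusive in all text I/O.

## Read counts, probes, allele depths, expression

*Bin counts* are Poisson: a bin covered at diploid depth `d` in a cell with
copy number `c` draws `Poisson(d · c/2 · b(gc))`, where the GC bias
`b(g) = max(0.1, 1 − κ(g − 0.45)²)` is a smooth unimodal quadratic
(default curvature κ = 4, about a 9 % dip at the GC extremes).  A quadratic
was chosen because it reproduces the wave-like coverage patterns that GC
correction is meant to remove while staying analytically transparent.

*Probe tracks* place heterozygous-probe BAF at the exact allelic-mixture
values: with aberrant-cell fraction `f` and aberrant copy number `c`, the
two mirrored heterozygous BAF modes are `(1−f)/(2−f)` and `1/(2−f)` for a
loss, `1/(2+f)` and `(1+f)/(2+f)` for a gain, and `(1∓f)/2` for
copy-neutral LOH; LRR is centred at `log2((2(1−f)+cf)/2)`.  Default noise:
BAF sd 0.03, LRR sd 0.15, typical of modern arrays.

*Variant sites* are germline (constant 0.5 or 1 allele fraction) or somatic
(heterozygous within one clone, so the expected variant fraction at time t
is half the clone fraction).  Depths are Poisson, variant reads binomial.
Sequencing error is off by default so that small-count oracles stay exact.

*Expression* draws log-normal FPKM per gene with six ground-truth clusters
(A–F) whose per-year prevalences follow the published cluster-by-date
composition pattern of the CLL patient (cluster D dominant at years 10 and
26, F at year 20, A/E expanding at year 28).  Each cluster has 100 marker
genes up-shifted two-fold in its cells; marker baselines sit comfortably
above the FPKM > 1 "expressed" threshold so they survive the core-gene-set
filter; dropout zeroes 2 % of entries; the per-cell log-noise sd is 0.25.
These four knobs were fixed once so that, at the two-fold effect the
validation conditions prescribe, the ground truth is recoverable with a
clear margin — which is the property a test-bed generator must have; they
understate the zero-inflation and overdispersion of real single-cell data,
so passing tests demonstrate correctness of the procedure, not expected
performance on real FPKM matrices.

# Copy-number calling

**Binning and normalization.** Bins are allocated to chromosomes
proportionally to length (largest-remainder rounding) with equal width
within a chromosome — 10,000 bins by default.  Real workflows use
mappability-adjusted bins; equal-width bins keep the ground truth exact and
need no external track.  Normalization is two-step: each sample is scaled
to mean bin count one, then each bin is divided by its cohort-mean scaled
value, making the cohort-mean profile identically 1.  The published wording
of this normalization is ambiguous between a per-bin cohort reference and a
per-sample mean; the two-step form implements both readings in sequence and
is recorded as this package's interpretation.  One consequence worth
knowing: when many cohort cells share a deletion, the cohort reference dips
there and diploid cells show an apparent gain.  Clustering is unaffected
(profiles remain clone-separating), but `assign_subclone` should be fed
profiles referenced to a predominantly diploid baseline.

**GC correction** divides ratios by a lowess fit of ratio against GC (span
0.3) and rescales to mean one.

**Segmentation** is circular binary segmentation, implemented from first
principles in compiled code: for a chromosome's ratio vector, the pair of
breakpoints maximizing the two-sample t statistic between the circular arc
and its complement is located exhaustively; the split is accepted when its
permutation p-value is below α (default 0.01, 1,000 permutations, seeded);
the two or three resulting segments are segmented recursively; and adjacent
segments whose means differ by less than 0.05 are merged.  Permutations
stop early as soon as the exceedance count already implies p ≥ α — this is
exact (the decision cannot change) and makes null chromosomes cheap.  The
permutation variance is held at the segment variance, which is
permutation-invariant, so the permutation test is exact regardless.

**Quality control** is the MAPD — the median absolute difference between
neighbouring bins' log2 ratios, with neighbour pairs never spanning
chromosomes — computed on GC-corrected ratios *before* segmentation
(whether the original workflow computed it pre- or post-correction is not
stated; pre-segmentation is the defensible choice since segment ratios are
piecewise constant and would understate noise).  Cells with MAPD ≥ 1.4 are
removed — the threshold is inclusive.  For i.i.d. log2 noise of sd s the
expected MAPD is about 0.954·s, so the cutoff corresponds to s ≈ 1.47.

**Clamping and clustering.** Segment ratios are transformed to
`min(1, max(−1, log2 r))` (non-positive ratios map to −1) and cells are
clustered with Euclidean distance and ward.D2 linkage.  A segment is called
a deletion below −0.3 and an amplification above +0.3 on the clamped scale;
the published state rule mixes the ratio and log scales, and the clamped
log2 thresholds are the internally consistent reading.

**False-positive test.** For a suspicious merged segment, a pooled-variance
two-sided t-test compares the raw (pre-segmentation) bin ratios of two
portions of the region within the same cell; zero-variance degenerate
inputs return p = 1 (equal means) or p = 0 (unequal), by convention.

# Mosaic aberrations from SNP arrays

The mirrored heterozygous-probe deviation Δ = |BAF − 0.5| is the detection
signal; mean BAF is uninformative under symmetric allelic splits, so every
BAF-side statistic in this module uses Δ (the published description says
"mean BAF"; this is recorded as an interpretation).  Δ is segmented with
the same CBS engine; segments with fewer than 20 heterozygous probes are
absorbed into their closer-mean neighbour, so every reported segment has at
least 20 probes; chromosomes with fewer than 20 heterozygous probes are
reported as single unscored segments.  Heterozygous probes are identified
by genotype class when present, else by BAF ∈ [0.15, 0.85].

Classification uses the mean LRR of the segment: Δ above the noise floor
(default 0.03, chosen because the folded null mean deviation at BAF noise
sd 0.03 is ≈ 0.024) with LRR below −0.05 is a mosaic loss, above +0.05 a
mosaic gain, within ±0.05 copy-neutral LOH.  The mosaic cell fraction
inverts the mixture algebra above: loss `f = 4Δ/(1+2Δ)`, gain
`f = 4Δ/(1−2Δ)` (capped at 1; Δ ≥ 1/6 already implies a pure gain), CNLOH
`f = 2Δ`.  These closed forms are derived from first principles — the
original publication names no estimator — and round-trip exactly against
the generator's forward model.

The **targeted focal test** guards against missing a deletion too small for
genome-wide segmentation: Welch two-sided t-tests compare the target
region's probe LRR, and the heterozygous-probe Δ, against a whole reference
chromosome (chromosome 1).  The human coordinates of the classic focal
13q14.3 interval are shipped as a preset label
(`focal_13q14_region()`); simulated tracks use toy-genome coordinates.
Manual review of candidate calls is inherently non-algorithmic and is
surfaced as a reviewable segment table rather than automated away.

# Allele-frequency trajectories

Sites flagged as population polymorphisms or database SNPs are removed,
then sites not reaching depth 30 in every one of the seven samples
(inclusive).  The germline filter is a correlation PCA of the per-site
trajectories (rows centred, columns standardized, values in percent): the
PC1 sign is oriented so that its correlation with per-site trajectory
variance is negative, making the published "remove PC1 > −1" rule
reproducible despite PCA sign ambiguity.  The percent scaling is this
package's choice — the original scaling is unstated — and the threshold is
a parameter for that reason.  A one-sided threshold keeps one trajectory
family per dominant PC1 direction; in the default synthetic patient the
clone that rises late is anti-correlated with the clone that vanishes, so
its sites can fall on the removed side.  This is a faithful property of the
procedure, not an artefact of the implementation.

Retained trajectories are clustered with the **self-organizing tree
algorithm** (SOTA), implemented from its published description: a binary
tree of prototype vectors grows from one root with two leaves; profiles are
presented in input order to their best-matching leaf, which moves toward
the profile at rate 0.1, dragging parent (0.05) and sibling (0.01) along
while the sibling is also a leaf; when an epoch's relative error change
falls below tolerance, the leaf with the largest resource (mean member
distance) splits; growth stops at 12 leaves by default, or earlier with a
warning when all resources are zero.  The procedure is deterministic given
the seed and input order.  Clusters whose centroid range (max − min over
time) is below 0.1 allele-fraction units are pruned as residual germline
signal — the original criterion ("changed in a small range") has no
published value, so 0.1 is this package's default.  Surviving centroids are
labelled by rule: monotone decrease (Spearman ρ ≤ −0.8) ending near zero is
"lost", monotone increase is "increasing", an interior peak returning to or
below the start is "transient", anything else "other".  MAF is defined as
alt/depth, unfolded, to preserve trajectory direction.

# Single-cell expression

**QC cascade**, applied in order: cells with fewer than one million mapped
reads are dropped; cells expressing more than 8,000 genes (FPKM > 1) are
dropped as suspected doublets; only protein-coding genes are kept; the
*core gene set* is defined as genes expressed in at least half the
remaining cells; cells both below the 10th percentile of core-set
expressed-gene count *and* with mean core-set FPKM ≤ 1 are dropped (the
rule is conjunctive); genes with mean FPKM above the 99th percentile are
dropped.  The core set persists as the gene filter — the alternative
reading (core set as a cell-QC reference only) is possible, and both counts
appear in the QC report.

**Iterative clustering**, three rounds: PCA of the current gene set
(log2(FPKM+1), per-gene standardized; component signs fixed by making each
loading vector's largest-magnitude entry positive, so the procedure is
fully deterministic); the union of the top-20 |loading| genes of the first
four components (at most 80 genes) drives ward.D2 clustering of cells cut
at k = 6; a Kruskal-Wallis test per gene across the six groups with
Benjamini-Hochberg adjustment retains q < 0.01 genes as the next round's
set.  (R's "fdr" and "BH" adjustments are the same procedure.)  Cluster
letters A–F are assigned by decreasing size, the published assignment rule
being unstated.  The Kruskal-Wallis statistic is computed from its ranks
with tie correction and is verified against the reference implementation
to 10⁻⁹.

**Markers** are called per (gene, cluster) pair by the upper-tail
hypergeometric probability of the observed count of expressing cells in the
cluster, BH-adjusted across all pairs, q < 0.01.

# Pseudotime

Genes varying with sampling time (per-gene Kruskal-Wallis p < 0.01,
unadjusted) feed a 2-D embedding of log2(FPKM+1).  The default embedding is
plain PCA with sign-fixed components; a whitened-PCA + seeded 2-component
ICA mode is available.  The original workflow's embedding is
independent-component analysis, but whitening equalizes the variance of
signal and noise directions, and at desk scale that destroys the path
structure of the minimum spanning tree built on the embedding — the PCA
default preserves relative variances and is the package's deliberate
deviation, kept as the default rather than a fallback.

The Euclidean MST over cells (via igraph, Prim's algorithm) yields the
**backbone** (weighted diameter path); with the path number set to 2, the
longest side branch defines a second path, decomposing cells into three
trajectories: backbone before the branch point, branch, backbone after.
Every cell attaches to its nearest skeleton node by tree distance;
pseudotime is the geodesic distance from the backbone root, ranks break
ties by cell index.  **Time anchoring** then divides cells into three
pseudotime phase groups (tertiles — the published phase boundaries are
undefined), sets the group richest in earliest-year cells as the start and
the group richest in the two late years as the end, preserving relative
order within groups; ties break toward the original order with a warning.
Finally genes are grouped (default 10 groups) by ward.D2 on their
rolling-mean-smoothed (window = cells/20), standardized profiles along the
ordering, and each group is tagged by comparing its smoothed mean over the
first/middle/last thirds of the path (margin 0.25 sd), yielding tags like
"high-low-high".  The differential-expression test is Kruskal-Wallis
rather than the generalized additive likelihood-ratio test of the original
toolchain; this substitution is deliberate and documented.

# Numerical choices and problem sizes

* CBS: α = 0.01, 1,000 permutations, minimum segment width 3 bins, merge
  tolerance 0.05; exact early stopping of permutations.  The 250-cell
  end-to-end subclone-recovery simulation runs segmentation with 200
  permutations (α·n = 2, so a split is accepted only with ≤ 1 exceedance) —
  the package's problem-size scaling for its largest routine validation;
  all other analyses use the 1,000-permutation default.
* Validation problem sizes: 100 profiles × 1,000 bins for the MAPD oracle;
  200 single-step profiles for breakpoint recovery; 5 clones × 50 cells ×
  10,000 bins at 100 reads/bin for subclone recovery; 1,000 heterozygous
  probes per mosaic-fraction condition; 1,000 null and 200 alternative
  replicates for the focal test; 500 trajectories for SOTA; 300 cells for
  expression clustering; 150 cells for pseudotime; exhaustive spanning-tree
  enumeration up to 8 cells.
* Ties: hierarchical clustering follows `stats::hclust` (deterministic in
  input order); pseudotime rank ties break by cell index; SOTA presents
  profiles in input order.
* Degenerate inputs are defined, not crashed: constant segments give one
  segment; zero-variance t-tests return p ∈ {0, 1} by the stated
  convention; all-identical SOTA profiles halt growth with a warning;
  constant trajectory matrices classify everything germline-like with a
  warning.

# Limitations

The generator omits library-prep amplification artefacts (MALBAC/MDA
biases beyond Poisson + GC), read-level simulation, alignment artefacts,
tri-allelic sites, and the zero-inflation of real single-cell expression;
the package does not call somatic variants, fit integer ploidy, refine
breakpoints to base pairs, or perform pathway enrichment.  Passing the
simulation suite demonstrates the procedures are implemented correctly
under their stated models, not that the thresholds (MAPD 1.4, q < 0.01,
range 0.1, …) are optimal for any particular real data set.
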