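---
title: "Detecting de novo chromatin activation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting de novo chromatin activation: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Multiple myeloma is a plasma-cell malignancy whose tumor cells, compared
with normal B cells, show widespread activation of regulatory elements.
Because B-cell differentiation itself remodels every layer of the
epigenome, a naive tumor-versus-normal comparison confounds
disease-specific changes with cell-of-origin differences. The analysis
implemented here therefore restricts attention to the genome fraction that
is *stable across the whole normal B-cell maturation program* (naive B
cells from blood and tonsil, germinal-center B cells, memory B cells, and
tonsillar plasma cells) and asks where the tumor deviates from that stable
baseline. Bone-marrow plasma cells — the tumor's direct normal counterpart,
for which only H3K27ac and RNA can usually be profiled — enter as an
additional hard filter so that ordinary plasma-cell biology is not mistaken
for tumor biology.

`chromactiv` implements that analysis as a pipeline over peak calls
(six histone marks and ATAC), bedGraph signal, whole-genome bisulfite CpG
tables, and a gene-expression matrix, together with a synthetic-data
generator that plants known events so every stage can be validated without
controlled-access patient data.

## Stage 1: stable-baseline differential chromatin

For one mark and one population, **consensus peaks** are defined base-wise:
a base belongs to the consensus when peaks cover it in at least
`ceiling(min_frac * n)` of the population's `n` samples (default
`min_frac = 0.5`); maximal runs of such bases are merged. Base-wise voting
(rather than interval-level voting) makes the consensus identical to an
explicit boolean-mask computation, which the test-suite exploits as an
independent oracle.

"Stable" is operationalized strictly: a base is **stably present** when
every one of the five normal-population consensuses covers it, and
**stably absent** when none does. Bases covered by some but not all
populations are *unstable* and take part in no differential call — they are
exactly the differentiation-modulated fraction the design wants to
exclude.

Tumor **gain** regions are bases recurrent in at least
`ceiling(min_mm_frac * n_MM)` tumor samples (default `min_mm_frac = 0.66`)
restricted to stably absent ground; **loss** regions are stably present
bases supported by at most `floor((1 - min_mm_frac) * n_MM)` tumor samples
— near-absence rather than zero, so that isolated spurious peaks do not
veto a loss call. Both are filtered to `min_region_bp = 200` to suppress
fragment-scale artifacts. Raising `min_mm_frac` can only shrink the gain
set (a property the tests assert).

Each differential region is annotated with the fraction of tumor and
normal samples harboring an ATAC peak (one shared base suffices by
default), the median across samples of the per-sample mean CpG beta inside
the region (CpGs under 5 reads are dropped per sample), the host gene
whose body contains the region midpoint (midpoint of a width-w region is
its start plus `floor(w/2)`), and that gene's differential-expression
status.

## Stage 2: rule-based chromatin states

Downstream summaries need one state label per region and sample, not a
trained segmentation, so states are assigned by a fixed, total rule table
over the six-mark presence vector: H3K4me3 with H3K27me3 is a bivalent
promoter; otherwise H3K4me3 with H3K27ac an active promoter, else a weak
promoter; otherwise H3K4me1 with H3K27ac an active enhancer, else a weak
enhancer; then H3K36me3 transcription, H3K27me3 Polycomb repression,
H3K9me3 heterochromatin, and low signal as the default. A deterministic
table makes every downstream count exactly reproducible; the cost is that
the nine labels cannot be mapped one-to-one onto any particular trained
chromatin-state model, and we make no such claim.

Group states are the majority across samples, with ties broken toward the
more active state (the vocabulary is ordered by activity). The
tumor-versus-normal **transition matrix** expresses, for each (tumor
state, normal state) cell, the percentage of differential regions making
that transition; its entries sum to 100 by construction, and the suite
checks this to 1e-9 on arbitrary inputs.

## Stage 3: de novo activated regions and superenhancers

A gain region for the activation mark (H3K27ac) is **de novo** when it
shares *zero bases* with any individual normal sample's peaks — the union
of raw sample peaks, not the consensus, because a single observed normal
peak already explains the signal as non-tumor-specific — including the
bone-marrow plasma-cell samples, whose absence is a hard error (an
explicit override exists and logs a warning). An independent second pass
(`audit_de_novo`) re-checks the zero-overlap contract on every reported
region.

Superenhancers follow the ROSE conventions, none being stated by the
upstream study: peaks fully inside ±2 kb of a TSS are excluded, the rest
are stitched at gaps up to 12.5 kb, and each stitched region is scored by
the mean across tumor samples of its total bedGraph signal (no
input-track subtraction; control tracks are out of scope). On the rank
curve with both axes scaled to [0, 1], the cutoff is the support point of
the slope-1 tangent line — the point minimizing y − x, where the curve's
tangent slope passes 1 — and everything ranked above it is a
superenhancer. This support-point formulation is numerically robust: a
rule that triggers on the first *local* inter-point slope ≥ 1 misfires on
real curves, because with n regions any local jump of about 1/n of the
signal range crosses slope 1 long before the true inflection. A flat
curve (all signals equal) yields no superenhancers by convention, and
fewer than three stitched regions leave the cutoff undefined (all
non-super, with a warning).

## Stage 4: target genes and coregulated neighbours

Enhancer-to-gene assignment is deliberately conservative: a candidate
target must have its TSS in the same TAD as the region midpoint, and must
be up-regulated in the tumor (BH q < 0.05 and linear fold change > 1.5)
against **every** normal population with RNA data, bone-marrow plasma
cells included — the same cell-of-origin logic as the peak filter. Regions
whose midpoint falls between TADs fall back to a ±1 Mb TSS window and are
flagged as such. All qualifying genes are linked; no tie-breaking is
attempted, so a region may have several targets and a gene several
regions.

Coregulated groups start from the linked gene list: genes are ordered by
TSS in the *full* annotation, and a candidate pair is two linked genes
with no other annotated gene's TSS strictly between them (an intervening
non-target gene breaks adjacency — the strictest reading of "adjacent";
target-list adjacency would be the permissive alternative). A pair is
kept when Pearson r > 0.5 with p < 0.05 across tumor expression samples,
both inequalities strict; kept pairs sharing a gene chain transitively
into maximal groups, which is how pairs and the occasional triplet arise.
The DE test operates on log2(x + 1) with the fold change taken on
pseudocounted linear means — the threshold logic (FDR < 0.05, |FC| > 1.5
two-sided on the linear scale) is the contract; the Welch t-test behind
it is the simplest defensible engine and is cross-checked against
`stats::t.test` gene by gene in the suite.

## Stage 5: motif-anchored DNA methylation

Supplied PWMs (MEME minimal format; uniform background by default) are
scanned over the de novo region sequences on both strands; a window is a
hit when its log2-odds score reaches 80% of the PWM's maximum attainable
score. N bases score −∞. CpGs within ±10 bp of a hit — "within or close
to" the motif; the choice is a documented default, not an inference —
are averaged per group over samples covering them with ≥5 reads, and a
CpG is called hypomethylated in the tumor when the tumor-minus-normal
delta is below −0.25 (an unsigned variant is available by flag). The
composite profile bins each CpG within ±2 kb of a hit center by its
offset (50 bp bins; bins with fewer than 3 CpG contributions are NA) and
averages group-mean betas per bin.

## The synthetic study and what it does (not) show

The generator's defaults *are* the simulated study design: a 2 × 10 Mb
genome tiled by ~80 kb TADs with 5 kb gaps; 300 genes; 200 planted de
novo regions (45 of them in 15 clusters of three within stitching range,
emulating superenhancers); H3K27ac, H3K4me1 and ATAC peaks planted in at
least 80% of 10 tumor samples and in no normal sample; 2 replicates for
each of six normal populations (bone-marrow plasma cells contributing
H3K27ac and RNA only); background peaks shared by all populations with
10% per-sample dropout and a 5% spurious-peak rate; 25 background peaks
per mark deleted in the tumor (the loss events); 37 tumor RNA samples and
3 per normal population, log-normal noise at CV 0.2, target genes up
4-fold in tumor only; 40 adjacent coexpressed pairs plus one triplet
coupled through a shared latent factor at Pearson r = 0.7; an
IRF-family-like 10-mer PWM planted at each region center whose in-motif
and flanking CpGs sit at beta ≈ 0.85 in normals versus ≈ 0.30 in the
tumor; a background CpG beta of 0.80 (within the narrow range consistent
with both the 0.85 motif-flank normals and a flat normal profile, and
typical of genome-wide CpG methylation); and ten 150 kb repressed blocks
(H3K27me3 or H3K9me3 in all populations) whose methylation drops
tumor-wide, emulating hypomethylation of inactive chromatin.

All randomness flows from a single seed, and generation is byte-identical
across runs at the same seed. Planted regions are guaranteed — and
re-checked after generation — never to overlap any normal-sample peak.

What passing tests on these data show: the interval algebra, voting
thresholds, filters, rank cutoff, linking logic and methylation
arithmetic do exactly what their definitions say, at realistic noise
levels, recovering planted truth with the precision/recall the design
permits. What they do not show: robustness to properties of real data the
generator does not model — copy-number distortion of ChIP signal,
fragment-level artifacts, batch effects, count-level expression noise
(the generator emits normalized abundances, since the pipeline consumes
them), sequence-composition bias around motifs, or incomplete TAD maps.

One sampling-theory note: with 37 tumor expression samples, the standard
error of a correlation estimated at r = 0.7 is about 0.09, so roughly one
planted pair in ten re-estimates more than 0.15 from its generating value
and a pair near the detection threshold occasionally drops below r = 0.5.
Recovery of ~90% of planted groups with zero background groups is
therefore the correct expectation, not a deficiency.

## Numerical and interface conventions

In memory all intervals are `GRanges` (1-based, closed), the native
convention of the Bioconductor interval stack this package builds on;
BED, bedGraph and the gene TSV are 0-based half-open on disk and
converted only at the reader/writer boundary, so no off-by-one reasoning
appears in analysis code. Strand is ignored for all interval arithmetic
(peaks are unstranded); gene strand is used only to place the TSS.
Chromosome-name dialects ("chr1" versus "1") are normalized by a
configurable prefix at read time. Degenerate statistical inputs have
fixed conventions: two zero-variance groups with equal means give p = 1;
all-zero genes give fold change 1; constant expression vectors make a
correlation undefined and the pair is skipped with a log message, not an
error.

Problem sizes used by the test-suite: the full planted study above backs
the acceptance-style checks (one generation plus one pipeline run, reused
across tests); a 2 × (3 + 2) Mb variant with 25 planted regions backs the
cheaper unit tests; statistical calibration uses 2,000 genes × 200
pure-null replicates; oracle-equivalence checks use 1,000 random
intervals against boolean base masks and exhaustive window scoring for
PWM hits.

## Known limitations

- The stable baseline is binary (present in all / absent in all); a
  population with systematically weaker peak calling shrinks both stable
  sets rather than being reweighted. Per-population recurrence is exposed
  (`min_frac`) but cross-population harmonization of unequal sample sizes
  is deliberately left to the user.
- Signal ranking for superenhancers uses raw bedGraph totals without
  input-track correction or copy-number awareness.
- The state vocabulary is a fixed rule table, not a trained model; its
  labels are operational, not biological ground truth.
- Target linking requires TADs as given; no TAD calling or Hi-C loop
  evidence is used, and no correlation between region signal and gene
  expression is required beyond the DE filter.
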