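---
title: "Differential histone-mark island analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential histone-mark island analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(islandiff)
library(dplyr)
```

# Scope and data model

`islandiff` implements the post-calling half of a paired (wild-type vs
mutant) broad-mark ChIP-seq analysis. Island and peak calling themselves are
out of scope: the package consumes caller output — interval tables with tag
counts, scores and summits — together with read-level tag libraries, binned
coverage tracks, a minimal TSS table, repeat-element intervals, genome
sequence and probe-set expression matrices.

Every interval is 0-based half-open `[start, end)`. Callers and browsers
disagree on coordinate conventions, and the original analyses do not state
one; converting once at the I/O boundary (1-based dialects are shifted on
read and restored on write) keeps all downstream arithmetic in a single
convention and avoids off-by-one drift. Chromosome names are never
rewritten. Abutting half-open intervals do not overlap, so `merge_regions()`
requires at least 1 bp of genuine overlap.

# Tag processing

**Repeat filtering.** Reads are collapsed to unique (chromosome, position,
strand) triples and removed when their extent overlaps a masked repeat
element by *more than* 5 bp; an overlap of exactly 5 bp is kept. The filter
is defined on reads, so overlap is computed on the raw read extent (36 bp
default, the sequencing read length) rather than the extended fragment —
the rule predates extension in the workflow and extending first would make
the filter fragment-length dependent.

**Extension and binning.** Reads extend strand-wise from their 5′ position
to the fragment length (200 or 300 bp depending on the library), deposit
bp-overlap-weighted mass into fixed bins (25 or 200 bp), and are scaled to
tags per million. Tags-per-million is a readability choice; any fixed
constant gives the same fold changes. Total mass is conserved:
`n_reads × fragment_length / (library_size/1e6)`, which the tests assert
exactly. Fragments running past a chromosome end are clipped and the
clipping reported.

**Pairwise normalization.** Two schemes serve fold-change comparisons:

* *Trimmed mean*: the larger library (by total counts) is scaled by
  `trimmedMean(smaller)/trimmedMean(larger)`. The trim is symmetric, 10%
  per tail, dropped by count with floor rounding — the convention of
  `mean(trim = 0.1)`. Scaling only the larger library leaves the
  better-sampled library's scale anchored to the smaller one rather than
  moving both.
* *Linear regression*: mutant counts are regressed on wild type (wild type
  is the reference; the direction is a package convention since either
  direction defines the same line) and normalized as
  `(mut − intercept)/slope`. A non-positive slope means the pair carries no
  common signal and is an error, not a silent fallback.

Both are exactly the identity on identical inputs, which the tests assert.
Quantile normalization of binned tracks maps each track's distribution onto
the mean of the order statistics (via `limma::normalizeQuantiles`), so the
sorted value vectors of all tracks coincide afterwards.

The trimmed-mean factor assumes most regions are unchanged. When a large
fraction of regions truly changes in one direction, the factor absorbs part
of the signal — with ~10% of islands decreased (the regime these filters
were built for) the residual bias on fold changes is a few percent, far
from the 1.8 threshold; with 50% decreased it becomes material. The
synthetic recovery checks therefore plant a 10% decreased fraction.

# Island filtering

Eligibility and artifact rules follow the published cascade with their
exact boundary semantics (`min 800 bp` is `≥ 800`; `> 50 tags`, `> 45`
score, density `> 0.03`/`> 0.04` are strict). Missing caller scores disable
the score clause with a warning instead of failing: island tables from
callers that report no score remain usable, and the remaining clauses still
apply.

Three artifact rules remove merged H3K27me3 regions: small TSS-distal
regions (`≤ 1.2 kb` and `> 5 kb` from the nearest TSS), island "tails"
(`< 2 kb`, within `< 5 kb` edge-to-edge of a `≥ 3×` longer island) and
high-input regions (normalized input density `> 0.024`). Design choices the
source leaves open, fixed here:

* The tail rule is evaluated against the *unfiltered* merged set: a tail
  should be judged against its neighbour even if that neighbour is itself
  excluded later by another rule.
* Distances are edge-to-edge in bp and ignore strand. A TSS on the first
  base past a region edge is 1 bp away; a TSS inside the region is 0 bp
  away. Vicinity (`< 5 kb`) between regions is the count of intervening
  bases, so abutting regions have gap 0.
* "Input's normalized tag/length ratio" is the library-size-normalized
  (tags-per-million) input count over the merged region, divided by region
  length.

Per-gene island selection minimizes the edge-to-TSS distance (0 when the
island spans the TSS), breaking ties by larger tag count and then leftmost
start, so the selection is deterministic.

# Differential calls and expression integration

A pseudocount of 1 (raw-count scale) is added to both sides before ratios;
the source is silent on zero-count regions and a pseudocount keeps every
ratio finite while shifting large counts negligibly. All fold-change
thresholds are strict (`> 1.8`, `> 4`), mirroring the wording of the
original figure legends. The 1.8 threshold can be applied to raw
pair-normalized counts or to per-bp densities (counts/length); both
supports are exposed since the analyses used both framings — over identical
regions the two are equivalent, and they differ only across regions of
different lengths.

k-means clustering of tag-density matrices runs on row-standardized values
with a fixed seed and 25 restarts (the original used external clustering
software without stated settings; standardization makes shape, not
amplitude, drive cluster membership). Group assignments that the original
work made by visual inspection of browser tracks are out of scope as
automated calls.

Expression integration selects, per gene, the probe set maximizing
expression × fold change (ties by identifier order) and flags genes as
dynamically regulated when their linear-scale max/min across samples
exceeds 4. Expression is stored log2; the filter converts internally.

# Annotation and co-localization

Promoters are the strand-oriented closed window from 10 kb upstream to 1 kb
downstream of the TSS; gene bodies run from beyond the +1 kb position to
the annotated body end; everything else is intergenic. Promoter takes
precedence, and among several overlapping genes the nearest TSS wins (the
source is silent; nearest-TSS is the standard HOMER-style resolution). The
closed window bounds are a documented choice — the source states the window
as "−10 and 1 kb" without saying whether the bounds are inclusive.
`annotate_regions()` is a total function: the three labels partition every
input set, asserted by test.

Venn partitioning merges all input sets and assigns each merged region the
subset of sets overlapping it; cell counts always sum to the merged-region
total and obey inclusion–exclusion, both asserted by test. Printed overlap
percentages round half-up (`overlap_percentage()`), reproducing the
published rounding of e.g. 4,689/5,351 → 87.6%.

# The motif-density statistic

For each peak, a 301-bp window (±150 bp of the summit) is scanned for
GGGA/GGAA and their complements TCCC/TTCC — including the complements in
the motif set covers both strands in one forward scan. Overlapping
occurrences count separately and `N` never matches. The null shuffles each
window's own bases (composition preserved exactly, asserted per shuffle)
`n_permutations` times; the default is 100 shuffles per window and the seed
is a required argument.

The χ² construction deserves care. The classical one-cell goodness of fit,
`(O − E)²/E` against χ²(1), implicitly assumes Poisson-scale variance for
the pooled count `O`. Motif occurrences are clumped — GGGAA contains both
GGGA and GGAA, so occurrences arrive in overlapping clusters — and the
pooled count is overdispersed by a factor of roughly 1.2 for this motif
set. Under a null simulation the one-cell statistic therefore rejects at
about 7.5–8% for a nominal 5% level. The package's default, `perm_var`,
keeps the same χ²(1) reference but divides the squared deviation by the
permutation-estimated null variance, inflated by `1 + 1/m` for the noise of
the estimated expectation over `m` permutations:

$$X^2 = \frac{(O - \hat{E})^2}{\widehat{\mathrm{Var}}(O)\,(1 + 1/m)} \sim \chi^2_1 .$$

This is calibrated (measured type-I error ≈ 0.055–0.06 at α = 0.05 over
2,000 null replicates) because the permutation distribution carries the
clumping. The one-cell form remains available as `method = "gof"` and in
`chi2_enrichment()` for comparability. The consensus-motif scanner
(`scan_core_motif()`, default `AGGAA[AG]` within ±40 bp) reports a match
when its leftmost base lies within the summit window, scanning both strands
via reverse complement.

# The synthetic-data generator

`sim_config()`/`simulate_genome()`/`simulate_tags()` emulate the
statistical structure the pipeline assumes: non-overlapping genes on
uniform-length chromosomes, repeat elements covering a configurable genome
fraction, planted islands centred on TSSs (plus a configurable intergenic
fraction), per-bp Poisson tag emission (`background_rate` outside islands,
`× enrichment_fold × fc` inside), uniform strands, motif copies planted by
base replacement (never insertion, so coordinates stay fixed) around peak
summits, and probe-set expression where decreased-mark genes receive an
8-fold mutant increase with probability 0.88 — the coupling rate observed
in the study system. Defaults of 0.005 tags/bp background and 20-fold
enrichment give islands of several hundred tags at realistic sequencing
depth, the regime where fold-change calling without replicates is sensible.
One replicate per condition mirrors the original design.

Poisson emission (not negative binomial) is deliberate: the pipeline's
arithmetic is pure counting, and Poisson is the minimal model matching it.
Real data add overdispersion between biological replicates, GC and
mappability bias, fragment-size variation and duplicate structure — none of
which the generator models. Passing recovery tests therefore demonstrates
the *bookkeeping* is correct (filters, normalization, thresholds,
labelling), not that fold-change calling is robust to biological variance.

Recovery checks run at 200 islands × 5 seeds with 2–3 kb islands and
expected wild-type island counts of 500–750 tags, planting a 0.3× mutant
fold change in 10% of islands: measured sensitivity 1.00 and false-positive
rate 0.00 against the strict 1.8 threshold. The χ² calibration uses 2,000
null replicates of 20 windows with 50 permutations each; these sizes are
the package's reference problem sizes and complete in about 90 seconds.

# Degenerate inputs and numerical notes

Empty region sets flow through every operation (empty tracks write
header-only files; empty peak sets give no induced islands). Constant count
vectors give a trimmed-mean scale of 1 but are a regression error (no
slope). Zero-variance rows are centred but not scaled before clustering.
Values in tracks are written with at least four significant digits and
round-trip within 1e-6. Windows clipped at chromosome ends keep their
remaining sequence and are flagged.

# Known limitations

* No statistical significance testing of differential islands: the method
  is a pure fold-change threshold by design, and the package does not add
  one.
* No replicate-aware variance modelling, GC/mappability correction, or
  duplicate-read modelling.
* SICER/MACS scoring is treated as an opaque input; BAM/SAM and full
  GTF/GFF parsing are out of scope (a minimal TSS table stands in).
* De novo motif discovery is not included; `scan_core_motif()` covers only
  a stated consensus.
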