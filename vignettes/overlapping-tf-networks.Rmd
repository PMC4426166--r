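---
title: "Methods: overlapping TF target networks, expression overlays and the circle/box layout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: overlapping TF target networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfoverlay)
```

## The problem and the model

A ChIP-seq experiment per transcription factor (TF) yields thousands of
binding peaks; assigning each peak to a gene produces, for each TF, a target
set of thousands of genes. The object of study is the *overlapping target
network*: the bipartite graph whose hub nodes are the k TFs and whose leaf
nodes are the union of their target sets, with an edge (TF, gene) whenever
the TF binds near the gene. Biologically, the interesting structure is the
*Venn partition* of the targets — each gene's membership signature, the
exact subset of TFs binding it — because co-regulated genes (signature of
size ≥ 2) are candidates for shared regulatory programs.

`tfoverlay` keeps hub and leaf identities strictly disjoint. When a TF of
the network itself appears in another TF's target list (TFs do bind each
other's promoters), that occurrence is represented as a separate target
node named `<gene>@target`. The alternative — letting one node be both hub
and leaf — would make the circle/box layout, the filter semantics and the
Venn partition all ambiguous.

## Peak-to-gene assignment

Raw COD-style peak lists carry 1-based inclusive genomic intervals; they are
converted at the boundary to the package's single internal convention,
0-based half-open (a 1-based row with `start == end` is a valid 1 bp peak).
A peak is assigned to the gene whose transcription start site (TSS) is
nearest to the peak midpoint `floor((start + end)/2)`, provided the distance
is at most `window` (default 10,000 bp, a common promoter-proximal
convention); exact ties go to the lexicographically smallest gene symbol so
the assignment is deterministic and checkable against an exhaustive
all-pairs scan. Peaks beyond the window, or on chromosomes absent from the
annotation, are dropped with a logged count. Peak strand is ignored (ChIP
peaks are unstranded); the TSS is taken from the annotation as given. This
nearest-TSS rule is deliberately the simplest defensible assignment; distal
enhancer–gene linking is out of scope.

## Expression statistics

Log fold change is `log2((mean(num) + ε)/(mean(den) + ε))` on linear-scale
intensities — the ratio of arithmetic group means, not the mean of
per-sample log ratios, which differs and is stated explicitly for that
reason. The pseudocount ε defaults to 0 and is only needed for genes with
non-positive means (the error message suggests it).

The per-gene test is a two-sided unpaired *t*-test via `stats::t.test`, with
the Student equal-variance flavour as the default (the common default in
biology software) and Welch selectable. Genes with zero variance in both
groups get `p = 1` (equal means) or `p = 0` (unequal) by convention rather
than `NaN`, because downstream numeric filters need orderable values; the
count of such genes is logged. No multiple-testing correction is applied —
the filter thresholds are display cut-offs chosen by the user, and
correction is left as a user responsibility.

Gene-symbol matching between value maps and the network is exact and
case-sensitive: silent case-folding can collide mouse and human symbol
conventions.

## Filtering

The filter grammar is a flat list of clauses `[abs(] attr [)] CMP number`
joined by a single combinator (`and` or `or`, never mixed; no parentheses).
This deliberately small grammar covers every practical use case — e.g.
`logfc > 4 or logfc < -4` (the complement of "between −4 and 4", i.e. at
least 16-fold difference), `abs(logfc) > 4`, `pvalue < 0.001` — while being
trivially parseable and diagnosable.

Boundary semantics are **strict**: a gene with `logfc` exactly 4 is *not*
up-classified and does not pass `logfc > 4`. The classification thresholds
default to −4/+4. Unannotated genes never satisfy any clause: absence of
evidence must not promote a gene into the expert's view. Non-passing genes
are either *blurred* (kept, drawn faded) or *hidden* (removed, with their
edges); the visible set is identical between the two modes.

## The circle/box layout

TF i (0-based, in network TF order) is anchored at angle
`π/2 − 2πi/k` on a circle of radius R (default 100 units): first TF at the
top, proceeding clockwise, all gaps exactly `2π/k`. Each membership
signature S gets a fixed axis-aligned box centred at
`shrink × centroid(anchors of S)` with `shrink = 0.6`, so exclusive regions
sit near their TF and fuller signatures sit toward the centre — the
k-set Venn diagram made literal. The box defaults (0.5 R × 0.35 R) keep
neighbouring regions visually separate at k ≤ 6 without tuning.

Two choices here were genuinely open and are fixed as follows. *Collisions*:
distinct signatures can have coincident centroids (e.g. two opposite pairs
at k = 4); boxes are processed in canonical order (fewer members first, then
TF-order indices) and any centre within `0.05 R` of an earlier one is nudged
radially outward in steps of `collision_offset` (default 0.15 R) until
clear; a centre at the origin takes its first member's anchor direction.
*Randomness*: targets are placed uniformly inside their box, in
lexicographic gene order, through a single RNG stream seeded from
`layout_params(seed=)` — so the layout is bit-reproducible given (network,
params) and independent of input file ordering, and node overlaps are
permitted (overlap-free packing would cost far more than it is worth at
~7,400 nodes). A plain force-directed layout (`layout_force`, igraph
Fruchterman–Reingold) is exposed behind the same interface as an optional
alternative.

## Rendering

Squares are TFs (drawn at twice the target size and labelled under every
policy except `none`); circles are targets. Up-regulated passing genes are
solid red (220, 20, 20), down-regulated solid blue (20, 20, 220), everything
else grey (128, 128, 128). "Blurring" is implemented as reduced alpha
(default 0.15) rather than a raster blur pass: it is resolution-independent,
cheap, and visually equivalent. Output formats are PNG (default), SVG, and
GIF; the GIF encoder is a minimal self-contained GIF87a writer (≤256-colour
quantisation by per-channel bit reduction, LZW stream in the fixed-width
literal idiom) because no installed R imaging package emits GIF; it has been
validated against an independent decoder. Hidden nodes and their edges never
reach the style map or the drawing.

## The synthetic generator

`synthetic_spec` describes a study by its Venn region counts (exact, not
sampled), the fold changes planted on named regions, the replicate count,
the log2-scale noise SD and a seed. Gene symbols are assigned
deterministically region by region, so `overlap_stats` recovers the
requested counts exactly — a round-trip identity used throughout the tests.
Expression is `base × 2^(±logFC/2) × 2^N(0, σ)`: the effect is split
symmetrically across the two groups (keeping the overall intensity scale
comparable) and the noise is multiplicative log-normal, the standard
microarray error structure, which keeps linear intensities positive. With
σ = 0 the group means are exact and every planted logFC is recovered
bit-for-bit up to floating-point rounding of `2^(fc/2)`.

The flagship scenario `demo_two_tf_spec` fixes two TFs with region counts
4532 / 1218 / 1682: 7,432 targets (7,434 nodes), the second TF sharing
exactly 58% of its 2,900 targets with the first, and 13 shared-region genes
planted beyond ±4 log2 FC (noise-free by default). Those three round numbers
— network size, overlap percentage, and the count of large-effect
co-regulated genes — are the scale and structure of a real two-factor
cardiac fibroblast study, and they are what `scripts/acceptance.R`
recomputes from scratch.

What the generator does *not* emulate: probe-level microarray artefacts
(the SOFT fixtures use one probe per gene; multi-probe collapsing is tested
with separately constructed files), peak-calling noise (fixture peaks sit
exactly on their gene's TSS), correlated genes, and batch effects. Passing
tests therefore demonstrate algorithmic correctness on clean data with
known truth, not robustness to real-data pathologies.

## Numerical and I/O choices

* COD column detection is by case-insensitive header name
  (`chromosome|chrom|chr`, `start`, `end`), tolerant of CisGenome-style
  dialect variants; unrecognised columns are preserved.
* SOFT probe→gene collapsing defaults to the **median** (robust to a single
  saturated probe); mean and max are selectable. Probes with a blank symbol
  are dropped; the gene count always equals the number of distinct
  non-empty symbols.
* Tuple inputs auto-detect tab vs comma (tab preferred); duplicate edges
  collapse with a warning; duplicate genes in a value table are an error
  (the value would be ambiguous).
* GraphML attributes are written as `double` with `%.17g`, which
  round-trips IEEE doubles exactly; the node-type attribute (default
  `nodetype`, values `tf`/`target`) is a string and its name is
  configurable on read.
* Problem sizes in the test suite: 200 random networks (k ≤ 5, up to 5,000
  genes) for the Venn partition oracle, 1,000 random small-sample t-test
  cases against a numerical-integration oracle at 1e-10, a 5,000-gene null
  simulation for type-I error calibration, and the full 7,434-node pipeline
  including rendering — the package's natural working scale.

## Known limitations

* The nearest-TSS rule ignores enhancer–promoter loops; a gene regulated
  only distally will be missed or mis-assigned.
* The layout conveys membership, not effect size or distance; position
  within a box is meaningless by design.
* The filter grammar has no nesting; complex predicates need two passes or
  a precomputed derived attribute.
* GIF output quantises to ≤256 colours; anti-aliased edges may band
  slightly. Use PNG or SVG for publication.
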