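---
title: "Methods: repressive-domain calling from pooled tiling sort-seq screens"
author: "rdscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repressive-domain calling from pooled tiling sort-seq screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdscreen)
```

## The screen and its statistical model

A pooled tethering screen expresses, in each cell, one Gal4-DBD-fused
50-amino-acid fragment ("tile") from a library tiled across candidate
regulators. Cells are FACS-partitioned by reporter fluorescence into a
GFP-negative (repressed) and a GFP-positive fraction, and tile abundances
are sequenced per fraction. A tile carrying a repressive domain (RD) shifts
its carrier cells into the negative fraction; the analysis problem is to
turn per-fraction fragment counts into positional RD calls on each protein.

`rdscreen` treats each CDS position independently. With collapsed fragment
coverage $c^-$ and $c^+$ at a position and stratum-wide totals $T^-$ and
$T^+$ (one stratum = one replicate of one reporter), the enrichment is the
depth-normalized ratio

$$\mathrm{FC} = \frac{c^-/T^-}{c^+/T^+},$$

and significance is the one-sided upper tail of the hypergeometric
distribution: drawing $K = c^- + c^+$ fragments from a population of
$T^- + T^+$ of which $T^-$ are "negative", $P = \Pr(X \ge c^-)$. This
conditions on the position's total observed depth and on the library-wide
fraction sizes, so unequal sequencing depth between fractions is absorbed
by the margins rather than modelled. P-values are Benjamini–Hochberg
corrected across all positions of all genes within the stratum.

Assumptions worth stating: one tile per cell (no co-transfection), fragment
counts proportional to sorted cell counts after UMI deduplication, and
independence across positions (ignored positional correlation makes the
per-position P-values conservative building blocks for *region*-level
calls, which require long qualifying runs).

## Region calling

Core regions are maximal runs of positions satisfying all of: coverage of
at least `min_cov = 10` fragments in *both* fractions (so the ratio is
estimable), $\mathrm{FC} \ge 1.5$, $P \le 10^{-5}$, over at least 60 nt
(20 AA — about the size of the shortest well-characterized RDs). Each core
is then extended outward through flanking positions; a side stops once 60
consecutive positions with $P > 10^{-3}$ have been seen (or the CDS ends)
and is trimmed back to the last position with $P \le 10^{-3}$. The
extension recovers the full enriched footprint around a core without
letting isolated sub-threshold positions beyond a long dead stretch rescue
it; we read "until P > 1e-3 over ≥ 60 bp" as exactly this
run-of-60-failures stop with trimming — the alternative reading (keep the
walked span untrimmed) would end regions on 59 failing positions, which we
consider unintended.

Replicate reconciliation keeps regions found in all replicates of a
reporter with an overlap of at least 50% of the *shorter* region, retaining
the *longer* one (which replicate's coordinates define a kept region is a
genuinely open choice; retaining the longer is consistent with the
cross-reporter rule, where the longest region of an overlap cluster is kept
explicitly). After the cross-reporter merge, every surviving region's
enrichment is recalculated in every screen; a region is labelled with a
reporter when its mean enrichment there exceeds the other reporter's by
more than 1.3-fold, otherwise it is a "global" hit. Each region is
represented by its most enriched fully-contained 50-AA tile (ties to the
leftmost; regions narrower than a tile — possible with 15-nt tiling — fall
back to the maximally overlapping tile).

All coordinates are 0-based half-open nucleotide offsets within the CDS
internally; reports use 1-based closed amino-acid intervals.

## UMI deduplication

Mapped fragments carry 10-nt unique molecular identifiers. Within each
(fraction, replicate, reporter, tile) group, UMIs within Hamming distance 2
are treated as PCR/sequencing images of one molecule. The collapse is
greedy in decreasing read-count order with lexicographic tie-break: each
UMI is absorbed into the first retained UMI within distance 2. The
greedy directional scheme (rather than transitive clustering) is standard
practice, deterministic, and idempotent — retained UMIs are pairwise more
than 2 apart, so re-collapsing changes nothing. Whether read counts should
order the absorption at all is not derivable from the collapse rule alone;
count-ordering makes the true molecule (most reads) the representative in
the common case.

## The synthetic screen

The simulator generates what the analysis consumes, with known ground
truth. Its defaults are the package's standard validation scenario:

| parameter | default | rationale |
|---|---|---|
| genes | 60, ~400 AA (gamma, CV 0.25) | typical TF length; enough genes for stable totals |
| planted RDs | 25% of genes, one 12-AA core each | minority of proteins repressive; core ≈ known SLiM-bearing RD cores |
| strength | uniform in [0.8, 1] | strong repressors, the regime the screen is designed to catch |
| sort error *b* | 0.02 | a cell sorts GFP-negative with probability $b + (1-b)s$ |
| cells | 200,000 per replicate, 2 replicates | ~19 cells per tile, matching a well-powered pooled screen |
| tile abundance | symmetric Dirichlet, $\alpha = 5$ | CV ≈ 0.45, a realistic synthesis-pool unevenness |
| PCR copies | geometric, mean 1.5 | exercises the UMI collapse |
| UMI errors | 0.001 per nt | Illumina-scale; exercises the ≤2-mismatch rule |

A tile is repressive iff its 50-AA window fully contains the planted core —
the sufficiency semantics of tethering assays. CDSs are uniform draws over
the 61 sense codons (no internal stops in frame). One cell carries one tile.

What the simulator does *not* emulate — and what passing tests therefore do
not show about real data: mapping and demultiplexing errors, partial-core
repression, bipartite or cooperative domains, expression-level variation
between tiles, position effects of the reporter, or biological replicate
batch effects. The recovery results below are statements about the
statistical pipeline under its own generative assumptions, not about wet-lab
performance.

Under the default scenario the pipeline recovers planted cores essentially
perfectly (precision and recall 1.0 at ≥ 50% overlap of the shorter
interval; `scripts/acceptance.R` recomputes this). Called regions are much
wider than the planted 12-AA cores because every tile containing the core
is repressive, producing an enriched footprint of up to ±38 AA around the
core; the 50%-of-shorter matching rule scores recovery of the core, not of
its footprint. Null specificity is assessed on screens with nothing planted
(30 genes, 60,000 cells, one replicate — one stratum so the raw caller is
tested without replicate intersection hiding false positives, scaled for
test-time); across 20 simulations the mean number of called regions is 0.

## Motif analysis

PWM scanning follows the FIMO construction: per-window score
$\sum_i \log_2 \left( p_i(a_i)/b(a_i)\right)$, with the exact P-value of a
window score computed from the null distribution of scores over
background-drawn windows, obtained by dynamic programming over columns
after discretizing column scores to $10^{-3}$ bits. The observed score is
discretized identically, so the DP tail equals exhaustive enumeration
exactly (the tests verify this to $10^{-9}$ for widths up to 4). Zero cells
are floored at a pseudoprobability of $10^{-4}$ and columns renormalized,
keeping log-odds and KL divergences finite. The default background is
uniform (1/20); published FIMO runs use their own background model, so
instance counts on real motif sets can shift — a documented divergence
risk. Matches are reported at $P \le$ threshold (stringent $10^{-4}$,
lenient $10^{-3}$); RD classification (known SLiM > novel discovered motif >
unexplained) uses instances at $P < 10^{-5}$, excluding designated
low-complexity motifs.

Motif similarity is a Kullback-based distance: for each ungapped offset
with at least 4 aligned columns, the mean symmetric KL divergence over the
union span (unaligned columns scored against the background), minimized
over offsets — an approximation of the TOMTOM kullback mode sufficient for
the downstream clustering contract, without TOMTOM's significance
calibration. Clustering then uses 1 − Pearson correlation between distance-
matrix rows, complete linkage, tree cut at 0.7.

SLiM scans are anchored regexes reporting all (including overlapping)
matches; the shipped pattern file is an editable consensus approximation of
the co-repressor-interacting ELM classes (EH1, WRPW, PxDLS, Sin3A-SID,
HBM) — substitute a specific ELM release for database-exact scans. SLiM
enrichment in RDs over non-RD, non-overlapping 50-AA background fragments
uses the two-sided Fisher exact test.

## Conservation

Column conservation is the Karlin-style mean pairwise similarity
$\frac{2}{n(n-1)} \sum_{i<j} M(a_i,a_j)/\sqrt{M(a_i,a_i)M(a_j,a_j)}$ over
non-gap residues, min–max normalized per alignment to [0, 1]. The
similarity matrix is BLOSUM62 shifted so its minimum entry is +1 (the ratio
needs positive entries); the matrix is exposed as a parameter because the
reference implementation of this score does not print its internal matrix —
absolute score values are therefore implementation-specific while the
motif-versus-flank *contrast* is robust. Flanks are one motif-length window
on each side (total 2× the motif; the alternative "total = motif length"
reading is selectable via `flank_mode`). Per motif type, motif-versus-flank
means are compared by two-sided paired Wilcoxon signed-rank tests (exact
for n ≤ 25 without ties, normal approximation with continuity correction
otherwise; all-zero differences give P = 1), BH-corrected across types.
Metaplots show median conservation per position within ±100 AA, aligned on
the motif center by default.

## Numerical and degenerate-input choices

* Enrichment at $c^+ = 0, c^- > 0$ is flagged `Inf`; both-zero positions
  have undefined FC and never qualify. Statistics always use raw collapsed
  counts; counts-per-million are display-only.
* Uncovered tiles never win representative-tile selection (their ratio is
  treated as $-\infty$).
* Fisher tables with a zero margin give P = 1 and an undefined odds ratio.
* Constant rows in the motif-distance matrix (undefined correlation) are
  treated as maximally distant, with a warning.
* Catalog entries shorter than one tile or out of frame are rejected with a
  warning; a flush-end tile is appended only when its start preserves the
  reading frame (for in-frame CDSs it always does), so the C-terminus is
  covered without frame breaks. Identical tile sequences from several loci
  are counted once as distinct fragments, keep all origins, and are
  excluded from coverage (they cannot be mapped uniquely).
* Tiles whose translation contains a stop codon are kept but flagged.

## Known limitations

Per-position hypergeometric tests ignore the 150-nt dependence between
neighbouring positions; the region caller compensates by requiring long
qualifying runs, but P-values of single positions should not be interpreted
marginally. Overlapping RDs within one enriched footprint are not
deconvolved. The simulator's one-cell-one-tile and full-core-containment
models are idealizations. Conservation scores are comparable within an
alignment, not across scoring implementations.
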