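---
title: "Methods: inferring regulatory context for lineage-specific genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring regulatory context for lineage-specific genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lsgpipe)
```

## The problem

Lineage-specific genes (LSGs) — genes with no detectable homologs outside a
taxonomic lineage — cannot be annotated by sequence homology. `lsgpipe`
implements a guilt-by-association strategy for such genes: starting from
microarray expression profiles, it grows co-expression clusters around the
uncharacterized transcripts, then asks what the promoters of each cluster
have in common (over-represented transcription factor binding sites, singly
and in spatially constrained combinations, plus de novo motifs), and which
cluster genes sit at the hubs of the weighted co-expression network. The
design mirrors a peripartal cattle study: an 18-tissue intensity panel and
a liver time series over seven time points (days −65 to +49 relative to
parturition) under two planes of nutrition (ad libitum vs energy
restricted).

Because the original microarray accessions, the commercial PWM library and
the repeat-masked genome cannot be redistributed, the package ships a
seeded synthetic-data generator that emulates all three with known planted
truth. Every pipeline stage is validated against that truth.

## Expression filtering

Tissue-panel genes are retained when at least one spot is simultaneously
flagged present, strictly above that sample's negative-control median
intensity, and at or above 250 fluorescence units (`filter_panel()`).
Time-series genes additionally need per-spot significance below 0.05 in at
least one sample-point; the intensity condition (floor 150) and the
significance condition are evaluated independently across sample-points —
they need not hold at the same spot. That independent reading follows the
filter's two separate "in at least one sample-point" clauses; a joint
reading would be stricter and is not what the rules say. Values equal to
the control median fail the "above control" test (strict inequality);
values equal to the intensity floor pass (inclusive).

## Diet-within-time contrasts

Log2 expression ratios are analyzed per gene by ordinary least squares on
the (time, diet) cell means, reporting the diet difference at each time
point with a pooled-variance standard error and a two-sided t test. The
original analysis used a mixed model whose random-effect structure was not
specified beyond the fixed diet-within-time effect; with no stated random
terms to reproduce, the fixed-effects cell-means model is the transparent
choice, and the simplification is deliberate and documented here. Empty
cells yield not-estimable (NA) contrasts rather than errors.
Benjamini–Hochberg correction is applied jointly across all gene × time
tests — the conservative scope, since the original scope was unstated.

## Seed-based clustering

Seeds (the LSG profiles) are grouped by single-linkage at Pearson r ≥ 0.90;
single linkage is the natural reading of "clustered at a threshold" and is
configurable. Each group's representative is its medoid (highest mean
correlation to the group; ties to the lexicographically smallest id).
A cluster is every gene correlated at r ≥ 0.90 with the representative;
it is then adjusted to an average pairwise correlation ≥ 0.75 by greedily
removing the non-seed member with the lowest mean correlation to the rest
(deterministic, monotone, seed-protecting). If only seeds remain below
threshold the cluster is returned flagged rather than mutilated.
Correlations use pairwise-complete observations with a minimum overlap of
3; pairs below that are undefined and excluded. Overlapping clusters are
resolved by keeping the largest (`overlap = "keep-largest"`), the only
resolution rule implemented. Tissue preferentiality is an inclusive
boundary: the target tissue must be at least `fold` (default 2) times the
maximum of every other tissue.

## Promoter extraction

The proximal promoter is \[−1000, +100\] around the TSS with no position 0,
hence 1100 nt. On the plus strand this is genomic \[TSS−1000, TSS+99\]
(1-based); minus-strand windows are reverse-complemented so promoters are
always TSS-oriented. (A variant form of the window with the signs exchanged
appears in some descriptions of this design; the window is a configuration
value here.) Soft-masked (lowercase) genome bases travel with the sequence;
hard-masking to N happens only in `masked_view()`, so one genome file
serves both the masked scanning analysis and the unmasked consistency
check. Windows that run past a contig end are clipped and flagged, never
padded. The background set keeps cluster genes by default — they are
subtracted only for de novo discovery, where the contrast between cluster
and non-cluster promoters is the signal.

## PWM scanning

TRANSFAC flat files supply per-position counts; frequencies are counts over
the per-position sum, and the information vector is
I(i) = Σ_b f(i,b)·ln(4·f(i,b)) with 0·ln0 = 0. The matrix similarity of a
word is (Current − Min)/(Max − Min), where Current sums I(i)·f(i, word_i)
and Min/Max substitute the per-position minimum/maximum frequency; the core
similarity applies the same formula to the 5 consecutive positions with
maximal summed information (leftmost on ties). The log base cancels in the
ratio. Hits require core similarity ≥ 0.9 and matrix similarity ≥ 0.85 on
either strand, reported in forward promoter coordinates; windows touching
an N are skipped entirely rather than partially scored, and no pseudocounts
are used here (zeros are handled by the 0·ln0 convention). Presence is
binary per promoter — a single occurrence counts, regardless of strand or
multiplicity.

## Composite over-representation

Composites are pairs or triplets of hits with pairwise-distinct matrices,
non-overlapping intervals, and each consecutive nearest-edge gap
(start_next − end_prev − 1) within \[d_min, 250\]; d_min runs at 20, 50 and
100 bp as three separate analyses. The nearest-edge definition was chosen
over start-to-start distance (configurable) because it makes
"non-overlapping" and the gap bounds a single coherent constraint. Ordered
keys (A\*B) follow positional order relative to the TSS; unordered keys
(A,B) are canonicalized by sorting. Each key counts once per promoter.
Enrichment versus the background promoter set uses the one-sided
hypergeometric tail (over-representation is the only direction of
interest; two-sided is available), BH-corrected within each
(arity, order-mode, distance-class) family, significant at adjusted
p ≤ 0.1. The minimum cell count of five is applied to the total count
k + K: composites can legitimately occur in fewer than five cluster
promoters, so the rule is read as "observed at least five times overall"
(placement configurable). A significant key found in repeat-masked
promoters must also occur in the unmasked cluster promoters, so no accepted
composite lies inside a repeat.

## De novo discovery

Discovery is a discriminative Gibbs sampler written for this package: one
site or none per foreground sequence (ZOOPS via an explicit no-site option
with prior site probability γ, default 0.99 — a high prior is needed for
motifs to nucleate in kilobase-scale promoters, and sequences can still
shed unsupported sites), the PWM re-estimated from the held-out sites with
pseudocount 0.5, and windows scored by log-odds against a 0-order
background model estimated from the background promoters. The reported motif maximizes, across
restarts, the mean foreground best-site log-odds minus the mean background
best-site log-odds (nats). Because that objective is a maximum over
restarts of a quantity optimized on the foreground, it carries a small
optimism bias on signal-free data — a fraction of a nat at typical problem
sizes — while planted or real motifs score an order of magnitude higher;
the objective is a ranking device, not a calibrated test statistic (the
PWM-match empirical p fills that role). The original study ran a perceptron-weighted
sampler as a black box with widths 6–16 and run-cycle parameter m = 100;
m is treated as the number of independent restarts (the more conservative
reading), and the neural weighting is deliberately not reproduced — planted
-motif recovery and null calibration are the testable contracts, and both
hold for the plain sampler. Discovery is deterministic given the seed.

Discovered matrices are matched to the known library by the best
aligned-column Pearson correlation over all offsets and both orientations
(minimum overlap 4 columns), with the aligned-column correlations summed
and normalized by the query width so that unaligned columns contribute
zero. Without that normalization, a 4-column overlap between two sharp
motifs can reach a perfect mean correlation, and the column-shuffle null
(empirical p = (1 + #better)/(n+1), 1000 shuffles) becomes so permissive
that even a self-match is not significant for motifs with repeated columns.
Matches are significant at p < 0.01.

## Weighted co-expression network

Unsigned power adjacency a_ij = |cor(x_i, x_j)|^β with β = 8 by default;
`pick_beta()` selects the smallest power on a 1–20 grid whose connectivity
distribution reaches a scale-free regression fit of R² ≥ 0.8 over 10
equal-occupancy bins. Topological overlap is
TOM_ij = (Σ_u a_iu·a_uj + a_ij)/(min(k_i, k_j) + 1 − a_ij), modules come
from average-linkage clustering of 1 − TOM with a static cut at height 0.95
(minimum size 30); a static cut replaces the reference implementation's
dynamic cut because "default parameters" is not a reproducible
specification and the study's outcome — a single module containing all 212
cluster genes — is a direct property of the static cut on coherent input.
Gene significance is the maximum over time points of −log10(raw p) from the
diet contrasts (so the 1.2 cutoff corresponds to p ≤ 0.063); max rather
than mean because a gene regulated at any time point is significant for
hub purposes (mean is available). Hubs are the top five genes by
connectivity among those with GS ≥ 1.2 and intramodular k/k_max ≥ 0.95.

## The synthetic-data generator

Co-expression is a single-factor model on the log2 scale:
x_g = √ρ·z + √(1−ρ)·ε_g with a cluster-shared z per sample, so the expected
pairwise correlation within a planted cluster equals ρ. Tissue preference
is planted exactly: the preferred tissue is set to fold × the maximum of
the other tissues after noise, so the 2-fold call is forced by construction
at any noise level. Diet effects subtract log2(fold) from the restricted
diet at the chosen time points. Panel intensities are log-normal
(log2 mean 9, sd 1.5) with a configurable floor (default 20 units) so the
250/150-unit filters bite realistically; time-series replicates default to
5 animals per diet-time cell with residual sd 0.3 log2 units — values a
two-color array study of this design would plausibly produce. Promoters
are i.i.d. sequence at a configurable GC fraction with planted instances
inserted as exact consensus words on the forward strand (orientation is
ignored downstream anyway) and soft-masking as a contiguous lowercase
block.

What the generator does not emulate: hybridization physics, dye and spot
artifacts, correlated (autocorrelated or repeat-derived) promoter
sequence, non-stationary base composition, and motif instances that
deviate from the consensus. Passing tests therefore demonstrate
correctness of the algorithms under the declared generative model, not
robustness to every artifact of real arrays or real genomes.

## Numerical choices and degenerate inputs

* Correlations with zero variance or fewer than 3 complete pairs are NA and
  excluded rather than propagated.
* A PWM whose maximum and minimum achievable scores coincide (no
  informative column) is rejected as degenerate.
* Greedy cluster adjustment breaks mean-correlation ties by removing the
  lexicographically last id; membership is invariant to gene input order.
* The hypergeometric tail is computed by `phyper`; BH by `p.adjust`. Both
  are cross-checked in the test suite against independent choose-sum and
  step-up implementations.
* Empirical p-values are (1 + #{null ≥ observed})/(n + 1), never 0.
* Planting collisions (overlapping planted instances after bounded
  retries) abort with the promoter named, rather than silently nesting
  motifs.

## Problem sizes used in the checks

The bundled checks run at the scale the design describes where that scale
is feasible at a desk: planted clusters of 50 genes among 1,000 noise genes
over 18 samples (20 seeds); 100 cluster vs 1,000 background promoters of
1,100 nt for composite enrichment (20 seeds, width-10 scanning matrices —
the sharp regime a curated vertebrate profile occupies; see the ordering
caveat below) and null calibration (50 splits); a 212-gene network module;
200 diet-affected genes at 5 replicates per cell.

A caveat the composite checks exposed: with matrices of width 8 or less,
the Match thresholds tolerate one mismatch outside the core, so each
matrix also fires on random kilobase sequence at an appreciable rate; in
promoters that carry a planted ordered pair, those chance hits sit next to
planted ones and the reversed ordering becomes genuinely (not spuriously)
enriched too. Distinguishing an ordered composite from its reversal
therefore requires scanning matrices sharp and wide enough that chance
hits are rare — which is precisely the design goal of
false-positive-minimized profile libraries. Motif discovery checks use 50 foreground promoters
with a width-8 plant and 25 sampler restarts, a restart budget at which
recovery is already stable; the m = 100 default remains for analyses.
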