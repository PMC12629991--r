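---
title: "Quantifying RNA multivalency with germkit: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying RNA multivalency with germkit: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germkit)
```

## The problem

Low-complexity protein domains — arginine-rich mixed-charge domains
(R-MCDs), glutamine repeats, proline/serine stretches — are encoded by mRNA
regions in which similar codons recur at high density. Such regions are
*multivalent* at the RNA level: they present many near-identical short
motifs in close proximity and can scaffold repeated protein binding, with
consequences for nuclear retention and condensate partitioning of the
transcript. germkit quantifies this property and the statistics built on
it: where the multivalent regions are, which k-mer classes they fall into,
whether the *synonymous codon choice* (not just the amino-acid content)
creates the multivalency, whether that choice is under elevated
conservation, and whether CLIP-assayed RNA-binding proteins prefer
crosslinking in multivalent contexts.

## The GeRM score

For a k-mer $A_0$ starting at position $p$ of a transcript, the raw
Generalized RNA Multivalency (GeRM) score is

$$ g(p) \;=\; \sum_{k \le |i| \le w} e^{-\lambda\, d(A_0,\, A_{p+i})}\;
   \mathrm{weight}(i), $$

where $d$ is the Hamming distance between k-mers, $w = (n+1)/2$ is the
half-window, neighbours overlapping the central k-mer ($|i| < k$) are
ignored, and positions outside the transcript contribute 0. The defaults —
`k = 5`, window `n = 123` nt, `lambda = 1`, smoothing width 123 nt — are
the published operating point of the score and give neighbour offsets
$\pm 5 \ldots \pm 62$.

**Weight term.** The displayed form of the distance weight, $|w - i|/w$,
exceeds 1 for upstream neighbours ($i < 0$), while its verbal description
is a decay from 1 at the centre to 0 at the window edge. We default to the
symmetric form $\mathrm{weight}(i) = (w - |i|)/w$, which matches the
description and treats both directions alike; the literal asymmetric form
is available via `weightScheme = "literal"` for comparison. A consequence
of the symmetric choice worth knowing: complementation preserves Hamming
distances, so the raw track of a reverse-complemented sequence is exactly
the mirrored track (`tests` assert this). Per-position scores on the two
strands of an asymmetric sequence still differ, which is what strand
specificity means in practice.

**Normalization and smoothing.** Raw scores are affinely rescaled so the
pooled minimum over the supplied transcript set is 0 and the pooled median
is 1 (`fitNormalization()` / `applyNormalization()`); the statistics are
stored with a provenance string because "the transcriptome" is whatever set
they were fitted on. Values from other transcripts may fall below 0 or far
above 1 and are never clipped. Smoothing is a centred moving mean of width
123; at transcript edges the window is truncated to in-bounds values rather
than zero-padded, so a constant track stays constant and edge scores are
not artificially suppressed beyond the score's own edge rule. Scores are
anchored at k-mer start positions; `perNucleotide()` carries the last
defined value across the trailing $k-1$ positions when a per-base view is
needed.

## Region calling

`callGermRegions()` pools smoothed scores over all CDS k-mer positions of
the set and thresholds at the 98th percentile (linear interpolation,
pooled — a per-transcript percentile would force calls on every transcript
and is available only as an option). Contiguous super-threshold runs are
extended by half the smoothing window on each side, so a region contains
every k-mer that contributed to its smoothed values; regions overlapping by
at least 41 nt are merged (iterated to a fixpoint, hence idempotent and
order-independent); regions with at least one third of their post-extension
length inside a UTR are discarded. Each region carries the fraction of its
total raw score contributed by each distinct k-mer — the feature vector
used for classification. Note that the percentile rule has a built-in
chance floor: on a null transcriptome ~2% of CDS positions exceed the
threshold by construction, so a handful of short chance regions is
expected; planted signal concentrates the calls instead.

## Codon-shuffle null models

`shuffleCodons()` permutes codons among the positions of the same amino
acid, within each transcript or across the pooled set, so the protein is
untouched while the codon *order* (and, transcriptome-wide, the
per-transcript codon usage) is randomized. `meanShuffledGerm()` averages
raw tracks over 10 shuffles by default (5 is the convention for
region-level summaries); both counts are exposed. The comparison of native
versus shuffled multivalency inside LCD-coding regions is the package's
central null: if multivalency survived shuffling it would be an amino-acid
composition effect, not a codon-choice effect.

## Codon-support ratios

A *mutable position* is any CDS nucleotide admitting a synonymous
single-nucleotide substitution — third positions of degenerate codons plus
first positions of the CTA/CTG↔TTA/TTG leucine and CGA/CGG↔AGA/AGG arginine
pairs; `mutablePositions()` derives them from the genetic code rather than
a hand-kept list. For each such position, `germCodonRatios()` takes the
maximum raw score over the ≤ k k-mers covering it, recomputes the same
maximum for every synonymous variant, and reports native / mean(variant).
Ratios above 1 mean the native codon choice supports the local
multivalency. Raw (unsmoothed, unnormalized) scores are used — the ratio
compares local maxima, so the affine normalization would cancel anyway.
Variant scoring is local: a substitution at position $q$ can only affect
k-mers whose window reaches $q$, so scoring the
$[q - w - k + 1,\, q + w + k)$ context reproduces full-transcript rescoring
*exactly* (the test suite and acceptance script verify bitwise equality
against a rebuild-and-rescore brute force). The score's own edge rule
applies near transcript ends, so no positions are excluded.

## Conservation at mutable positions

Per-base conservation (PhyloP-like, logarithmic scale, missing values kept
as NA and never treated as 0) is normalized in two subtractions: the
conservation of the codon's middle base — a per-instance internal control
that can never be synonymously mutated — is subtracted first, and the
differences are then centred by their median within each (codon, offset)
type. The published description applies the type-median centering first and
the middle-base subtraction second; the two orderings differ only by a
per-type constant, which the per-codon binning absorbs, and ours maps a
constant track to exactly zero, which makes the null case transparent.
Binning by codon-support ratio is equal-count *within each codon identity*
(10 bins by default; the count is not prescribed anywhere, so it is a
package choice) and then pooled, so every bin contains the same proportion
of each codon and composition differences cannot masquerade as a
conservation trend.

One attenuation effect matters when interpreting pooled summaries: for a
codon type whose instances are *mostly* supporting (as happens for AGA in
an arginine-rich simulated set), the type median sits inside the supporting
group and absorbs part of a planted effect. The recovery analyses therefore
estimate the effect as the supporting-minus-nonsupporting difference within
each type (where the medians cancel exactly) and average across types.

## Low-complexity and mixed-charge domains

`windowEntropy()` computes Shannon entropy (base 2) of the amino-acid
composition in a 41-residue sliding window; the base only rescales the
threshold's input monotonically, so domain calls are insensitive to it.
`callLcds()` pools window entropies over the proteome and takes the bottom
2% as low complexity; every sub-threshold window contributes its full span,
overlapping spans merge, and an explicit `threshold` override supports
reusing a threshold fitted on another proteome. Composition flags follow
the stated rules sharply: R-LCD requires arginine fraction ≥ 0.20; R-MCD
additionally requires net charge (K+R−D−E) strictly positive and charged
fraction (D, E, K, R — histidine excluded by the mixed-charge-domain
convention) strictly above 0.40. `arginineCodonUsage()` computes per-domain
proportions of the six arginine codons, their pairwise Spearman
correlations across domains, and a PCA split: the top and bottom thirds of
PC1 are the GA-rich and CG-rich classes, with the PC1 sign fixed so AGA
loads positively (PCA signs are otherwise arbitrary).

## Multivalency classes

Region k-mer profiles are embedded to 4 dimensions with the package's own
UMAP implementation (exact kNN with 50 neighbours, smooth-kNN membership
calibration, fuzzy-union symmetrization, spectral initialization, SGD with
negative sampling in compiled code; `minDist = 0.001`), ordered by density
with OPTICS at `minPts` equal to 1% of the region count, and cut at a
threshold derived from the reachability profile: scanning thresholds from
the 99th percentile of reachability down to 0, the knee is the first point
at which the derivative of the proportion-below-threshold curve reaches 40%
of its maximum (the derivative is smoothed before the rule is applied — it
is a histogram estimate, and single-bin spikes from near-coincident
embedded points would otherwise dominate the maximum).

**The flat-cut handoff at modest region counts.** With a few hundred to a
few thousand regions, `minPts` at the 1% rule is small (~10), core
distances are noisy, and the within-cluster reachability tail overlaps any
bulk-derived threshold; a strict DBSCAN extraction then shatters coherent
classes (we confirmed the same behaviour with an independent
implementation of the identical pipeline). At the original scale of the
analysis (~10^5 regions, `minPts` ~10^3) core distances are smooth and
this does not arise. The package therefore keeps every stated parameter
but makes the extraction robust to the scale: a *boundary* between
clusters requires a reachability spike above `sepFactor` (default 3) times
the knee threshold — between genuinely distinct k-mer classes the
reachability jumps by an order of magnitude, so the rule is insensitive to
the exact multiple — and sub-separation points are absorbed into the
nearest core's cluster (the DBSCAN border rule, widened to the same
separation scale). Cluster count remains an outcome, never a parameter;
noise points are labelled −1 and excluded downstream.

Representative k-mers per class are the minimal descending-sorted prefix
covering 50% of the class's pooled multivalency mass (ties broken
lexicographically for determinism); `dedupe = TRUE` keeps a k-mer only in
the class where its contribution proportion is highest, so feature tables
have disjoint k-mer sets. `transcriptClassScores()` z-scales every CDS
k-mer instance against all other instances of the same k-mer (so a
transcript is rewarded for carrying class k-mers *in multivalent
contexts*, not merely for carrying them) and sums over the class's
representative k-mers. `retentionFeatures()` adds CDS length and mean exon
length (an exon-junction-density proxy) and length-normalized,
standard-scaled per-class multivalency sums, with an option to merge
correlated classes into a single GC-rich feature; the table is meant to
feed any external classifier, which is out of scope here.

## RBP binding potential and CLIP statistics

`motifZscores()` standardizes RBNS-style per-5-mer enrichment (R) scores by
their own mean and standard deviation, assigns one-sided upper-tail normal
p-values, and selects motifs at p < 0.05 (boundary excluded).
`bindingPotential()` multiplies rolling-window counts of each significant
motif by its z-score and sums — exact integer arithmetic times fixed
weights, hence exactly reproducible.

For CLIP, every CDS k-mer instance receives the percentile of its raw score
*within the distribution of the same k-mer* across the set
(`100 (rank − ½)/n`; a single-instance k-mer sits at 50 by construction, an
uninformative prior). Each crosslinked nucleotide maps to the ≤ 5 covering
k-mers by default (`mapping = "start"` is available). Per k-mer, the
crosslink-weighted mean percentile summarizes the multivalency of its
crosslinked contexts; the preference ratio compares the 50 most crosslinked
k-mers (ties lexicographic) with all others, and a sample passes at ratio
≥ 1.1. Sample QC (`filterClipSamples()`) drops the bottom third by
CDS-crosslink proportion and then the bottom third of the remainder by raw
CDS counts. `regionCrosslinkEnrichment()` divides in-region crosslink
density by rest-of-CDS density per region (transcripts in the bottom half
of CDS crosslink density are excluded first; an empty denominator uses a
0.5-count pseudocount or skips the region), and `regionMetaprofile()` sums
counts around region midpoints, normalized by region count and per million
sample crosslinks so the profile is invariant to sequencing depth.

## Synonymous recoding

`recodeCds()` pushes the count of purine-only (A/G-only) 5-mers down or up
under three hard constraints: the protein never changes, GC content stays
within 0.02 of the input, and protected spans are byte-identical. The
optimizer is greedy coordinate descent over codons in seeded random order
(objective first, total A+G content as tiebreak — the lexicographic
objective is monotone, so sweeps terminate), with random-order restarts.
For short sequences the GC tolerance can forbid every single-codon step:
one substitution already shifts GC by more than 2% of a toy CDS, making
compensated multi-codon optima unreachable by single moves. Search spaces
up to 2 × 10^5 synonymous combinations are therefore enumerated exactly;
the greedy path serves full-length CDSs. The acceptance checks compare the
enumerable regime against an independent exhaustive search.

## The synthetic transcriptome

`simulateTranscriptome()` generates what the statistics need and nothing
more: multi-exon spliced transcripts (3–12 exons, log-normal lengths with
median ~150 nt; half on the minus strand so the coordinate plumbing is
exercised), UTRs of 100–300 nt, codon-frequency-matched random CDSs drawn
from a bundled human-like codon usage table, and — in a configurable
fraction of genes (default 10%) — a planted 252–399 nt stretch of one of
four multivalency classes. Low-complexity domains are repetitive, so each
planted stretch tiles a class repeat unit (GA: R-E-R-K encoding a
mixed-charge domain with AGA/AGG/CGA arginine bias; CAG: glutamine; GC:
G-A-R-P with CGG/CGC bias; C: P-S-P-T) with a 10% substitution rate, and
each degenerate codon follows the class-consistent choice with probability
`codonBias` (default 0.9) — consistent codon choice is precisely what makes
a repeat multivalent at the RNA level, and is what the shuffle null
destroys. `simulateConservation()` adds a configurable constraint signal
δ at mutable positions whose native codon follows the class bias;
`simulateCrosslinks()` places a multinomial crosslink budget uniformly over
the CDS or enriched by a factor inside planted regions.
`simulateRegionProfiles()` draws per-region k-mer fraction vectors directly
(Dirichlet around class-prototype profiles, concentration 50; sparse
random-support noise regions) to exercise the clustering stage at scale
without simulating thousands of transcripts.

What the simulator does *not* emulate: real codon usage covariation across
genes, isoform structure (one transcript per gene), sequencing noise in
crosslink counts beyond multinomial sampling, phylogenetic structure in
conservation (i.i.d. Gaussian noise around a baseline), and the
co-occurrence of several multivalency classes on one transcript. Passing
tests therefore demonstrate the correctness and calibration of the
implementation under controlled conditions — recall of planted regions,
exactness of the ratio decomposition, null calibration of the CLIP
statistic — not performance on annotated genomes.

## Problem sizes and numerics

The bundled checks run at desk scale, chosen so the full suite completes in
minutes: 200-transcript simulations for region recovery; 100 planted
fixtures over a 300-transcript pool for the shuffle null; ~7,000 mutable
positions for conservation recovery; 900 regime regions plus 10% noise for
clustering; 200 null samples of 10^4 crosslinks for CLIP calibration (10^5
for enrichment recovery). Scorer-versus-oracle agreement is required to
10^-9 (observed: ~10^-15, i.e. float accumulation order only);
codon-ratio locality is required to be exact. Percentiles use type-7
(linear interpolation) quantiles; medians are the standard mean-of-central
pair; ties in all sorted k-mer lists break lexicographically; seeds are
mandatory wherever stochasticity exists (UMAP layout, shuffles,
simulation), and all randomness flows through R's RNG so a single
`set.seed` reproduces a run bitwise.

## Known limitations

- Scoring is transcript-space only; genome-wide scoring of unspliced DNA
  is out of scope.
- The OPTICS/extraction adaptations documented above are designed for
  10^2–10^4 regions; at 10^5+ regions the O(n²) exact kNN and eigendecomposition
  in the embedding would need approximate replacements.
- The retention feature table stops at the feature matrix; training and
  evaluating a classifier on it is the user's concern.
- Cross-species LCD analyses are supported only through the explicit
  entropy-threshold override; fetching annotations is not the package's
  job.
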