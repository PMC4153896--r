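---
title: "Motif-breakpoint association on circular genomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif-breakpoint association on circular genomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoqfp)
```

# The scientific question

Mitochondrial DNA deletions rejoin two distant genomic coordinates — a 5′
and a 3′ breakpoint. If non-B DNA structures such as G-quadruplexes (GQ)
or short perfect repeats contribute mechanistically to deletion formation,
breakpoints should sit closer to such motifs than chance placement on the
circular genome would predict. `mitoqfp` implements both halves of that
question: bespoke scanners that turn a circular genome into motif midpoint
sets, and rotation-based statistics that compare breakpoint-motif
proximity against an exhaustive, distribution-matched null.

Everything operates on a circular coordinate system: positions are 1-based,
position arithmetic is modular, and the distance between two positions is
the length of the shorter arc, so distances lie in `[0, L/2]` for a genome
of length `L`. Midpoints of even-length elements are kept as exact
half-integers internally; they are only rounded in human-readable report
tables, which avoids a systematic ±0.5 bias in distance statistics.

# Motif scanners

## Quadruplex-forming potential (QFP)

A QFP element is a window of at most 33 nt containing four disjoint runs of
guanine, each at least 2 nt ("2G") or 3 nt ("3G") long, with at least one
nucleotide between consecutive runs. The scanner's structural parameters
are exposed (`max_span`, `min_loop`, `min_run`) with those defaults; 33 nt
maximises the number of non-overlapping clusters recoverable from a
16.6-kb genome, and the 2-nt run minimum admits the two-tetrad structures
that have been validated spectroscopically.

Two deliberate choices govern enumeration:

* **Loops may contain guanine.** A 5-G run can donate two 2-G tracts
  separated by a 1-nt G "loop"; without this, the biophysically confirmed
  element `GGGGGATGCGGGGG` would be missed. This matches the behaviour of
  the widely used QGRS-style predictors.
* **Candidates are collapsed by their sequence region.** Many distinct
  4-tract selections can share a first-tract start and last-tract end; the
  scanner keys candidates on that `(start, end)` interval, and the
  element's tetrad count is the best (max over selections of the minimum
  tract length) the region supports. Elements are regions of sequence, not
  tuples of tracts.

Overlapping candidates are resolved per strand by iterative greedy
selection: shorter span first, then more tetrads, then start position as a
deterministic tie-break. When the top rank is shared by mutually
overlapping candidates of equal span and tetrads, one synthetic element is
emitted at the *median* of their midpoints. The result is a maximal
pairwise non-overlapping set.

The intrastrand scan runs on the deposited strand and its reverse
complement (windows may wrap the origin), maps complement hits back to
reference coordinates, and resolves overlaps per strand; per-genome motif
counts are the union over both strands. Because a FASTA deposit does not
announce which mitochondrial strand it carries, "heavy" is defined
operationally as the G-richer strand.

Duplex-derived interstrand (ddi) elements allow each of the four runs to
sit on either strand of the duplex — in reference coordinates, a
complementary-strand G-run is a C-run — with at least one run from each
strand; no further constraint is placed on run arrangement, since the
motif definition only requires four runs within one window. Candidates
overlapping any resolved intrastrand element are removed first, so the
intrastrand and interstrand sets never overlap.

## Fixed-length repeats

For word size `k` (default 11 nt — long enough to exclude most triplet
repeats, short enough to capture the perfect repeats associated with
disease), a window start qualifies when the class transform of its k-mer
(identity, reversal, complementation, or reverse complementation) occurs
exactly at another start on the reference strand. `N` never matches.
Maximal runs of consecutive qualifying starts collapse into one repeat
unit, mirroring the QFP non-overlap handling; this prevents a single
12-bp repeat from being counted as two 11-mer motifs. The published
genome-wide unit counts do not state their collapsing convention; maximal
blocks are this package's reconstruction, and they reproduce the same
order of magnitude on composition-matched synthetic genomes. Palindromic
self-matches qualify provided the partner start differs from the window's
own start. Pairs of units sharing a transformed word (`enumerate_repeat_pairs()`)
are oriented so the 5′ unit precedes the 3′ unit in the linearisation from
position 1.

# Statistics

## Minimal Distance Analysis

For a "from" set `B` and "to" set `M`, the statistic is the mean
nearest-neighbour circular distance from members of `B` to `M`. Controls
rotate `M` rigidly by every nonzero offset `r = 1 … L-1`; the identity is
excluded, so a 16,569-nt genome yields 16,568 control sets and the
smallest attainable p-value is `1/(L-1)` (a computed p of 0 is printed as
"< 1/(L-1)"). The p-value counts controls with mean distance *smaller
than or equal to* the actual value: ties count against the alternative,
making the test conservative. Whether a motif lies inside or outside the
deleted interval is deliberately ignored — distance is measured in either
direction around the circle.

The analysis is asymmetric and is always offered reciprocally. With few
motifs and many breakpoints, breakpoint-to-motif means are dominated by
breakpoints that cannot all be near a motif; motif-to-breakpoint analysis
can still detect that the rare motifs sit near *some* breakpoints.

Implementation: distances from a point `p` to `M` rotated by `r` equal a
circular shift of the minimal-distance profile of `M`, so all `L` control
sums are accumulated in `O(|B| · L)` after an `O(L log |M|)` profile
computation. Sums (not means) are compared: every distance is a multiple
of 0.5, so sums are exact in double precision and tie comparisons are
never corrupted by rounding.

## Individual enrichment

For each threshold `D`, the observed count `K` of from-points within `D`
is tested against Binomial(N, P), where `P` is the fraction of integer
genome positions whose minimal distance to the motif set is ≤ `D` — the
chance a single rotated breakpoint lands within `D`, an identity the test
suite checks explicitly. `P` is computed over integer positions only:
breakpoints are integers, while motif midpoints may be half-integers.

Two binomial conventions are reported side by side. The literal form
`1 − F(K; N, P)` equals `P(X > K)` and returns 0 whenever `K = N`, even
under the null; the default `P(X ≥ K)` does not have that defect. Both are
emitted in every curve and both-ends result so either published table can
be compared. Distances below ~16 nt for QFP (and ~6 nt for direct
repeats) can reflect literal overlap of motif and breakpoint rather than
action at a distance; interpretation of very small `D` should bear this in
mind. No multiple-testing correction is applied across motif sets, ends,
directions or thresholds: raw p-values are reported, as is conventional
for this analysis.

## Both-ends tests

A deletion is motif-associated when both of its breakpoints are within `D`
(default 10 nt) of a motif midpoint. The chance probability is exhaustive,
not analytic: the motif set is rotated through every nonzero offset and
`P = Σ_r c_r / ((L-1) N)`, where `c_r` is the qualifying count under
rotation `r`. (Rotating the motif set or the deletion set is equivalent on
the circle; the motif set is rotated.) The paired-repeat variant requires
one and the same repeat pair to match both ends in order — 5′ breakpoint
to 5′ unit, 3′ breakpoint to 3′ unit — which is strictly harder than the
pooled-midpoint test, and the suite contains a fixture separating the two.

# Synthetic data: what it emulates, and what it does not

The generators produce: i.i.d. random circular genomes under a named base
composition (the `mtdna_composition()` preset, A 0.309 / C 0.313 / G 0.131
/ T 0.247, approximates the G-poor deposited strand of human mtDNA and is
configurable, not a hard-coded fact); exact composition-preserving
shuffles; planted motifs at known positions; and deletion sets that are
uniform, anchored on motif midpoints with a signed displacement (uniform
or geometric magnitude, sign uniform, rounded half away from zero), or
mediated by repeat pairs. All generators are bit-reproducible from their
seed.

These emulate the *statistical geometry* of the real analysis — set sizes,
strand-asymmetric composition, circular coordinates, displacement of
breakpoints from motifs — but not mutational mechanism, selection,
replication-origin structure, or the strong regional clustering of real
mtDNA breakpoints. Passing calibration and power tests therefore shows
that the statistics are correct and usefully powered under their stated
models, not that any particular real genome will show association.

# Validation strategy and problem sizes

The test suite validates every statistic against brute-force oracles
(explicit rotation loops, exhaustive 4-tract tuple enumeration, all-pairs
repeat search) on 100 random instances with `L ≤ 300`, plus full-scale
checks at `L = 16,569`: 500 uniform-null MDA runs with 50 breakpoints
(the empirical fraction of `p ≤ 0.05` must lie in `[0.03, 0.07]`) and 200
planted-association runs with ≤ 5 nt displacement (`p ≤ 0.001` in ≥ 95%).
The motif-count-excess check plants 20 QFP oligos on a 3-kb background and
compares against 99 composition-matched shuffles; at that density the
planted arrangement exceeds every shuffle by several null standard
deviations. Genome-wide published counts (9 intrastrand 3G QFP, 178
intrastrand 2G QFP, 137 direct-repeat units on the reference human mtDNA;
620 unique 5′ breakpoints among 730 published deletions) are asserted in
tests that run whenever the corresponding reference files are supplied
under `inst/extdata/`; those inputs are not redistributed with the
package. The published 2G count is treated as the union over both strands,
since the reference analysis reports light-strand 2G elements alongside
heavy-strand ones.

# Degenerate inputs and edge behaviour

* Empty point sets are rejected; statistics on them are undefined.
* A genome in which every window qualifies as a repeat (e.g. a homopolymer)
  collapses to a single warned unit covering the genome.
* `N` bases are legal input; they terminate G-runs and never match in
  repeat comparison.
* Deletions with `bp5 > bp3` are accepted with a warning — published mtDNA
  deletions all satisfy `bp5 < bp3` in reference linearisation, so
  violations usually indicate a coordinate problem; no re-orientation
  across the origin is attempted.
* Subgroup analyses deduplicate breakpoints per end *after* filtering, so
  a subgroup's unique-breakpoint counts are internally consistent.

# Known limitations

* Motifs are reduced to midpoints; interval-aware distances are not
  offered, consistent with the method being validated here.
* QFP scanning does not score thermodynamic stability (no G-score); repeat
  scanning is exact-match only, one word length per run.
* The rotational null preserves each set's internal geometry but assumes
  rotational exchangeability of the circle; genomic features that break
  that symmetry (e.g. the control region) are part of the signal, not the
  null.
* Stem-loop/cruciform prediction is out of scope; externally computed
  midpoint lists can be supplied via `midpoint_spec()` and enter every
  analysis on equal footing.
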