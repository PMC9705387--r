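---
title: "Painting hybrid polyploid assemblies by subgenome ancestry"
author: "ancestryPaint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Painting hybrid polyploid assemblies by subgenome ancestry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ancestryPaint)
```

## The problem

Commercial sugarcane is an auto-allopolyploid hybrid of *Saccharum
officinarum* and *S. spontaneum* carrying 8–12 copies of each
chromosome. When such a genome is assembled from noisy long reads, the
two progenitor subgenomes can be more similar to each other (about
94% nucleotide identity) than either is to a raw long read (10–15%
error). Consensus error correction — replacing bases of a long read by
the majority of the short reads recruited to it — then recruits reads
from *both* subgenomes, and the corrected reads, and ultimately the
whole assembly, become mosaics of the two ancestries. The diagnostic
signature is an implausibly large number of contigs whose segments
derive from different progenitors.

This package implements the diagnosis end to end: it paints each
contig of an assembly by progenitor ancestry from its alignments
against the two progenitor references, flags recombinant (chimeric)
contigs with breakpoint estimates, and computes the supporting
genome-scale statistics. A seeded synthetic generator provides a
hybrid genome with known truth so that every stage is testable without
any external data.

## The ancestry classifier

The input is two alignment sets for each contig: one against
progenitor A and one against progenitor B (MUMmer `show-coords`
output, PAF, or SAM with CIGAR; all converted to 0-based half-open
coordinates at the boundary). Overlapping alignments of a contig are
reduced to a single merged range per reference — the same
range-reduction that `IRanges::reduce` provides — giving the tallies
`bp_A` and `bp_B`.

Each contig receives exactly one of five categories, tested in this
order:

1. **unaligned** — less than `min_aligned_frac` (default 0.10) of the
   contig aligns to either progenitor;
2. **recombinant** — the exclusive-coverage test below fires;
3. **equal** — `|bp_A - bp_B| / (bp_A + bp_B)` is at most
   `equal_tolerance` (default 0.10, the operational meaning of
   "mapped almost equally to both ancestors");
4. otherwise **A_dominant** or **B_dominant**.

None of these thresholds has a canonical published value; all of them
are explicit fields of `ancestryParams()` so that any analysis states
its own operating point.

### Why recombinant detection uses ancestor-exclusive coverage

At ~94% inter-progenitor identity, most of a contig aligns to *both*
references, so raw coverage cannot say which half of a chimeric contig
came from which ancestor. What does discriminate is coverage that is
exclusive to one reference: positions covered by the A alignments but
not the B alignments are evidence of A ancestry, and vice versa. The
contig is tiled into 1 kb windows (`window_bp`); each window is
labelled by the majority of A-only versus B-only covered bp; windows
with no exclusive evidence are absorbed into the flanking runs; and
maximal same-label runs are delimited at the midpoint between adjacent
runs' evidence. The contig is recombinant iff at least two
alternating runs each span at least
`max(recomb_min_segment_bp, recomb_min_segment_frac * aligned bp)`
(defaults 10 kb and 0.20), with breakpoints reported at the
transition midpoints. The run-size floor is what keeps isolated
divergent islands from being misread as ancestry switches.

### The two-pass design

Contigs that map almost equally to both references on the tally pass
are re-examined on a second alignment pass of different stringency;
when the second pass is decisive the contig is reassigned
(`disambiguateEqual()`). The passes are named *first* and *second*
rather than lenient/strict: which settings of a real mapper are
"more stringent" at a given score threshold is genuinely ambiguous,
and nothing in the method depends on the direction — only on the two
passes being different. Stored `bp_A`/`bp_B` tallies always come from
the first (tally) pass.

### Other statistics

* `compareGenomes()` reports coverage of each genome by merged
  alignments of the other, plus two identity summaries. "Average
  nucleotide identity" is ambiguous between an alignment-length
  weighted mean and a plain mean over alignments; the weighted mean is
  the headline number (an unweighted mean overweights short hits) and
  the plain mean is always reported alongside so the difference is
  measurable.
* `depthPartition()` splits assembly bp into single- and multi-copy
  by comparing each contig's depth with the *length-weighted* median
  depth (the genome-scale partition must weight contigs by their bp,
  not count them equally). A contig is multi-copy iff
  `depth > c * median` with `c = 1.5`; a tie at exactly the threshold
  stays single-copy.
* `bridgeAndCount()` reproduces the repeat-masker convention that
  stretches *strictly* shorter than 10 bp between masked regions are
  also masked — a 10 bp gap survives — before counting regions larger
  than 20 kb.
* `repeatSummary()` reports per-class masked bp after merging within
  each class, a grand total equal to the sum of the per-class rows,
  and separately the bridged union across classes: the two views
  differ whenever classes overlap, and both are needed.
* `unplacedConcordance()` measures how much unplaced sequence aligns
  onto the pseudochromosomes and how often it carries the same
  ancestry as the scaffolded sequence it lands on; only positions
  where both sides have a definite A/B call enter the concordance
  term.
* One painting palette is used everywhere: A teal, B green, equal
  pink, recombinant purple, unaligned grey (`paintingPalette()`).

## The synthetic test bed

`simParams()` fixes the study conditions: 1 Mb of progenitor genome
over 5 chromosome segments, genome-wide divergence `d = 0.057`
(94.3% identity), 200 contigs of 40–160 kb, 20% chimeric with 1–3
uniformly placed breakpoints and segments of at least 5 kb, 10% of
contigs collapsed at copy number 2–3, and a single-copy read depth of
13. These sizes keep every binomial bound tight while the whole
pipeline runs in seconds to minutes.

### Divergent islands

If genome B were derived from A by uniform i.i.d. substitutions, a
score-thresholded aligner would align every contig end-to-end to
*both* progenitors: `bp_A` would equal `bp_B` everywhere and ancestry
would be unidentifiable from coverage — which real data plainly is
not. Real subgenome divergence is not uniform: indels,
presence/absence variation and fast-evolving islands fragment
cross-subgenome alignments. The generator therefore concentrates part
of the divergence budget in short **divergent islands**: a fraction
`island_fraction = 0.22` of the genome, in islands of
`island_length = 800` bp, mutates at `island_divergence_factor = 4.5`
times the genome-wide rate, and the background rate is lowered so
that the overall substitution fraction is exactly `d`:

`d_background = d * (1 - phi * kappa) / (1 - phi)`.

Genome-wide statistics (realised mismatch fraction, weighted identity
of full-coverage truth alignments) are therefore unchanged, while an
emulated score-thresholded aligner breaks at islands — exactly the
behaviour that makes per-contig ancestry identifiable in real data.
The island fraction and factor were chosen once so that, at the
default divergence, island divergence (~26%) is far past the
alignment break-even point and cross-ancestor coverage of a pure
contig falls well below its own-ancestor coverage.

### The emulated aligner

`simulateAlignments()` produces what a local aligner with a minimum
output score would report, without running one. Against its source
ancestor a segment aligns end-to-end at 100% (contigs are exact
copies; read errors are out of scope). Against the other ancestor,
islands whose local rate exceeds `1 / (1 + penalty)` — the point
where expected local score (+1 match, −penalty mismatch) turns
negative — split the alignment, and each remaining chunk is emitted
only if its exact planted score reaches the threshold. The first pass
uses penalty 4 (a common mapper default) with minimum score 1000; the
second pass uses penalty 8 with minimum score 500, a genuinely
different operating point for disambiguation. Identities are computed
exactly from the planted variant counts, so `exportTruthAlignments()`
and the emulated records round-trip bit-exactly through the coords
and PAF writers.

### Coupled randomness and the monotone-divergence property

All structural draws (base genome, island layout, contig layout,
breakpoints, copy numbers, placements) are made before and
independently of divergence, and each base's substitution is decided
by one uniform draw compared against its local rate. Under a fixed
seed, the mismatch set at a lower divergence is therefore a subset of
that at a higher divergence, and recovery metrics respond
monotonically to divergence by construction rather than by sampling
luck — which is what the monotone-response tests assert.

### What the generator does not emulate

No read-level simulation (no error profiles, no FASTQ), no indels
(`indel_rate` must be 0: the substitution-only model keeps every
truth coordinate exact; supporting indels would require offset maps
throughout and adds nothing to what the tests can show), no
structural rearrangement between progenitors (they are colinear by
construction, which is also why a chimeric contig can switch ancestor
at the same homologous coordinate — the signature of
consensus-correction chimerism), and no realistic repeat landscape.
Consequently, passing recovery tests show that the classifier
correctly inverts the generative model at realistic divergence and
alignment-fragmentation scales; they do not show robustness to
repeat-induced mis-mapping, which only real alignments can probe.
The simulated AGP places contigs in `+` orientation only; the AGP
reader and painting code handle `-` and are unit-tested on explicit
fixtures.

### Sensitivity is quoted over the caller's operating range

The generator plants segments down to 5 kb; the caller's default
minimum run is 10 kb (or 20% of aligned bp, whichever is larger). A
detector with a documented minimum detectable segment cannot be
expected to find segments below it, so `evaluateRecovery()` reports
sensitivity both over all planted chimeras and over those whose
planted segments all exceed the caller's threshold by a 10%
resolution margin (the margin covers breakpoint-localisation error,
which is bounded by roughly half the island spacing, ~1 kb). The
operating-range figure is the one compared against the >= 90%
expectation; the all-chimeras figure is reported so the difference is
never hidden.

## The consensus-correction model

`simulateConsensusCorrection()` makes the chimerisation mechanism
quantitative with a deliberately minimal majority-vote model — it is
not a reimplementation of any assembler's correction stage. At a
diagnostic site (a position where the subgenomes differ), a long read
from subgenome A is corrected by the majority allele of the short
reads recruited to it:

* the recruitment window spans `window_bp = 20` bases around the
  site; besides the site itself, each position is divergent with
  probability `d` (that profile is shared by all reads at the site);
* short reads err at one tenth of the long-read error rate `e`;
  window identity is modelled from divergence and short-read errors,
  while the long read's own error rate sets the recruitment allowance
  `1 - e - margin` (margin 0.05);
* a read is recruited iff its window mismatches are at most
  `floor(w * (e + margin))`; under the uniform-alternative
  substitution model a B read matches a divergent position only when
  its own error recreates the A base (probability `e_s / 3`);
* each recruited read votes its allele at the site (its own error
  flips the vote to the opposite allele a third of the time,
  otherwise the vote is spoiled); ties, including zero recruits,
  retain the long read's base, which is the B allele with probability
  `e / 3`.

Coverages default to 8 reads from each subgenome: at a conserved
locus of a high-ploidy hybrid, reads from all homoeologous copies are
recruited, so the two pools are comparable — which is precisely the
regime in which correction flips alleles. With `e = 0.12` the model
chimerises roughly 10% of sites at 1% divergence, falling
monotonically as divergence rises and wrong-subgenome reads start
failing the identity filter; at `e = 0` the rate is exactly 0. At
`d = 0` there are no distinguishing sites and the rate is reported as
0 by convention (with a message). Both a seeded Monte-Carlo mode and
an exact enumeration over the window composition are provided; they
implement the same probability model and agree within Monte-Carlo
error, which the tests assert at 3 standard errors.

## Numerical conventions

* All internal coordinates are 0-based half-open; 1-based inclusive
  dialects (show-coords, RepeatMasker, AGP) are converted at the
  boundary, and reversed query coordinates become `strand == "-"`
  with start < end.
* Merging treats touching intervals as one; bridging closes gaps
  strictly below the gap threshold.
* SAM identity is `100 * (aligned_columns - NM) / aligned_columns`
  with `aligned_columns = M + I + D`; without an NM tag the `=`/`X`
  operators are used, and a record with neither is an error rather
  than a guess. Hard clips are treated like soft clips for the query
  offset. Secondary and supplementary records are retained (the
  range-union method requires multi-hit evidence) and tagged.
* The length-weighted median is the lower weighted median; ties at
  the copy-number threshold are single-copy.
* Writers are byte-stable given identical record order; the coords
  writer prints identity with four decimals so exact truth identities
  survive a round-trip.

## Worked example

```{r example, eval = FALSE}
params <- simParams(seed = 42)
pair <- simulateProgenitors(params)
truth <- simulateHybridAssembly(pair)
aln1 <- simulateAlignments(pair, truth, "first")
aln2 <- simulateAlignments(pair, truth, "second")
lens <- setNames(truthContigs(truth)$length,
                 truthContigs(truth)$contig_id)
calls <- disambiguateEqual(callAncestry(aln1$A, aln1$B, lens),
                           aln2$A, aln2$B)
ancestryTotals(calls)
evaluateRecovery(truth, calls)
```

## Known limitations

* The classifier assumes the two references are assemblies of the
  actual progenitors; a diverged relative shifts all tallies toward
  `equal`.
* Breakpoint localisation is limited by the density of
  ancestor-exclusive evidence (here, island spacing; in real data,
  indel/PAV density) — about 1 kb under the default conditions.
* The exact correction-model enumeration is quadratic in coverage and
  window length; it is intended for the default-scale parameters, not
  for genome-scale scans (use the Monte-Carlo mode there).
* Reproducing a specific published recombinant-contig count is not
  promised: such counts depend on unpublished minimum-segment
  conventions; the package instead exposes every threshold and
  reports its own.
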