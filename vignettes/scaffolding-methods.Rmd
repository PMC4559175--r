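---
title: "Mate-pair scaffolding with scafmate: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mate-pair scaffolding with scafmate: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scafmate)
```

## The scaffolding problem

A de novo assembler turns reads into contigs; what it cannot resolve —
repeats, coverage gaps, low-complexity stretches — fragments the genome.
Scaffolding restores large-scale structure by ordering and orienting the
contigs using mate-pair (MP) libraries: read pairs whose two mates sit a
known, kilobase-scale distance apart on the genome. A pair whose mates map
to two different contigs is a *link*: physical evidence that the two
contigs are neighbours, with the facing ends identified by where on each
contig the mates landed.

scafmate implements a deliberately transparent, semi-automatic version of
this idea. Every intermediate artifact — the chimera verdicts, the copy
numbers, the scaffold map itself — is a small, hand-editable text file
that can be corrected and re-imported, because the hard 1 % of a genome
(collapsed repeats, chimeric joins, rearrangement-dense islands) is
exactly where an automatic decision should be inspectable and reversible.

## The link model

All evidence derives from mate mappings filtered for accuracy: full-length
alignments with at most `max_mismatches` (default 3) mismatches. Insert
sizes are observable only for pairs whose two mates map to one contig;
scafmate measures them as the outermost-coordinate span
(`max(end) − min(start) + 1`) and histograms them. The user reads two
bounds off this histogram and writes them into the configuration:

* `small_insert_upper` (bp) — the upper edge of the short-insert
  contaminant population that most MP protocols carry (0 if absent);
* `main_insert_upper` (bp) — the upper edge of the main MP population.

These bounds are deliberately user-set rather than fitted: a mixture fit
adds fragility for no benefit on a decision a person makes correctly in
seconds from the plot, once per library.

For a pair mapping to two contigs the true insert is unobservable (it
spans the unknown gap), but geometry still constrains it. Each mate is
assigned to its nearer contig end, with `dist` the outer-coordinate span
between mate and end; `dist_a + dist_b` is the insert the pair would have
if the gap were zero, hence a lower bound. A link is *clean* — usable as
adjacency evidence — when

1. the two mates are on different contigs,
2. each mate lies within `main_insert_upper` of its nearer end (a mate
   buried deeper cannot reach another contig), and
3. `dist_a + dist_b ≤ noisy_factor × main_insert_upper`
   (default factor 1.5), the inter-contig form of the noise rule that
   discards implausibly long inserts.

Mate strands are recorded and reported in the neighbourhood map but not
used to accept or reject links: post-trimming MP protocols disagree on
FR/RF conventions, while the insert-size and accuracy filters do the
actual discriminating work.

## Preprocess: what is wrong with the contigs?

Two failure modes of assembly must be caught *before* ordering anything.

**Collapsed repeats.** A repeat present in k copies is assembled once, at
roughly k-fold coverage. Taking the largest contig as the single-copy
reference (the largest contig is overwhelmingly likely to be single-copy),
`estimate_copy_numbers()` reports
`copies(c) = max(1, ⌊coverage(c)/coverage(ref) + 0.5⌋)` — a half-up
rounding, so 2.5× reads as 3 copies. The estimate tolerates a
multiplicative perturbation of the coverage *ratio* strictly below
`1/(2·copies)`: 25 % for 2 copies but only 12.5 % for 4. Per-contig mean
coverage at the several-hundred-fold depths typical of MP projects is
estimated to within a few percent, so the test fixtures use lognormal
noise with sd 3 % truncated at ±6 %, keeping every draw inside the
guarantee; genuinely noisy coverage (heavy contamination, very short
contigs) will produce off-by-one calls at 3–4 copies, which is precisely
why the copy-number file is editable.

**Chimeric contigs.** A single-copy contig longer than the insert size can
be linked to at most two big neighbours — one off each end. A chimera
erroneously fusing two loci inherits both neighbourhoods and shows more.
`detect_chimerae()` counts, for each single-copy big contig and each of
its ends, the distinct big partners supported by at least
`min_link_support` links, and flags the contig when one end has ≥ 2 such
partners or the contig totals ≥ 3. Two points matter:

* Detection runs on the **raw** link set. The extra partners of a chimera
  attach at its internal breakpoint, far from both ends — exactly the
  links rules 2–3 above discard. Restricting detection to clean links
  would blind it to every chimera whose fused halves are longer than the
  insert; the distance rules protect ordering decisions, not diagnosis.
* Both the per-end and the whole-contig count are tested, since a
  breakpoint near the contig midpoint can split its foreign partners
  across the two nearer-end labels.

Flagged contigs are written unsplit to the chimera resolution file. The
split itself is a manual edit, guided by the per-contig linkage-location
histogram (partner profiles of the two halves occupy disjoint position
ranges); components may overlap, and on re-import mappings falling in an
overlap are assigned to the component in which they lie farther from the
shared boundary.

## Scaffold: greedy iterative extension

`run_ise()` (iterative scaffold extender) orders the single-copy contigs.
Multi-copy contigs are excluded outright — they occur at several genomic
locations, so their neighbourhoods are intrinsically ambiguous — and they
are, predictably, what extension eventually runs into.

The largest unplaced big contig seeds a scaffold. At a growing end, the
candidates are unplaced single-copy contigs with at least
`min_link_support` (default 5) clean links to the terminal placement's
outward end. Big contigs take strict priority over small single-copy
ones; within a class the most-linked candidate wins, with ties broken by
length then lexicographic id, making the whole procedure deterministic.
The candidate's orientation follows the majority of its end-to-end link
evidence; a majority margin below `orientation_margin` (default 2 links)
rejects the candidate at that step rather than guessing. One side is
extended to exhaustion, then the other, repeated to a fixpoint; then the
next-largest unplaced big contig seeds the next scaffold, until every big
contig is placed. (If no big single-copy contig exists at all, the run
seeds from the largest single-copy contig and says so.)

The support threshold of 5 is chosen for the 50–800× coverage regime these
libraries are sequenced at, where true junctions carry tens to hundreds of
spanning pairs and stray mismapped pairs appear in ones and twos; it is
configurable for thinner data.

`run_sci()` (small-contig inserter) then places the leftovers — small
single-copy and all multi-copy contigs — *inside* existing scaffolds. For
each such contig every junction between consecutive placements is scored
by the links connecting the contig to the junction's two inward-facing
ends; junctions reaching `min_link_support` are congruent insertion
points, and the contig is inserted at the best-supported ones, at most
once per junction and at most its copy number in total (the copy number
is recorded on each placement). Nothing is ever added before the first or
after the last placement, so scaffold edges remain as the extender left
them and scaffolds are never merged — edge evidence is one-sided and
therefore too weak to commit automatically. Scaffold-end-to-end link
support is instead *reported* (the circularization aid), leaving the join
decision to the user.

A caveat the scaffold map makes explicit through its provenance column:
for a contig much shorter than the insert size, mates can sit anywhere on
it, so the 5'/3' labels carry little signal and SCI orientations of short
repeats are approximate. The placements are sound; the strand of a 700 bp
repeat between two anchored big contigs may not be.

## Buildfasta: emission

Scaffold sequences are the placements in rank order, `-` placements
reverse-complemented, with exactly 50 `N` characters between consecutive
placements. The gap is fixed, not estimated: MP insert variability is on
the order of ±1 kb, so per-junction gap estimates would be noise
presented as precision, while a decent primary assembly makes truly large
gaps rare. A constant small spacer marks the junction honestly. (The
length is overridable via `gap_size` but defaults to 50 everywhere.)
Multi-copy placements emit the same consensus sequence at each insertion
point; unscaffolded contigs go to a companion FASTA unchanged.

## Polish: majority-vote correction

After finishing, remapping the reads onto the assembled genome gives a
weight-position matrix: per-position counts of A/C/G/T seen in the
aligned reads (match/mismatch columns only; indels and clips contribute
nothing, and both mates count independently). A position is corrected to
base b when b differs from the assembly and more than 50 % of covering
reads show b; it is flagged — never corrected — when the top two counts
tie, no base exceeds 50 %, or depth is below `min_depth` (default 5,
below which a majority is too few reads to act on). Positions with zero
coverage are left alone. Corrections are substitutions only, so genome
length is invariant and polishing error-free reads twice changes nothing
the second time. The input is expected linearized; reads spanning a
circular origin should be dealt with upstream.

A companion scan reports sliding-window median depth against the
genome-wide median (windows below 0.5× suggest an undetected intra-contig
chimera, above 1.5× a collapsed repeat); thresholds are advisory and the
output is a report, not an edit.

## The simulator: what it emulates, and what it does not

`simulate_dataset()` exists so that every pipeline behaviour is testable
against known truth in seconds. It builds a circular genome of
unique-sequence segments, optionally inserting repeat-family copies
between them and fusing non-adjacent segments into planted chimerae; the
"assembly" is then read off by construction — one contig per unique
segment, one consensus contig per repeat family at multiplied coverage —
and mate pairs drawn from a two-component insert mixture are mapped
*analytically*: a mate maps iff its interval lies fully inside one
segment instance, which is the full-length criterion an aligner applies
at contig boundaries.

Default conditions mirror a prokaryotic MP project shrunk ~100-fold so a
full run takes seconds: a 24 kb circular genome in 8 contigs, 101 bp
reads, ~800× coverage, 6 000 pairs, main inserts 1 000 ± 100 bp with 10 %
short-insert contamination at 300 ± 30 bp, coverage noise sd 5 %. The
read length is kept at the realistic 101 bp, so the insert mixture cannot
be shrunk by the same factor as the genome; it is scaled to preserve the
ratios that drive the algorithm: insert ≫ two read lengths, contig length
≈ 3× insert, `big_contig_min` = main-insert upper bound = mean + 3 sd.

What the simulator does **not** model: sequencing errors beyond optional
uniform mismatch sprinkling, quality scores, chimeric *pairs* (PCR
artifacts), GC-coverage bias, misassembly other than clean two-locus
fusion, and real aligner behaviour (multi-mapping is produced only by
collapsed repeats, analytically). Tests passing on these fixtures
therefore demonstrate algorithmic correctness — order/orientation
recovery, detector logic, bookkeeping invariants — not robustness to
library pathologies, which is what the editable-intermediate design is
for.

## Validation against exhaustive search

The greedy extender is checked against an independent brute-force
reference (`exhaustive_scaffold_search()`): enumerate every permutation
and orientation of up to ~8 contigs, score each arrangement by the number
of links it satisfies (a link is satisfied when its contigs are adjacent
with the linked ends facing), and find the maximum, counting optima by
dynamic programming over orientations within each permutation. On random
well-linked instances the extender's output is compared with the optimum
whenever it is unique up to global reversal. Reversal symmetry is also
exercised directly: relabelling 5'↔3' on every link is a per-contig
strand flip of the underlying genome, so the recovered order must be
unchanged and every orientation inverted (up to the usual global
reversal).

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere; SAM input is converted
  once on read.
* Copy-number rounding is half-up (`⌊x + 0.5⌋`), floored at 1.
* All greedy ties are broken by (support, length, id) so identical inputs
  give byte-identical scaffold map files.
* A read pair with several retained best hits expands into all mate1 ×
  mate2 combinations up to `multimap_cap` (default 4); beyond that the
  pair is dropped with a warning.
* Empty inputs degrade explicitly: an empty contig table warns and
  returns an empty set; an empty fragment set yields zero statistics with
  a warning; a mapping table with no intra-contig pair stops with advice,
  since no insert model can be built.
* The 7-column mapping dialect accepts coordinate pairs in either order
  (some aligners encode strand by reversed coordinates) and both dialects
  tolerate blank lines and CRLF endings.

## Known limitations

Gap sizes are fixed, not estimated. Scaffolds are never merged or
circularized automatically; the terminal-link report supports doing so by
hand. Chimera breakpoints are not called automatically — the detector
flags, the histogram localizes, the user splits. Orientation of
sub-insert-length repeats is approximate. The polisher ignores indel
evidence by design. Real-data performance depends on the upstream mapper
and its best-hit behaviour, which this package deliberately does not
bundle.
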