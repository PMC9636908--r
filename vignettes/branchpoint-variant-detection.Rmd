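---
title: "Detecting branchpoint-disrupting variants: model, conventions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting branchpoint-disrupting variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpscan)
```

## The biological model

Splicing begins when the spliceosome recognizes the branchpoint (BP), an
intronic nucleotide — an adenosine in the large majority of introns — whose
2'-OH attacks the 5' splice site to form the lariat. The BP motif follows
the loose consensus YTNAY (Y = C/T, N = any base, A = the BP), and
functional BP concentrate in a 3'-proximal band roughly 20–40 nt upstream
of the 3' splice site. Because BP recognition depends on the BP adenosine
itself and on base-pairing of its flanking bases with the U2 (or U12)
snRNA, substitutions at the BP and at BP−2, and deletions removing part or
all of the motif, can abolish splicing of the host intron.

`bpscan` operationalizes this as a detection problem: given a BP database
and a VCF, report every variant whose affected bases intersect the
`[-2, 0]` transcript-sense window of a database BP, with enough context to
triage the hits.

## Coordinate and offset conventions

Everything in memory is 1-based inclusive, matching VCF and genomic
`g.`-notation; BED input is shifted by +1 at the boundary. Two derived
conventions matter:

* **Distance to the 3' splice site.** The last intron base (the G of the
  AG acceptor) is position −1; a BP with distance −20 has 19 intron bases
  between it and the intron end. The mapping window retained is
  `[-100, -3]`: BP closer than −3 would overlap the acceptor itself, and
  distal BP beyond −100 involve splicing mechanisms (recursive splicing,
  long-range structures) outside this model's scope.
* **Hit offsets.** For a genomic site `s` and a BP at `b`, the offset is
  `s − b` on the plus strand and `b − s` on the minus strand, so offsets
  read in transcript orientation: −2 and −1 are the two bases upstream of
  the BP, 0 is the BP. SNVs hit one offset; deletions hit every offset
  whose base they remove; insertions hit the two offsets flanking their
  breakpoint, only when that breakpoint falls strictly inside the window,
  and are flagged low-confidence because the splicing impact of inserted
  sequence is much harder to predict.

Variant normalization splits multi-allelic rows and trims shared
prefix/suffix bases. The prefix is trimmed first: VCF indels carry a left
anchor base, and prefix-first trimming keeps an anchored deletion on
exactly its anchored interval (suffix-first trimming would slide deletions
inside repeat runs). Left-alignment is deliberately not performed — inputs
are expected to be normalized upstream — and a complex substitution (both
alleles multi-base after trimming) is conservatively treated as a deletion
of its REF side and flagged.

## Consensus-guided positional adjustment

Raw experimental BP positions are noisy: reverse transcriptase traversing
the 2'–5' lariat junction misplaces a fraction of read-derived positions by
a nucleotide or two. Each raw record is therefore screened over a
`[-2, +2]` transcript-sense window and moved to the closest candidate whose
centered 5-mer (offsets `[-3, +1]`) matches YTNAY exactly; records with no
matching candidate are left untouched, so datasets without nearby consensus
(for example cytosine-BP sets) pass through unchanged. Two design points:

* **Tie-break.** When YTNAY matches at both −d and +d, the
  transcript-downstream candidate wins, on the rationale that BP closer to
  the 3'ss are the more likely functional ones. The candidate order is
  therefore 0, +1, −1, +2, −2.
* **Orientation.** The window is evaluated in transcript orientation. For
  the symmetric `[-2, +2]` window the choice only matters for ties, but it
  makes the rule identical on both strands.

Adjustment can only merge records (several raw neighbors collapsing onto
one consensus position), never create them, so the per-dataset size delta
is always ≤ 0 — a property the test suite fuzzes. Adjusted datasets merge
into one record per `(contig, pos, strand)`; a position supported by both
an experimental and a computational source is an mBP, otherwise eBP or cBP.

## Intron typing and the snRNA duplex stand-in

Minor (U12-type) introns are typed by the AT-AC terminal-dinucleotide
heuristic, with an override list input for curated catalogs — most real
minor introns are GT-AG and can only be recovered from such a list, so the
heuristic is documented as conservative rather than complete.

The BP–snRNA binding-energy estimate is an explicit stand-in model, kept
out of the score: the BP base of the `[-5, +1]` 7-mer bulges out and the
six flanking bases pair antiparallel with the snRNA branch-recognition
hexamer, scoring GC = 3, AU = 2, GU = 1, mismatch = 0, with the energy the
negated sum (lower = stronger). The U2 hexamer is GUAGUA; for U12 no
authoritative hexamer is fixed here, so the default GUAAGG — the
antiparallel complement of the minor branch consensus UCCUUAAC with the BP
adenosine bulged — is used and can be overridden per call. Under this model
the canonical TACTAAC branch motif pairs U2 perfectly at energy −14, and
any single substitution strictly weakens the duplex.

## The prioritization score

The score is an additive reconstruction honoring the ordinal structure of
the prioritization strategy; the published weight table is not available in
the main text, so the weights live in `score_weights()` and can be replaced
wholesale. Defaults:

| term | values |
|---|---|
| hit | 3 full-motif deletion or BP itself; 2 BP−2; 1 BP−1 |
| rank | 2 only BP; 1.5 first of ≤ 3; 1 second of ≤ 3; 0 otherwise |
| consensus | 2 / 1.5 / 1 / 0.5 / 0 for levels 1/2/3/4/0 |
| sources | 1 if ≥ 2 sources; +0.5 if mBP; capped at 1 |
| population | 1 no variant at BP or BP−2; 0.5 singleton/rare only; 0 common |
| conservation | 1 if GERP or PhyloP > 0 at the hit position; 0.5 if missing; 0 if negative |
| penalty | −1 for T>C or C>T at BP−2 |

The total is clamped to `[0, 10]`; ≥ 3 is the recommended follow-up
threshold. Missing conservation scores 0.5 rather than 0 because splicing
elements evolve quickly and low conservation does not imply low functional
importance; the penalty encodes the observation that T>C / C>T changes at
BP−2 are common in the population and depleted among pathogenic variants.
The score is monotone in every factor (fuzz-tested), and half-point
granularity is a consequence of the chosen weights, not a contract.

## What the synthetic fixtures emulate — and what they do not

All tests run on synthetic data built by the `fixtures` functions:

* `generate_fixture()` plants BP at collision-free distances (spaced ≥ 9 nt
  so 5-mer motif windows never interact) in two-exon genes on both strands,
  and plants SNVs, deletions and insertions at known transcript offsets;
  the manifest records expected hits by plant-time arithmetic, independent
  of the detection code, so detection is validated against planted truth
  and against a brute-force all-pairs oracle.
* `build_validation_fixture()` reconstructs the *geometry* of the 48 published
  pathogenic BP variants — variant type, deletion length and shape,
  distance to the 3'ss, rank and intron BP count, hit offsets, and the
  not-detected rows (whose introns carry a BP 9+ nt upstream of the
  variant) — on synthetic loci. Consensus levels (24/8/7/1 across levels
  1–4), BP classes (19 mBP / 1 eBP / 20 cBP), source counts, population
  and conservation context are assigned per variant consistently with the
  published aggregate counts; the published table prints one rank
  (`#1/2` for the first row) whose rank tallies disagree with the published
  aggregate 24/9/7 split, and the fixture follows the aggregate.
* `generate_adjustment_fixture()` builds YTNAY-centered loci with a chosen
  number of off-by-one duplicate raw records; the acceptance-level worked
  example uses 90 loci + 10 duplicates = a 100-record raw dataset whose
  adjustment delta is exactly −10.

What passing these tests shows: the interval arithmetic, strand handling,
ranking, consensus logic, merging and scoring behave exactly as specified,
at any scale, on both strands, including the published validation geometry.
What they do not show: performance of the published integrated database
itself (its 546k positions and their composition are products of ten real
datasets not shipped here), realistic population-frequency or conservation
distributions (fixture tracks are hand-planted), or detection sensitivity
on real sequencing artifacts (the fixtures contain no alignment noise, no
un-normalized indels, no multi-nucleotide repeats at BP motifs).

Problem sizes were chosen to keep the full suite comfortably within a few
minutes on one CPU: the oracle-equivalence suite runs 1,000 variants
against ~200 BP in 110 genes; the sweep, mirror and fuzz suites use smaller
bundles; the validation fixture has 48 loci.

## Degenerate inputs and numerical choices

* `N` bases never match any consensus level, and motifs that would leave
  the contig are reported missing rather than padded.
* Two BP equidistant from one 3'ss cannot occur on a single strand; the
  ranking code asserts this rather than defining a tie order.
* A BP inside several overlapping introns (alternative acceptors) yields
  one mapped record per intron, and a detection row per transcript
  membership, so transcript-level consequences stay visible.
* MAF exactly 1% classes as common; singleton requires AC = 1 from the AC
  track; a missing track is distinct from a value of 0 everywhere.
* Output rows sort by (contig, position, BP name, transcript) so repeated
  runs are byte-identical.

## Known limitations

Variants that create a new BP, or that create an AG dinucleotide between
the BP and the 3'ss (the mechanism behind the eight not-detected validation
variants), are out of scope by design — the engine only reports disruption
of documented BP. Insertions are reported with a low-confidence flag rather
than scored as confidently as SNVs and deletions. The minor-intron
heuristic under-calls GT-AG minor introns without an override list. The
binding-energy model is a pair-counting stand-in, suitable for ordering
motifs by complementarity, not a thermodynamic prediction.
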