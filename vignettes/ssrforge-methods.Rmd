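---
title: "ssrforge: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ssrforge: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrforge)
```

This vignette explains the models and procedures behind `ssrforge`, the
parameters that matter, and the design choices made where more than one
reasonable reading existed. It states no empirical result beyond what the
package's own tests and `scripts/acceptance.R` compute.

## What counts as an SSR locus

A locus is a **maximal whole-copy tandem run** of a **primitive** motif:

* *whole-copy*: the reported interval is an integer number of motif
  copies, so `end − start + 1 = repetitions × |motif|` always holds;
* *maximal*: the run cannot be extended by one whole unit on either side;
* *primitive*: the motif is not itself a repetition of a shorter word.
  `ATAT` is excluded from the motif library, which is what prevents an
  `(AT)x6` tract from being double-reported as `(ATAT)x3` — each run is
  attributed once, to its minimal period.

Coordinates are 1-based inclusive everywhere a user sees them (a `TAx6`
tract at 2693–2704 spans 12 bases); chunk offsets are internal and
0-based. Mining is case-insensitive, so soft-masked lowercase sequence is
searched, and motifs are reported uppercase in the phase in which they
occur at the locus start (no canonical rotation — both `TA` and `AT`
can appear in a locus table). Non-ACGT characters are preserved in the
records and simply never match a motif.

### The scan and its greedy phase rule

For each period `p` the miner computes the boolean array
`eq[i] = (s[i] == s[i+p])` and reads maximal `TRUE` blocks as maximal
periodic regions; this is O(n) per period and vectorises well in R. A
region of length `R` yields a run of `floor(R/p)` copies anchored at the
region's left edge. When a region carries partial trailing copies, some
phase must be chosen; `ssrforge` takes the leftmost one, and when two
same-period regions overlap by a sub-period amount the later run is
shifted right to the first free base — exactly the behavior of a greedy
regex engine that consumes each match and resumes scanning after it.
Consequences worth knowing:

* runs of the same minimal period never overlap;
* the unit test and acceptance suites verify the scan against an
  independent brute-force implementation (a literal per-position greedy
  scan) with exact equality on hundreds of random sequences;
* mining a reverse-complemented sequence mirrors locus *intervals*
  exactly when every periodic region is a whole multiple of its unit
  (all planted fixtures); with partial trailing copies the mirrored
  anchor can shift by up to `p − 1` bases, because "leftmost" refers to
  opposite physical ends in the two orientations. The run count, length
  and period multiset are orientation-invariant either way.

### Containment filtering

With the filter on (default), a locus whose interval lies inside another
reported locus is dropped, keeping the longer locus; on an exactly equal
interval the shorter period wins as the more parsimonious description.
Partial cross-period overlaps are deliberately *kept* — nothing in the
underlying method defines a winner there, and dropping either would hide
a real repeat.

### Chunking and why it is invisible

Sequences longer than `chunk_size` (default 2,000,000 bp) are mined in
chunks overlapping by `overlap` (default 20 bp). Runs short enough to fit
inside the overlap are simply seen whole by one of the two chunks and
deduplicated. For runs wider than the overlap, each chunk reports its
truncated piece (near chunk edges the per-chunk copy threshold is relaxed
to 2 so that short border fragments survive); the merge step then
coalesces pieces that overlap or abut *in phase* — motifs must be
rotation-equivalent with the rotation implied by their start offsets —
and re-anchors every merged run on the parent sequence: extend by whole
units both ways, re-read the motif at the merged start, re-apply the real
copy threshold, then re-run the greedy overlap resolution and containment
filter. The test suite asserts byte-identical `.ssr` output between
chunked and unchunked runs, including tracts planted across chunk
borders, on multi-megabase fixtures.

## Mining parameters

| parameter | default | notes |
|---|---|---|
| `min_unit`–`max_unit` | 2–6 bp | any range is accepted; monomers enabled by `min_unit = 1` |
| `min_repeats` | 5 copies for units 2–6 | per-unit map; the conventional monomer threshold is 12 (`c("1" = 12)`) |
| `chunk_size` | 2,000,000 bp | memory/speed trade-off only; results are invariant |
| `overlap` | 20 bp | border runs longer than this are restored by the merge step |
| `containment_filter` | on | see above |

The 2–6 bp / 5-copy preset is an inference from the worked examples this
package models (locus tables listing 5-copy dimers and trimers, figure
settings of "unit length 2–6 bp" and "monomers with a minimum of 12
repeats"); the true defaults of the original tool are not published, so
the preset is documented here as inferred and everything is overridable.

## Statistics

The five classifications are: unit-length counts (MT = Σ L(i)); motif
counts (phase preserved); complementary groups, pooling each motif with
its reverse complement under the label `min/max` lexicographically
(`GA/TC`; self-complementary `AT` forms `AT/AT`) — rotations are *not*
pooled, since published motif lists keep e.g. `AG`-type and `GA`-type
groups distinct; per-sequence frequency `scale·count/length`; and tract
length counts (SL = Σ l). The frequency scale default is 10⁶ ("per Mb",
the interpretable convention) although the formula as printed in the
source literature uses 10⁵; `--freq-scale`/`scale` restores the latter.
Percentages are reported to 2 decimals; every section of the `.sat2`
report is ranked by descending count; counts in every section sum to the
total locus count (tested).

## Primer design

No primer3 binding backs the designer; `ssrforge` implements the
standard nearest-neighbor duplex model directly: unified NN parameters
(Allawi & SantaLucia), duplex initiation terms per terminal base, the
entropic salt correction `ΔS += 0.368 (N−1) ln[Mon⁺]` with the von Ahsen
monovalent equivalent `[Mon⁺] = [Na⁺] + 120·√([Mg²⁺] − [dNTP])` (defaults
50 mM Na⁺, 1.5 mM Mg²⁺, 0.6 mM dNTP), and `Tm = 1000·ΔH / (ΔS + R ln C)`
at C = 50 nM oligo. The implementation is cross-checked in the tests
against biopython's `Tm_NN` at identical settings to 10⁻⁴ °C. Under
these conditions a balanced 20-mer sits near the 60 °C target, which is
why the default acceptance window is 57–63 °C.

Candidates are every substring of length 18–27 wholly inside one flank
(primers never overlap the SSR tract), filtered on GC 20–80%, Tm window,
no homopolymer of 6+, no non-ACGT base, and no self-complementary
(palindromic) sequence — palindromes are primer-dimer prone and their
duplex symmetry shifts the effective Tm. Prefix sums over the window make
candidate enumeration O(1) per candidate. The pair minimising
`|Tm−60| + 0.2·|len−20|` summed over both primers, subject to the product
size range (default 100–400 bp), is returned; ties break
deterministically by position then length. Because only the flanking
window (default 400 bp per side) is ever examined, design cost scales
with locus count, not genome length.

Identical `(left, right)` string pairs cluster into one marker with
serial IDs in first-occurrence order. When duplicated source regions
yield the same pair with different amplicon sizes, all source loci are
kept and the first-seen size is printed in `.sts` — the e-PCR stage, not
the declared size, is the authority on per-target alleles.

## e-PCR

Binding sites are located with a mismatch budget (default 0) and a
required exact 3' terminus (default 3 bases; extension cannot start from
a mismatched 3' end). Convergent site pairs in both template orientations
become amplicons, bounded by absolute size limits (default 50–5000 bp) to
prevent genome-spanning pairings. A margin around the declared size is
*off* by default: allele-length polymorphism is precisely a deviation
from the declared size, so filtering on it would defeat the purpose; the
margin exists for transferability screening where spurious distant
pairings are a concern. Multi-band amplification is reported in full;
allele-matrix cells join sizes ascending with `+` (`200+204`) — the
ordering convention is this package's own, as published examples are
inconsistent on it — and `NA` marks no amplification. A marker is
polymorphic when at least two distinct non-NA cell values occur.

## GFF3 export

Feature lines are formatted by the package itself so output is
deterministic (no timestamps); `rtracklayer`'s importer is used as the
round-trip reader and syntax checker in the tests. Loci become
`microsatellite` features (strand `+`, attributes `motif`,
`repetitions`), marker placements become `STS` features named by marker
ID; both types are Sequence Ontology terms that genome browsers accept.
Only GFF3 is emitted — no other browser dialect is defined precisely
enough to target. Exported intervals are asserted identical to the
`.ssr`/`.amp` tables.

## The synthetic-data generator

`generate_genome()` plants exact tandem tracts into i.i.d. background at
a chosen GC content, then repairs the background by point mutation until
a permissive scan (thresholds one copy stricter than any default preset:
monomers ≥ 8, dimers ≥ 4, units 3–6 ≥ 3 copies) reports exactly the
planted truth — this also removes background context that would extend a
planted tract. `mutate_alleles()` applies whole-unit copy-number changes
with flanks untouched, modelling replication-slippage length variants.
Both are deterministic per seed.

What the generator does *not* emulate: interrupted or compound repeats,
base-composition heterogeneity, duplicated regions (markers on real
genomes dedup far more aggressively), sequencing gaps and ambiguity
codes in bulk. Passing tests therefore demonstrate algorithmic
correctness on clean truth, not recall on real genomes, where the
perfect-repeat definition itself (no mismatch tolerance) is the binding
limitation.

## Problem sizes and numerical choices in the test suite

The suite verifies oracle equivalence on 100 random 5–10 kb sequences,
chunking invariance on a ~5 Mb two-record fixture with border-spanning
tracts, and the design→mapping closure plus indel tracking on 20 kb
planted genomes; it completes in a few minutes on one CPU. Frequencies
are checked to 10⁻⁹ relative tolerance, Tm against the independent
oracle to 10⁻⁴, percentages to 0.01. Plots render through cairo at fixed
size and DPI and are hash-compared across runs.

## Known limitations

* Perfect repeats only; imperfect/interrupted SSRs and compound-SSR
  annotation are out of scope.
* Monomer defaults are conservative; homopolymer-rich genomes need an
  explicit `min_repeats["1"]`.
* The primer designer models duplex stability but not secondary
  structure, cross-dimers or template specificity beyond e-PCR
  re-mapping.
* Genic/intergenic partitioning of loci is left to standard interval
  tools on the exported GFF3.
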