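# ssrforge

Genome-scale microsatellite (SSR) mining, marker design and in-silico PCR
in R.

Simple sequence repeats — tandem DNA repeats with unit lengths of
typically 1–6 bp — are among the most variable sequences in eukaryotic
genomes and remain a workhorse marker system in plant breeding, forensics
and population genetics. Turning an assembled genome into a panel of
usable SSR markers requires a chain of steps: finding every tandem repeat
locus, summarising the repeat landscape, designing a PCR primer pair
flanking each locus, collapsing duplicate pairs into uniquely identified
markers, predicting each marker's amplicon sizes on other genomes to
screen polymorphism and transferability, and exporting everything as
genome-browser tracks. `ssrforge` implements that whole chain for DNA
sequences of any length, for R users who want it scriptable end to end.

## The method

**Mining.** Sequences longer than a configurable limit (default 2 Mb) are
split into chunks that share a short overlap (default 20 bp). Within each
chunk, every maximal whole-copy tandem run of a *primitive* motif (one
that is not itself a repetition of a shorter word, so `(AT)x6` is never
double-reported as `(ATAT)x3`) is located by a vectorised periodicity
scan equivalent to a greedy left-to-right regex search; runs of the same
minimal period never overlap. A run of motif `m` with unit length `|m|`
and `k` copies occupies `k·|m|` bases, and is reported once
`k ≥ min_repeats(|m|)` (default: 5 copies for unit lengths 2–6; monomer
mining is off unless enabled, conventionally at 12 copies). Runs reported
from overlapping chunks are deduplicated, border-spanning pieces are
coalesced and re-anchored on the parent sequence, so chunked and
unchunked mining give byte-identical locus tables. Loci contained inside
another locus are dropped.

**Statistics.** Five classifications of the locus table: motif type by
unit length MT = Σᵢ L(i); motif composition; complementary motif groups
(a motif pooled with its reverse complement, e.g. GA/TC, since strand
orientation is arbitrary); per-sequence frequency = scale·Σ(SSR)/Length
(default scale 10⁶, i.e. loci per Mb); and the SSR length distribution
SL = Σᵢ l. Each table carries counts and percentages in descending rank
and is plotted as bar/pie/scatter charts.

**Markers.** For each locus a flanking window (default 400 bp per side)
is extracted and a primer pair is chosen by exhaustive candidate
enumeration under nearest-neighbor thermodynamics (unified SantaLucia
parameters; defaults: length 18–27 nt, GC 20–80%, Tm 57–63 °C targeting
60 °C, product 100–400 bp, one primer wholly within each flank).
Identical (left, right) pairs are clustered into one marker (`MK1`,
`MK2`, ...).

**e-PCR.** Markers are mapped onto any FASTA set by locating primer
binding sites (exact by default; optional mismatch budget with an exact
3' end) and pairing convergent sites within size bounds. Per-marker
allele sizes across targets form the polymorphism matrix (`200+204`
multi-band cells, `NA` for no amplification); a marker is polymorphic
when targets disagree.

## Worked example

```r
library(ssrforge)

# a 20 kb synthetic chromosome with three planted SSR tracts
plants <- data.frame(motif = c("TA", "AAG", "GT"), copies = c(6, 5, 8))
g <- generate_genome(plants, c(chr1 = 20000), seed = 42)

res <- mine_genome(g$seqs)
res$loci
#>   seq_id seq_len start   end repetitions motif
#> 1   chr1   20000  1252  1267           8    GT
#> 2   chr1   20000  9290  9304           5   AAG
#> 3   chr1   20000 18753 18764           6    TA
```

Each row is one locus: `(GT)x8` spans 16 bases at 1252–1267 (coordinates
are 1-based inclusive, so end − start + 1 = repetitions × unit length).
Statistics, marker design and self-mapping then chain directly:

```r
ssr_stats(res$loci, g$seqs)$complement_group
#>     group count percentage
#> 1 AAG/CTT     1      33.33
#> 2   AC/GT     1      33.33
#> 3   TA/TA     1      33.33

mk <- deduplicate_markers(design_all(res$loci, g$seqs)$pairs)
mk$markers
#>   marker_id          left_primer         right_primer product_size motif n_loci
#> 1       MK1 GCAATGACGGTATCCGAACT ATTGGAATAGCTCTTGGCCG          335    GT      1
#> 2       MK2 CCTTAGGCAATAGGCAGAGC ACCGCGATACATTCGTCAAA          343   AAG      1
#> 3       MK3 CTCAAGGTCCGTCGTACAAG CGTAACAGGTATTCGCCGAA          399    TA      1

epcr(mk, g$seqs)[, c("marker_id", "seq_id", "start", "end", "size")]
#>   marker_id seq_id start   end size
#> 1       MK1   chr1  1203  1537  335
#> 2       MK2   chr1  9236  9578  343
#> 3       MK3   chr1 18427 18825  399
```

Every marker re-amplifies its declared product size at its source locus —
the design-to-mapping loop closes. `loci_to_gff3()` / `markers_to_gff3()`
write browser tracks, and `run_pipeline("settings.cfg")` (or the
`exec/ssrforge` command-line front end) drives any subset of the stages
mine → stats → plot → design → emap → export from a flat key=value
settings file, writing the `.ssr`, `.sat1`, `.sat2`, `.mk`, `.sts`,
`.amp`, `.frg`, `.emap`, `.sat4` and `.gff3` artifacts.

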