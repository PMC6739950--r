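---
title: "From ISCN karyotypes to genomic gain/loss intervals: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From ISCN karyotypes to genomic gain/loss intervals: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyoconvert)
```

## The problem and the model

A karyotype is a compressed, band-resolution description of the
chromosome complement of a cell population: a modal chromosome count, a
sex designation, and a comma-separated list of aberration terms, with
clones separated by `/` and cell counts in brackets. karyoconvert turns
that description into net copy-number calls in genomic coordinates.

The model is deliberately the simplest one consistent with the
nomenclature's semantics:

1. **Clone baseline.** Every autosome starts at the clone's ploidy
   (2 unless a `<kn>` marker says otherwise). A sex chromosome starts at
   its count in the sex designation *plus one for every structural term
   (without a `+` operator) whose base chromosome it is*, because ISCN
   drops the rearranged homolog from the sex field: in
   `46,X,del(X)(q21.31q27.2)` the cell still has two X-derived
   chromosomes, so the deleted segment is a hemizygous, not homozygous,
   loss.
2. **Per-term deltas.** Each unbalanced term contributes signed copy
   deltas on intervals (the table in the README). Balanced
   translocations, inversions and insertions move material without
   changing its amount and contribute nothing; markers, double minutes
   and hsr carry unknowable content and contribute nothing but a warning.
3. **Accumulation and classification.** A sweep over interval endpoints
   sums the deltas per chromosome into maximal segments of constant net
   change, which are classified against the baseline as Gain, hemizygous
   Loss, or homozygous Loss (net copies clamp at zero).

Two conventions are load-bearing and worth stating explicitly:

* **Coordinates are 0-based half-open**, exactly as in UCSC cytoBand.txt.
  Whole-chromosome rows therefore start at 0, and no +1 shift exists
  anywhere in the code.
* **Breakpoint bands are wholly included in the segment the event
  describes.** A deletion `del(X)(q21.31q27.2)` removes from the *start*
  of q21.31 to the *end* of q27.2; a derivative `der(10)t(10;21)(p13;q21)`
  retains chromosome 10 from the start of p13 and gains chromosome 21
  from the start of q21. Cytogenetic breakpoints are only localized to a
  band, so the convention resolves the ambiguity identically for losses
  and gains and keeps reciprocal events exact inverses of each other.

## Band resolution

Band lookup runs against the 850-band UCSC cytoband tables vendored for
hg18, hg19 and GRCh38 (default hg19; the table is the standard 5-column
cytoBand.txt and a user file can be substituted). Three cases need rules
beyond exact lookup:

* a label *coarser* than the table (`q21` where the table holds
  q21.1/q21.2/q21.31…) resolves to the union of all finer bands that
  extend it, comparing labels with dots removed;
* a label *finer* than the table resolves to the finest enclosing table
  band — the tables have fixed resolution and sub-band interpolation
  would be false precision;
* `p10`/`q10` denote the centromere and resolve to the zero-width point
  at the shared edge of the two acen bands, not the midpoint of the
  centromeric region. The whole-arm intervals are `[0, boundary]` and
  `[boundary, length]`, so the two arms tile the chromosome exactly.

Label normalization strips whitespace and a stray dot after the arm
letter (`q.21.31` is read as `q21.31`), both observed in real-world
karyotype transcriptions. A label that still matches nothing causes the
*aberration* (not the run) to be skipped with a warning naming the term.

## Parser behavior on messy input

Batches of archival karyotypes are never clean, so the parser is
warning-driven: any term it cannot type becomes an `unknown_term` on the
warnings channel and processing continues. Specific decisions:

* `?` marks a term uncertain; it is processed as written and flagged. A
  fully unknown breakpoint (`del(5)(?)`) is untypeable and becomes
  `unknown_term`.
* A trailing `c` (constitutional) is included in the output like any
  acquired change, with a warning noting its status — net genomic content
  is what downstream interval queries care about, regardless of origin.
* `xN` multiplies a term by repetition: `del(5)(q13)x2` is two deletions.
* `idem` prepends the stemline's (first clone's) aberrations to the
  current clone; `sl`/`sdl` stemline shorthand is not supported and
  degrades to a warning.
* The modal number is parsed but never enforced: `46,XY,der(1;19)(q10;p10)`
  implies 45 chromosomes as written, and the row output is produced
  anyway, with a consistency warning. Only explicit terms generate
  deltas, so `45,X` without a `-X` term produces no rows — a warning
  points this out, since the writer probably meant a lost X.
* Three-way derivatives (`der(1)t(1;3)(p32;q21)t(3;7)(q26;q22)`) are
  assembled by walking the t() chain piece by piece under the same
  band-inclusion rule; intermediate pieces span between the two
  breakpoints named on the shared chromosome. The nomenclature has
  dialects here; chains that do not connect are skipped with a warning.

Decisions where the nomenclature is genuinely silent, resolved as this
package's own choices: `add()` counts the unknown added material as
nothing (the distal loss is reported, the gain is unquantifiable);
`+i(cq)` contributes +2 on the arm (a supernumerary isochromosome carries
two arm copies); a `-` in front of a structural term is read as loss of
that derivative, with a warning, since the form is nonstandard.

## Output and heatmap

The report has one row per maximal gained/lost segment: clone id
(`<sample>_<n>`, the suffix always present so multi-clone and
single-clone samples sort identically), chromosome, start, end,
Gain/Loss, and a cells string. The cells string is `k of N` where N sums
the *known* clone counts of the sample; clones with unknown counts are
excluded from N with a warning rather than poisoning the whole sample's
denominator.

The heatmap bins the concatenated genome (default bin 1 Mb — at the
850-band table's median band size of ~3 Mb, finer bins add pixels, not
information). Each bin takes the state covering most of its bases; ties
break toward loss (homozygous over hemizygous over gain) so a small
homozygous deletion is never visually swallowed by a surrounding gain.
Gains are red, hemizygous losses blue, homozygous losses yellow.

## The synthetic generator and what passing means

`sample_karyotype()` draws random clones and renders them as ISCN
strings, but its real purpose is the *constructive oracle*: each clone is
assembled as an explicit list of homologs, each a list of
(chromosome, start, end) pieces, and every event edits a fresh untouched
homolog (so event stacks are never self-contradictory). Expected
segments then fall out of per-base piece coverage minus the starting
copy counts — code that shares nothing with the parser, the delta rules,
or the interval sweep except the band table itself. The test suite
demands *exact* segment equality between that oracle and the full
pipeline on several hundred generated karyotypes over both the hg19
table and randomized toy band maps (the suite uses ~370 clones across
three generator configurations, and the acceptance script repeats the
check at similar size).

The generator emulates: 1–2 clones per sample, 1–6 events per clone
drawn from seventeen event kinds (weights in
`default_event_weights()`), breakpoints drawn uniformly from the band
table, cell counts present ~70% of the time. It does **not** emulate the
empirical aberration spectrum of any real cohort, recurrent breakpoint
hotspots, `idem`/composite-karyotype shorthand, or transcription noise
(a `--dialect-noise`-style corruption layer was considered and dropped:
whitespace and `?` tolerance are unit-tested directly). Passing the
oracle test therefore shows the *semantics* are internally consistent
and the golden examples show agreement with published conversions; it
does not certify every dialect of real-world ISCN.

Toy band maps (`make_toy_bandmap()`) place the centromere at the
chromosome midpoint and randomize interior band edges under a seed; they
exist so parser/engine properties can be exercised on chromosomes of a
few hundred bases where per-base oracles are cheap.

## Numerical and degenerate-input choices

* Interval arithmetic is pure integer arithmetic on base positions; no
  floating-point tolerances exist anywhere.
* Zero-width intervals (a `q10` centromere point; a deletion whose band
  starts at position 0 leaving an empty distal piece) are dropped before
  accumulation.
* Deltas below −baseline clamp at zero copies and classify as homozygous
  loss, with an over-subtraction warning.
* Chromosomes with baseline zero (chrY in a female clone) drop any
  stray deltas with a warning rather than dividing by an absent
  reference.
* Duplicate sample names in a batch are uniquified (`_dup` suffix) so
  clone ids stay unambiguous.

## Limitations

No liftover between assemblies (pick the table matching your
coordinates); no sub-band interpolation; human karyotypes only; no FISH
(`ish`) or microarray (`arr`) nomenclature; balanced events are by
design absent from the output, so fusion breakpoints must come from
other tools. Per-clone reporting is deliberate: no cross-clone averaging
into a single sample-level profile is attempted.
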