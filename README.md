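# karyoconvert

Convert human karyotypes written in ISCN cytogenetic nomenclature into the
net chromosomal gains and losses they imply, expressed as genomic
coordinate intervals.

Karyotypes such as `46,XY,der(1;19)(q10;p10)` summarize the chromosome
complement of a cell population at cytoband resolution. Modern analyses —
locating genes, comparing against microarray or sequencing copy-number
calls — need genomic coordinates instead. karyoconvert parses a karyotype
(or a whole tab-delimited table of them), splits it into clones, types
every aberration term, and reports each clone's net copy-number changes as
`chrom:start-end` intervals on hg19 (or hg18/GRCh38), together with the
number of cells in each clone when the karyotype records it. It is aimed
at researchers mining archival cytogenetic data — leukemia cohorts, cell
line catalogues, tumor registries — where the DNA is long gone but the
karyotypes survive.

## What it computes

Each clone is scored against a baseline of *b* copies per chromosome
(*b* = 2 for autosomes at near-diploidy, scaled by a `<kn>` ploidy marker;
sex chromosomes are counted from the sex designation plus the homolog each
structural term consumes). Every unbalanced term contributes signed copy
deltas on intervals resolved through the UCSC 850-band cytoband table:

| term | net change |
|---|---|
| `+N` / `-N` | ±1 over the whole chromosome |
| `del(c)(b)` | −1 from band b (included) to the telomere |
| `del(c)(b1b2)` | −1 over [b1, b2], both bands included |
| `dup` / `trp` | +1 / +2 over the same span |
| `i(cq)` | +1 on the q arm, −1 on the p arm (+2 on q if supernumerary) |
| `der(c1;c2)(q10;p10)` | −1 on c1's p arm and c2's q arm (whole-arm swap) |
| `der(c)t(c;d)(b1;b2)` | −1 on the c piece lost, +1 on the d piece gained |
| `add(c)(b)` | −1 distal to b; the unknown added material counts nothing |
| `r(c)(b1b2)` | −1 on both tips outside the ring |
| `t`, `inv`, `ins` | nothing — balanced events change no net copy number |

A sweep over interval endpoints accumulates the deltas into maximal
segments of constant net change *d*, classified as Gain (*b+d > b*),
hemizygous Loss (*0 < b+d < b*) or homozygous Loss (*b+d ≤ 0*). Breakpoint
bands are always wholly included in the segment the event describes, and
only explicit terms generate output — the modal number and sex field alone
never do. Anything unrecognized degrades to a warning, never a crash, so
thousand-row batches run unattended.

## Worked example

```r
library(karyoconvert)
res <- karyo_convert("46,XY,der(1;19)(q10;p10)", sample_ids = "ABC")
res
#> <karyo_result: 1 clone(s), 2 gain/loss row(s), 1 warning(s), assembly hg19>
#>   sample_clone chrom    start       end type   cells
#> 1        ABC_1  chr1        0 125000000 Loss unknown
#> 2        ABC_1 chr19 26500000  59128983 Loss unknown
```

The whole-arm derivative der(1;19)(q10;p10) fuses 1q to 19p, replacing one
chromosome 1 and one chromosome 19; the clone therefore nets one copy of
1p (chr1:0–125,000,000, ending at the centromere) and one copy of 19q
(chr19:26,500,000–59,128,983, centromere to telomere) below baseline —
both hemizygous losses. `_1` marks the first (here only) clone; with
multiple clones (`.../...[30]/...[50]`) each gets its own rows and a
"30 of 80"-style cell count. `write_table(res, "out.tsv")` writes the
six-column report, `write_warnings()` the warning side-channel, and
`render_heatmap()` a genome-wide overview (gains red, hemizygous losses
blue, homozygous losses yellow).

A thin command-line wrapper is installed under `exec/`:

```sh
Rscript "$(Rscript -e 'cat(system.file("exec/karyoconvert", package="karyoconvert"))')" \
  --input samples.tsv --assembly hg19 --out results --plot
```

with a `synth` subcommand that emits random karyotype/expected-segment
fixture pairs from the package's constructive generator.

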