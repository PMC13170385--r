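# stemloopscreen

Genome-wide detection of mRNA stem-loops immediately 3' of stop codons,
and quantification of stop codon readthrough (SCR) reporters.

## The problem

When a ribosome reaches a stop codon, a near-cognate tRNA sometimes
decodes it and translation continues into the 3'UTR, yielding a
C-terminally extended protein. This *programmed stop codon readthrough*
is widespread in *Drosophila* and is promoted by *cis*-acting mRNA
features: the stop codon identity, the +4..+9 downstream hexamer
(+1 = first base of the stop codon), and a stable RNA stem-loop just 3'
of the stop. `stemloopscreen` is for researchers who want to

* screen an annotated genome (FASTA + Ensembl-dialect GFF3) for genes
  whose stop-codon-proximal 3'UTR window folds into a qualifying
  hairpin,
* design destabilizing / stabilizing / compensatory stem-loop sequence
  variants for reporter experiments, and
* quantify dual-luciferase and dual-fluorescence readthrough reporters.

## The method in brief

For each gene, the transcript with the most-upstream 3'UTR (in gene
orientation) is selected, and the window $w = u_1 \ldots u_W$ of the
first $W$ spliced 3'UTR nucleotides ($W = 60$ or $80$) is excised
downstream of the stop codon. A secondary structure of $w$ is obtained
either from an external thermodynamic folder (RNAfold-style dot-bracket
files are ingested) or from the built-in maximum-base-pairing folder,
which maximizes $\sum_{(i,j)} s(u_i, u_j)$ over nested structures with
$s(\mathrm{GC}) = 3$, $s(\mathrm{AU}) = 2$, $s(\mathrm{GU}) = 1$ and a
minimum hairpin loop of 3 nt. Each hairpin element of the structure —
a helix read outward from a terminal loop, absorbing bulges, stopping
at multiloop junctions — is then classified as a stem-loop when

* element span ≥ 35 nt,
* terminal loop length in [3, 10] nt, and
* every unpaired run interrupting the stem ≤ 2 nt

(the `"paper2026"` criteria preset; all thresholds configurable). A
gene is called when at least one element qualifies. Readthrough
efficiency is quantified as
`100 × (FLuc/RLuc)_test / (FLuc/RLuc)_sense-control` after background
correction, the sense-codon control defining 100%.

## Worked example

```r
library(stemloopscreen)

# a deterministic toy genome: 20 genes, 7 with a planted qualifying hairpin
g <- synthGenome(nGenes = 20, plantedFraction = 0.35, seed = 1)
res <- runStemloopScreen(g$genome, g$transcripts)
attr(res, "summary")
#>                 genes     windows_extracted structures_classified
#>                    20                    20                    20
#>                passes               skipped
#>                     7                     0

head(res[res$passed, c("gene_id", "passed", "element_start", "element_end", "mfe")], 3)
#>  gene_id passed element_start element_end mfe
#>    sg001   TRUE            15          56 -48
#>    sg002   TRUE             6          51 -51
#>    sg003   TRUE             4          55 -60
```

The seven planted genes are exactly the seven calls; element
coordinates are in the +1-at-stop convention, so `15..56` means the
hairpin starts 11 nt after the 3'UTR begins (+4). Looking at one gene:

```r
ctx <- extractStopContext(g$genome, g$transcripts[[1]])
ctx
#> StopContext sg001: stop UAA, window 60/60 nt (+4..+63)
#>   AAAAAAAAAAAGGGGGGGGGGGGGGGGAAAAAAAAACCCCCCCACCCCCCCCCAAAAAAA

foldMaxPair(windowSequence(ctx))
#> SecondaryStructure (maxpair) of length 60
#>  AAAAAAAAAAAGGGGGGGGGGGGGGGGAAAAAAAAACCCCCCCACCCCCCCCCAAAAAAA
#>  ...........((((((((((((((((.........))))))).))))))))).......
#>   score: -48.00
```

a 16-bp stem with a 9-nt loop and a 1-nt bulge: span 42, loop 9,
bulge 1 — a qualifying stem-loop. Reporter quantification uses the
same functions a plate analysis would:

```r
readthroughEfficiency(4.1, 22)          # reporter vs sense-codon control means
#> [1] 18.63636                          # ~18% readthrough
relativeReadthroughLevel(c(dfr288 = 18.6, variant = 9.3), "dfr288")
#>  dfr288 variant
#>     1.0     0.5
```

A thin CLI over the same functions lives in `inst/scripts/slscreen.R`
(subcommands `screen`, `fold`, `detect`, `simulate`, `readthrough`).

## Package layout

| file | contents |
|------|----------|
| `R/genome-io.R` | FASTA/GFF3/RNAfold-dialect readers, table writers |
| `R/stop-context.R` | primary-UTR selection, window extraction, +1-at-stop map |
| `R/folding.R` | dot-bracket/pair-table conversion, max-pairing folder |
| `R/hairpin-detect.R` | hairpin enumeration and the criteria classifier |
| `R/variant-design.R` | DV/DVC/SV/SVC designs, stem shift/deletion edits |
| `R/screen.R` | genome-wide orchestration, gene-set overlaps |
| `R/reporter-stats.R` | readthrough efficiency formulas |
| `R/synth-fixtures.R` | planted-hairpin and toy-genome generators |

See the methods vignette (`vignettes/stemloop-screen-methods.Rmd`) for
the model, parameter meanings, design decisions and limitations.
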