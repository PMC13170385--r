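---
title: "Screening for stop-codon-proximal mRNA stem-loops: methods and design"
author: "stemloopscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for stop-codon-proximal mRNA stem-loops: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemloopscreen)
```

## The biological question

During translation termination, a near-cognate tRNA occasionally decodes
the stop codon and the ribosome continues into the 3'UTR, producing a
C-terminally extended protein. This programmed stop codon readthrough
(SCR) is common in *Drosophila* and is promoted by *cis*-acting mRNA
features: the identity of the stop codon, the immediately downstream
hexamer (+4 to +9 in the convention where +1 is the first stop-codon
base), and — the feature this package screens for — a stable RNA hairpin
(stem-loop) located just 3' of the stop codon. This package implements
the computational side of that biology: extracting the stop-codon-proximal
3'UTR window of every annotated gene, predicting or ingesting secondary
structures, classifying hairpins against explicit geometric criteria,
designing stability-perturbing sequence variants, and quantifying
dual-reporter readthrough measurements.

## Coordinate conventions

All genomic input follows GFF3: 1-based, inclusive. Internally every
interval is a 1-based inclusive `IRanges`, the native convention of the
R/Bioconductor stack, so annotation coordinates pass through unchanged
and there is exactly one place (none, in practice) where an off-by-one
could be introduced. The Ensembl annotation convention is assumed: the
CDS includes the stop codon and `three_prime_UTR` starts immediately
after it.

Window positions are reported in the +1-at-stop convention: position +1
is the first base of the stop codon, +4 is the first 3'UTR base. A
window of width $W$ therefore occupies $+4 \ldots +(3+W)$, and
`offsetMap()` exposes the bijection between window indices, these paper
coordinates, and genomic coordinates.

## Window extraction

For each gene the screen selects the transcript whose stop codon lies
most 5' **in gene orientation** (`selectPrimaryUtr()`), i.e. whose 3'UTR
starts most upstream of the gene. The equivalent genomic-coordinate
reading would be wrong for minus-strand genes, so ties and orientation
are handled strand-aware; remaining ties go to the longer annotated
3'UTR, then to the lexicographically smallest transcript id, making the
choice deterministic.

Windows are mRNA-level: the spliced 3'UTR exons are concatenated in
transcript order (reverse-complemented for minus-strand genes) before
the first $W$ nucleotides are taken, because the structure forms on the
mature transcript, not on genomic DNA. Genes whose annotated UTR is
shorter than $W$ are kept with a shorter window and flagged `truncated`
rather than dropped — dropping is a reversible downstream filter,
recovery is not. The stop triplet is checked strictly
(UAA/UAG/UGA) by default with a permissive flag, since transcripts
annotated through a readthrough event can legitimately embed internal
stops. Softmasked (lowercase) genome bases are treated as ordinary bases
for extraction and folding; masking matters for alignment, not for a
per-window structure screen.

## Secondary structures and the two backends

Structures are nested (pseudoknot-free) pair tables interconvertible
with dot-bracket strings. Two backends exist:

* **external** — thermodynamic predictions (e.g. RNAfold text output)
  are ingested via `readRnafoldFile()`, which parses the
  header/sequence/"dot-bracket (MFE)" dialect, tolerates padding inside
  the energy field, rejects individual entries with unbalanced brackets
  and keeps the rest. When a structure file is supplied the screen never
  folds internally — no silent backend mixing. Reproducing published
  genome-scale counts requires this backend with the pinned folder
  version and annotation build.
* **maxpair** — a self-contained maximum-base-pairing folder
  (`foldMaxPair()`): Nussinov-style dynamic programming maximizing total
  pair weight over nested structures with Watson–Crick plus G·U wobble
  pairs, a minimum hairpin loop of 3 nt, and unpairable N. It exists so
  that every downstream module is testable with no external dependency;
  it is a base-pair-count model, not a thermodynamic one.

Default weights are GC = 3, AU = 2, GU = 1 (hydrogen-bond counts),
which rank helix stability qualitatively like free energy; `minLoop = 3`
is the steric minimum. The reported score is minus the total weight so
that "lower = more stable" matches the MFE sign convention; its unit is
weight, not kcal/mol. Traceback is deterministic: whenever pairing the
interval's first position attains the optimum it is paired with the
smallest admissible partner, otherwise left unpaired — identical input
always yields an identical structure.

One symmetry subtlety: with a symmetric weight matrix the optimum score
is invariant under sequence *reversal*, but **not** under reverse
complementation once wobble pairs score, because a G·U pair maps to
unpairable C/A (at minimum loop 3, `GAAAU` scores 1 while its reverse
complement `AUUUC` scores 0). The test suite asserts the symmetry that
actually holds.

## Hairpin elements and the classification criteria

`enumerateHairpins()` produces one element per terminal loop: starting
at the loop's closing pair it extends outward through consecutive
pairs, absorbing helix interruptions where at least one side is
unpaired (one-sided bulges and two-sided internal loops, each side
recorded as its own run), and stops at a multiloop junction or the
exterior. Elements of different terminal loops never share pairs.

A sequence is called a stem-loop when **at least one** element satisfies
the criteria — unpaired flanking tails and additional non-qualifying
elements are permitted, since per-element evaluation is what makes a
longer window able to *lose* a call when the energetically preferred
structure reorganizes. The default preset `"paper2026"`:

| parameter | default | meaning |
|-----------|---------|---------|
| `minSpan` | 35 nt | element span, outermost pair to outermost pair |
| `loopMin`..`loopMax` | 3..10 nt | terminal loop length |
| `bulgeMax` | 2 nt | maximum unpaired run interrupting the stem |

Two genuinely open readings were fixed as follows. First, the minimum
length is interpreted as the **element span**, not the input length
(all inputs are 60/80 nt, which would make a sequence-length reading
vacuous) and not the helix length alone. Second, for internal loops the
two sides are limited **individually** by default (`bulgeMode = "each"`);
a joint limit (`"sum"`) is available as a switch because the
published wording does not decide between them. The best passing
element is the one of greatest span, ties to the 5'-most; when nothing
passes, per-element failure reasons are aggregated and structures whose
helices are interrupted by multiloop junctions additionally carry
`branched_only`.

## Variant design

The mutagenesis strategy perturbs a stem-loop's stability while
controlling for sequence identity:

* **DV** (destabilizing): for each selected pair the 3'-side base is
  substituted to the identity of its 5' partner — X/X never pairs under
  WC+GU. If a rule application would leave a pairable or unchanged base
  (not reachable for valid ACGU pairs, but guarded), a documented
  fallback picks the first of C/A/G/U that cannot pair the 5' base.
* **DVC** (compensated): the 5' partner of each broken pair is mutated
  to the Watson–Crick complement of the DV-mutated base; the pair
  re-forms while both positions now differ from the original sequence —
  structure restored, sequence diverged.
* **SV** (stabilizing): a two-sided internal loop is closed by
  substituting, innermost-out, the 3'-side base to the complement of
  its aligned 5' counterpart. One-sided bulges cannot be closed by
  substitution and are rejected.
* **SVC**: each SV-created pair is reopened by mutating the 5' partner
  to a base unpairable with the SV-mutated base, restoring the original
  loop topology with a diverged sequence.

The published figures show which bases were mutated but not a general
rule; these rules are one concrete deterministic realization (the
mutated side is the 3' one by convention). G·U wobble counts as pairing
for "disruption must abolish pairing"; compensation targets strict WC
pairs. `stabilityDelta` is the variant score minus its parent's score
under the active backend (positive = destabilized), so DV/DVC and
SV/SVC deltas mirror each other exactly on fixtures with unique optima.

Distance and deletion edits operate on a `StopContext`: insertions of
3/6/9 given nucleotides immediately after +9 displace the stem-loop
from the stop codon, and `delete_stem` removes +12..+57 (46 nt); both
remap the offset map, with inserted bases carrying no genomic
coordinate.

## Reporter quantification

Dual-luciferase: per record, background-corrected FLuc over
background-corrected RLuc; readthrough efficiency is 100 × (test mean /
sense-codon-control mean), the sense control (stop mutated to a sense
codon) defining 100%; relative readthrough level rescales efficiencies
so a chosen reference construct is exactly 1. Replicates are averaged
as per-replicate ratios by default, with a ratio-of-sums mode behind a
flag, because the order of averaging is not fixed by the published
description and the two differ under noise. The imaging ratio divides
corrected GFP by corrected mCD8 intensity per unit area and optionally
adjusts the normalizer towards a reference construct's mean mCD8 level;
the printed formula is ambiguous about the orientation of that
adjustment, so both directions are available (`"multiply"` default,
`"divide"`), and the scaling behaviour is asserted as an algebraic
property rather than assumed.

## Synthetic fixtures and what they do (not) show

`plantHairpin()` builds sequences whose maximum-weight structure is
known *provably*, not just empirically: stems use G on the 5' arm and C
on the 3' arm, and every unpaired region (flanks, terminal loop,
bulges) uses A only. Then the only admissible pairs are G:C with every
G 5' of every C, a maximum structure must pair all of them, and the
unique non-crossing perfect matching between two separated runs is the
"rainbow" — exactly the planted helix with its bulges skipped. (An
earlier A/C unpaired alphabet was rejected: C in a flank can pair a
stem G and destroys uniqueness.) Terminal loops shorter than 3 nt are
rejected because the folder could never reproduce them.

`synthGenome()` emulates the screen's inputs: genes with a CDS ending
in a sampled stop triplet and a 3'UTR whose first $W$ nucleotides embed
a qualifying hairpin (stem 16–20 bp, loop 3–10 nt, at most one ≤2 nt
bulge), a sub-span hairpin (span ≤ 34), or unpairable A/C sequence;
both strands are used and a fixed fraction of genes carries a two-exon
(spliced) 3'UTR. The truth table records the expected call and element
coordinates. `synthLuminescence()` generates plate tables whose
per-replicate corrected ratio fluctuates log-normally with a chosen CV
around the configured true ratio, with constant backgrounds.

These fixtures validate coordinate arithmetic, strand handling,
splicing, classification and determinism. They deliberately do **not**
emulate thermodynamic folding: real 3'UTR windows fold under the Turner
energy model, can host competing structures, pseudoknots and G-quadruplexes,
and their hairpins are not guaranteed unique optima. A perfect score on
the synthetic screen therefore demonstrates pipeline correctness, not
predictive accuracy on real genomes — the latter is inherited from the
external folder used in ingest mode.

## Numerical and degenerate-input choices

* Pair tables are symmetric integer vectors; crossing tables are
  rejected when rendered to dot-bracket ("pseudoknot unsupported").
* Gene identifiers are version-stripped and whitespace-truncated (the
  header handling of common folders) before matching and set algebra;
  duplicate ids within a set deduplicate with a warning.
* Output tables sort by gene id with locale-independent (radix)
  ordering, so reruns are byte-identical across platforms.
* Empty inputs are first-class: a gene without a 3'UTR, a window too
  short for the motif context, a missing ingested structure — each is a
  counted, logged skip, never a crash.
* Validation problem sizes (chosen to exercise every code path while
  keeping the suite quick): exhaustive-enumeration folding oracle up to
  n = 18 over hundreds of random sequences, hairpin-enumeration oracle
  on 1000 random nested structures up to 100 nt, and a 200-gene
  synthetic genome for the end-to-end screen.

## Known limitations

* The internal folder maximizes pair weight; it has no stacking,
  dangles, temperature or ensemble notion, and its scores are not
  energies. Published MFE values require the external backend.
* Biotype filtering is exposed (the GFF reader keeps `biotype`) but no
  opinionated isoform filter is applied; the annotation's notion of
  "protein-coding mRNA with a CDS" is taken at face value.
* Selenocysteine recoding, transcript assembly, conservation scoring
  and statistical testing of reporter data are out of scope; the
  reporter module exports tidy tables for standard statistics tools.
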