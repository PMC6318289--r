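---
title: "Quantifying CRISPR editing outcomes from amplicon deep sequencing"
author: "crisprEdits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying CRISPR editing outcomes from amplicon deep sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprEdits)
```

## The problem

After Cas9 introduces a double-strand break at an sgRNA target site,
error-prone non-homologous end joining (NHEJ) repairs it, leaving
insertions and deletions (indels) clustered at the cut. Amplicon deep
sequencing of a PCR product spanning the site reads out the resulting
allele spectrum. Turning millions of reads into an editing efficiency, an
allele table and a per-position match profile requires a chain of small,
exactly specified decisions — which reads count, how alleles are
canonically represented, what qualifies as an NHEJ event — and each
decision changes the reported numbers. This package implements that chain
as a tested, deterministic pipeline, together with the two flanking
analyses that motivate such an experiment: selecting an sgRNA site
conserved between two orthologous coding sequences, and predicting the
truncated translational product an edit produces.

The motivating application is C-terminal truncation of the amyloid
precursor protein (APP): a guide whose blunt cut falls on the codon-659/660
boundary of the 695-residue isoform produces frameshifted products
translated up to residue 659 — losing the last 36 residues, including the
C-terminal YENPTY region and the epitope of C-terminus-specific
antibodies — which is exactly the arithmetic the worked examples below
compute.

## Pipeline model and assumptions

The pipeline consumes single amplicon-spanning reads (paired-end merging is
out of scope) and proceeds:

1. **Collapse.** Reads are counted as exact duplicates; reads containing N
   are dropped (and reported) first. The unit of all later accounting is
   the unique sequence with its count.
2. **Frequency filter.** Groups with count below `minCount` are discarded,
   with strict "less than" semantics: a group whose count equals the
   threshold is retained. The default threshold of 100 reads presumes
   HiSeq-scale depth; it scales naturally as depth/1000 for smaller runs.
   The filter is applied immediately after collapsing, before target
   classification, and the threshold is an exposed parameter.
3. **Target classification.** A read is *target* when the forward primer
   matches within the first `len(primer) + 3` bases (the slack absorbs
   ragged starts) and the reverse complement of the reverse primer matches
   downstream. Hamming matching only; the allowed mismatches per primer
   default to 0. Non-target reads are counted but contribute nothing to
   alleles or profile.
4. **Global alignment.** Each target group is aligned to the wildtype
   amplicon with Needleman–Wunsch/Gotoh affine-gap alignment
   (defaults: match +2, mismatch −3, gap open −6, gap extend −1). A gap of
   length $L$ scores $\mathrm{open} + (L-1)\,\mathrm{extend}$, so one
   contiguous indel is preferred over scattered gaps — matching how NHEJ
   alleles are tabulated. Traceback ties are broken deterministically
   (diagonal, then vertical/deletion, then horizontal/insertion) so the
   same read always yields the same alignment.
5. **Canonical signature.** Gap and mismatch runs become insertion,
   deletion and substitution operations; indels are left-normalized
   (shifted to the smallest reference position producing the same edited
   sequence, e.g. within homopolymers). Coordinates are 0-based
   internally; reports add 1-based columns.
6. **NHEJ call.** An allele is an NHEJ event iff an insertion or deletion
   overlaps the closed window
   $[\mathrm{cut} - w,\ \mathrm{cut} + w]$, default $w = 5$ bases.
   Substitution-only alleles are *never* NHEJ — lone mismatches are
   treated as sequencing or PCR error. Tools that count substitutions
   will report higher efficiencies.
7. **Summary.** Editing efficiency is
   $\mathrm{nhejReads} / \mathrm{targetReads}$ over the filtered
   population (no alternative denominators are offered); the match
   profile counts matches, mismatches and deletions per reference
   position, weighted by read counts. Insertions sit between reference
   positions and contribute no profile column.

### Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `minCount` | 100 | reads | noise floor at HiSeq depth; scale as depth/1000 |
| `nhejWindow` | 5 | bases each side of cut | covers typical SpCas9 NHEJ spectra while excluding distal artifacts |
| primer slack | 3 | bases | ragged read starts |
| `maxMismatches` | 0 | bases per primer | exact primer matching |
| match/mismatch | +2 / −3 | score | transversion-heavy penalty discourages spurious matches |
| gap open/extend | −6 / −1 | score | one contiguous indel beats scattered gaps |

All are exposed; none is inferred from data.

## Guide-site selection

`scanPams()` reports every NGG with 20 nt of protospacer context, on both
strands, with the blunt cut fixed 3 bp 5′ of the PAM (canonical SpCas9).
`mapCutToCodon()` converts a cut to the last complete codon 5′ of it,
`upstreamAa + \lfloor(\mathrm{cut} - \mathrm{cdsStart})/3\rfloor`, in
full-protein numbering — consistent with products "translated up to"
that residue. `conservedSites()` anchors one orthologue to the other by
global alignment and calls a site conserved when an NGG PAM sits at the
homologous position in both sequences; the protospacers may differ and
their Hamming distance is reported with no threshold imposed (the modelled
APP659 site differs by two nucleotides between mouse and human yet is
conserved in this sense). No on-target activity scoring or genome-wide
off-target search is attempted; candidate ranking is left to the user.

## Translational-product prediction

`applySignature()` reconstructs the edited allele; `translateCds()`
translates it under the standard genetic code, stopping at the first stop
codon (codons containing N give X; a trailing partial codon is ignored).
The last retained wildtype residue is defined by the *longest common
prefix* of the edited and wildtype proteins — not by nucleotide
coordinates — which is robust to in-frame indels. Products are named
`<label>-<lastWtResidue>[-<appended>]`, e.g. `APP-659-GG` for the product
that retains residues 1–659 and appends Gly-Gly before its new stop.
When no stop occurs within the supplied context the product is flagged
`stopFound = FALSE` and the appended residues are reported to the context
end; genomic edits can legitimately terminate beyond the sequenced
amplicon, so this is a reportable state rather than an error. Epitope
retention counts only wildtype residues: appended novel residues never
contribute.

```{r products}
mod <- syntheticAppModel("human")
fs <- variantSignature(data.frame(kind = "deletion", refPos = mod$cutSite,
                                  length = 1L, alt = ""))
predictProduct(mod$context, fs, mod$map, label = "APP")
```

## The synthetic APP model

Real APP coding sequences cannot be assumed present on an analysis
machine, so the packaged worked examples run on `syntheticAppModel()`: a
deterministic, code-generated coding context that is *not* the real APP
CDS but carries the documented structure of the APP695 editing site — a
695-codon protein model whose TGG-PAM guide cuts on the codon-659/660
boundary, mouse/human protospacers differing by exactly two synonymous
nucleotides, a downstream frame in which the most common frameshift
yields the `-659-GG` product, and a last-20-residue antibody epitope
(676–695). Everything computed on it (cut codon 659, protospacer distance
2, truncation 36) is genuine sequence arithmetic on the model, not a
stored constant; the same functions run unchanged on real CDS FASTA
files.

## What the simulator emulates — and what it does not

`simulateFastq()` draws reads from a mixture: with probability
`editingRate` an edited allele (uniform over `nAlleles` distinct
single-indel alleles), otherwise the reference; then uniform per-base
substitution noise at `errorRate`; constant Q30 qualities. Allele indels
have truncated-geometric lengths (support 1–20, default $p = 0.5$, mean
≈ 2) and starts uniform within `maxOffset` (default 5) of the cut.
Placement is defined on the **canonical** signature: a draw whose
left-normalized start escapes the placement interval is rejected, so the
generated spectrum and the NHEJ-window classification agree by
construction.

Defaults (depth 20,000; error 0.002/base; five alleles, 70% deletions)
describe one HiSeq-scale amplicon sample. The spectrum is a deliberately
simple stand-in for real NHEJ outcomes: no indel sequencing errors, no
PCR chimeras or jackpot duplicates, no quality-score structure, no
microhomology-biased deletion spectrum, and single-indel alleles only.
Passing the recovery tests therefore shows the pipeline's accounting is
correct under clean mixture sampling — not that real libraries are free
of the artifacts the simulator omits.

```{r recovery}
cfg <- simulationConfig(mod$context, mod$cutSite, editingRate = 0.4,
                        depth = 20000L, seed = 7L)
fq <- tempfile(fileext = ".fastq")
truth <- simulateFastq(cfg, fq)
kept <- filterLowFrequency(collapseReads(readFastq(fq)), 20L)
summary <- quantifyEdits(kept, mod$assay, totalReads = cfg@depth)
summary
c(realized = truth$realizedEditFraction,
  estimated = editingEfficiency(summary))
```

## Numerical and design choices

- **Tie-breaking and determinism.** The alignment traceback order and the
  count-descending / lexicographic allele ordering make every report
  byte-reproducible; `summary.json` carries parameters and version but no
  timestamp (the run manifest does).
- **Left-normalization** is the canonical coordinate convention; an indel
  only shifts across exact-match columns, so the edited sequence and
  alignment score are invariant under the shift.
- **Degenerate inputs.** Zero target reads yields an NA efficiency with a
  warning, not an error; empty FASTQ files are valid and empty; scoring
  configurations must satisfy `match > mismatch` and
  `gapOpen <= gapExtend <= 0`.
- **Filter timing** (the one genuinely open ordering question) is fixed
  as: collapse, then frequency filter, then classification — so the
  filter threshold has the same meaning for target and non-target reads —
  and the threshold is a parameter.
- **Problem sizes.** The test suite exercises alignments exhaustively up
  to length 6 (full enumeration of all global alignments), against an
  independent reference implementation up to length 12 (500 pairs),
  simulation recovery at depth 20,000 across editing rates 0.1–0.9, and
  4,000 seeded draws for the indel-length distribution; these sizes give
  stable statistics while keeping the default suite fast.

## Known limitations

- Substitution-only alleles are never called NHEJ; point-mutagenic
  repair outcomes are invisible to the efficiency estimate.
- Allele identity is the exact post-filter sequence; sequencing errors on
  an edited allele create distinct low-count alleles that the frequency
  filter must remove, so very low depth with high error rates will
  fragment the spectrum.
- Paired-end merging, UMIs, quality-aware error models, HDR/knock-in
  classification and batch orchestration are out of scope.
- The O(nm) dynamic program is intended for amplicon-scale references
  (hundreds of bases to a few kilobases), not whole genes.
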