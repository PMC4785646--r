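---
title: "Genomic ambiguity of tRNA-derived fragments: methods and design"
author: "tRFspace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic ambiguity of tRNA-derived fragments: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tRFspace)
```

## The problem

Small RNA sequencing of human samples yields large numbers of reads that
match mature transfer RNAs. It is tempting to map such reads against the
tRNA transcriptome alone and call every hit a tRNA-derived fragment
(tRF). That shortcut is unsafe, for four genomic reasons:

1. **Truncated tRNA copies.** The nuclear genome carries hundreds of
   short, incomplete tRNA-like segments (RepeatMasker class `tRNA`)
   outside the annotated tRNA loci. Reads arising from these segments
   match mature tRNAs yet need not be tRNAs.
2. **Spliced junctions.** Many tRNA genes carry an intron; reads that
   span the exon–exon junction of the mature sequence exist nowhere in
   the genome as a contiguous string, which is what makes them
   tRNA-specific — but one can only know this by scanning the whole
   genome.
3. **CCA-ending decoys.** Every mature tRNA ends in a non-templated
   `CCA` added enzymatically. The resulting CCA-ending 3' strings can
   nevertheless occur verbatim at many genomic locations unrelated to
   tRNAs, so candidate 3'-tRFs are particularly prone to false
   attribution.
4. **tRNA-lookalikes.** The genome contains loci of mature-tRNA length
   whose sequences resemble real tRNA genes closely enough to share
   many exact k-mers with them, creating cross-talk in any
   transcriptome-only mapping.

This package quantifies all four mechanisms for a given genome and tRNA
annotation, and classifies candidate fragment reads accordingly. We call
the merged set of annotated tRNA gene intervals **tRNA space**. A
sequence is **exclusive** when every exact genomic copy of it lies fully
inside tRNA space (zero copies also qualifies: junction- and
CCA-spanning sequences exist only in the mature transcriptome);
otherwise it is **ambiguous**.

## Procedure

1. **Mature tRNA construction.** Each annotated locus (BED12 + 3
   auxiliary columns: amino acid, anticodon, anticodon genomic start)
   is extracted in transcript orientation (minus-strand loci
   reverse-complemented), intron blocks are removed, and `CCA` is
   appended. A per-base coordinate map back to the genome is retained;
   the three CCA bases are marked non-templated. CCA is appended
   unconditionally, to nuclear and mitochondrial tRNAs alike, because
   human tRNA genes do not encode it.
2. **k-mer exclusivity.** All distinct k-mers of the mature set
   (including windows across junctions and into the CCA) are
   enumerated, then counted across the genome by exact multi-pattern
   matching (Biostrings `PDict`/`matchPDict`). Per k-mer we report
   occurrences inside vs. outside tRNA space and the share of
   exclusive k-mers, typically for k = 14, 15, 16.
3. **Side analyses.** The CCA-terminal report counts outside copies of
   each mature tRNA's 3'-terminal k-mer (default k = 16); the
   cross-talk report counts exact k-mers shared with a foreign set
   (e.g. lookalike loci); the repeat filter counts RepeatMasker `tRNA`
   segments of length ≤ 50 nt outside tRNA space.
4. **Read classification.** Reads are dereplicated, length-filtered
   (default minimum 16 nt — 14-mers, and to a lesser degree 15-mers, are
   too common genome-wide to be informative), placed on mature tRNAs by
   exact substring matching, typed by their endpoints, and labelled
   `EXCLUSIVE`/`AMBIGUOUS` from a whole-genome occurrence count. A
   genome is mandatory for labelling: transcriptome-only labelling is
   the practice the package exists to correct.

## Counting conventions

Several conventions are not dictated by the biology and had to be fixed;
they are applied uniformly to every reported count:

- **Both strands.** A genomic window matches a k-mer when it equals the
  k-mer or its reverse complement, because a sequenced read can derive
  from either strand's transcript. A palindromic k-mer matching one
  window both ways counts once.
- **Containment.** An occurrence is *inside* tRNA space only when its
  interval is fully contained in a tRNA-space interval. A copy hanging
  off a locus boundary is not tRNA-templated end to end and counts as
  outside. (The synthetic fixtures occasionally exhibit this naturally:
  a `TGG` immediately flanking a minus-strand gene extends the
  CCA-terminal 16-mer past the locus and creates a legitimate outside
  copy.)
- **Coordinates.** Internally everything is 1-based closed, the native
  convention of `IRanges`/`GenomicRanges`; BED input/output converts at
  the boundary, and human-readable reports print 1-based inclusive
  positions.
- **Percentages** are rounded half away from zero to one decimal
  (`base::round` rounds half to even, which disagrees at values such as
  12.25).
- **Ambiguous bases.** Loci whose sequence contains `N` are kept but
  flagged; windows containing `N` are excluded from enumeration and
  queries containing `N` are rejected — matching is exact over
  `{A,C,G,T}`.

## Fragment typing

Placements are typed by their mature coordinates: start at position 1
gives a 5' fragment, an end at the final (CCA-inclusive) position gives
a 3' fragment, anything else is an internal fragment (i-tRF). A 5'
fragment whose end (or a 3' fragment whose start) falls within a window
of ± `halvesWindow` nucleotides around the anticodon is called a half.
The field's nomenclature does not fix the half boundary numerically, so
the window half-width is a parameter (default 2 nt), as is the slack
allowed for 3' calls (default 0: the fragment must reach the CCA end,
since candidate 3'-tRFs are defined by their CCA terminus). Matching is
exact with zero mismatches — mismatch tolerance is precisely what lets
non-tRNA reads masquerade as tRFs, so it is not offered.

Profiles are reported per tRNA with **one row per distinct fragment
sequence**. Counts are never merged across distinct sequences and no
"dominant" fragment is designated: fragments from the same template
differing by single nucleotides have uncorrelated abundances across
samples, so aggregation destroys exactly the signal of interest.
Multi-mapping fragments appear in every matching profile, flagged.

## The synthetic fixture generator

`generateGenome()` plants, on an i.i.d. background of configurable GC
content, all four ambiguity mechanisms: tRNA genes (72-nt mature body,
anticodon at mature positions 34–36; intronic genes carry a 10–20 nt
intron immediately 3' of the anticodon, the canonical position in
eukaryotic tRNA genes), truncated copies of the genes (20–50 nt, the
RepeatMasker-segment regime), lookalikes (gene bodies with 2–10 point
substitutions, so k-mer sharing is partial and the cross-talk report is
exercised non-trivially), and verbatim CCA-ending terminal 16-mers.
Partial copies are truncations of the *genomic* gene sequence (introns
included), so junction-spanning mature sequence never gains an outside
copy by construction; decoys are verbatim so their ambiguity is certain
under exact matching. tRNA genes are planted on random strands, all
decoy features in mature orientation on the forward strand.

The default conditions — a 100 kb genome at GC 0.41 with 6 tRNAs (2
intronic), 10 partial copies, 3 lookalikes and 3 CCA decoys — are the
package's reference study scale: large enough that every feature class
is represented several times over and accidental 16-mer collisions are
rare, small enough that the whole analysis re-runs in seconds. Ground
truth is never assumed from the construction: each simulated read's
expected label is recomputed from the emitted genome with the naive
brute-force scan at generation time, so accidental background copies
are reflected in the truth rather than breaking it.

What the generator does **not** emulate: real tRNA sequence composition
and secondary structure, covariance among loci, repeat-family
evolution, sequencing errors, or non-uniform fragment-length
distributions. Passing tests therefore demonstrate the correctness of
the counting and classification machinery under exact matching — not
performance on real libraries, where error rates and modification-driven
misincorporations add noise upstream of this package's scope.

## Oracles and verification

Every exact-matching operation is verified against
`bruteForceOccurrences()`, a deliberately naive pure-base-R scan
(substring windows compared character-for-character on both strands)
that shares no code with the Biostrings-based implementation. The test
suite checks agreement over hundreds of random genome/query pairs
(genomes up to a few kilobases, k from 8 to 20), strand symmetry
(reverse-complementing the genome leaves all counts unchanged),
space-nesting (enlarging tRNA space never increases an outside count),
and non-decreasing exclusive fractions from k = 14 to 16.

## Limitations

- Only mature-tRNA-derived fragments are modelled: no 5' leader / 3'
  trailer (pre-tRNA) fragments, no histidine G−1 addition, no
  modification-aware handling.
- Exact matching means a single sequencing error unplaces a read; the
  package reports such reads as unplaced rather than guessing.
- Full-genome replication at human scale is supported by the same code
  paths but takes hours and multi-gigabyte inputs; the bundled tests
  run the identical machinery at the 100 kb fixture scale described
  above.
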