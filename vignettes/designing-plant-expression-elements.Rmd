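---
title: "Designing and characterizing synthetic plant expression elements"
author: "plantElements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and characterizing synthetic plant expression elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plantElements)
```

# Scope and model

Transgene expression cassettes in crops need promoters (with 5' UTR
leaders), introns and 3' UTR terminators that behave predictably and share
as little literal sequence as possible with the host genome and with each
other. This package implements a complete desk-side pipeline for that
problem:

1. extract anchored training windows from co-expressed native genes;
2. find position-specific word enrichment between a foreground and a
   background training set, and summarize per-offset base composition as a
   positional profile;
3. generate candidate elements by sampling from the profile under hard
   structural constraints, and validate any sequence against those
   constraints;
4. screen candidates for continuous identity runs against source genomes
   and for unintended open reading frames;
5. build transversion knockouts of annotated motifs;
6. quantify transcript behavior from spliced alignments: splice-junction
   usage, adapter-anchored transcription start site (TSS) and
   polyadenylation site distributions, and qPCR read-through by the
   2^-ddCt method.

A read simulator with a recorded truth table makes step 6 testable without
any sequencing data.

# Training windows

Windows are anchored, strand-resolved, and length-aligned:

* promoters: 1,000 bp strictly upstream of the TSS plus 50 bp starting at
  and including the TSS (1,050 nt; anchor at 0-based offset 1,000);
* introns: the intron plus 5 bp of exon on each side (variable length;
  donor at offset = flank);
* terminators: 400 bp strictly upstream of the polyadenylation site plus
  200 bp starting at and including it (600 nt; anchor at offset 400).

The "from -1000 to +50" phrasing of window extents is ambiguous about
inclusivity; we fix the convention that a window has exactly
`upstream + downstream` bases with the anchor base the first base of the
downstream part. This keeps the anchor at a single well-defined column for
positional statistics. Windows that would cross a chromosome boundary are
skipped (with a warning) rather than truncated so that every record of an
anchored set has the same length; truncation would shear the positional
alignment that the enrichment statistics depend on. Whether a window
crosses a neighboring gene is not checked: the native training procedure
gives no such filter, and applying one silently would change set sizes.

Coordinates are 1-based inclusive everywhere a file is read or written
(GFF3/SAM convention). Feature intervals inside elements are stored as
`IRanges` (1-based inclusive) rather than 0-based half-open offsets; this
matches the rest of the Bioconductor stack the package is built on, and
all adjacency contracts are stated in base counts ("30 bases strictly
between the TATA box and the TSS") so they are representation-independent.
Input genomes may contain N but any other ambiguity code is rejected: a
training window with an R or Y in it would poison word counts invisibly.

# Positional enrichment

Word enrichment follows a position-sensitive word-counting design: the
window is tiled into half-open bins of `binWidth` bp (default 25) and each
sequence contributes at most once to a (word, bin) pair. Presence/absence
counting (rather than occurrence counting) keeps a single repetitive
window from dominating a bin. Default word length is k = 6, the typical
scale of core promoter elements (TATA box, Inr). Enrichment against the
background is a one-sided Fisher test (hypergeometric tail) with
Benjamini-Hochberg control at alpha = 0.05, and significant words are
greedily merged into motifs: seed with the most significant word, absorb
same-bin words within Hamming distance 1, consensus = per-position IUPAC
union. All four knobs (k, binWidth, the test's alpha, the merge radius)
are exposed; the defaults are design choices of this package, not values
inherited from any published tool, and the background set is an explicit
input — either windows from a random gene sample or the provided seeded
dinucleotide shuffle.

The positional profile is a 4 x L matrix of per-offset base frequencies
with a pseudocount (default 1): `(count + pc) / (n_eff + 4 pc)`, N bases
excluded. Variable-length intron sets are prefix-aligned at the donor
before profiling.

# Element design

The generative procedure is deliberately simple and fully documented:
sample every position independently from the positional profile (aligned
so the element's anchor matches the profile's anchor), stamp enriched
motifs at bin-consistent offsets, then overwrite the structural core and
repair residual violations locally (resampling single bases from the
profile, up to 10 sweeps) before rejecting the attempt; a fresh attempt is
drawn up to 1,000 times, after which the unsatisfiable constraint is named
in the error. Designs are byte-deterministic given (inputs, seed), and the
provenance (profile fingerprint, stamped motifs, constraint fingerprint,
seed, attempt count) travels with the element.

Class-specific structural cores, with defaults and why:

* **Promoter** (500 bp): `TATAAA` TATA box, exactly 30 bp between the box
  and the predicted TSS (the canonical plant TATA-to-initiation distance),
  a pyrimidine-purine initiator with the TSS base fixed to A (plant
  Inr-like consensus; the exact native consensus is not fixed by
  published material, so the pattern is a config-exposed default), and a
  50 bp leader containing no ATG at or downstream of the TSS so the first
  start codon a scanning ribosome meets belongs to the transgene.
* **Intron** (300 bp + 5 bp exonic flanks): canonical `GT`/`AG` at the
  intron boundaries; no donor-like word (`GTAAG`) and no acceptor-like
  context (`CAG` after a >= 6 nt pyrimidine run) strictly between the
  intended sites, suppressing cryptic alternative splicing; at least one
  enhancement (IME) motif placed in the promoter-proximal part of the
  intron (window 10-150 bp from the donor). The shipped IME motif
  `TTNGATYTG` is a placeholder: published IME work defines such motifs
  but the exact sequences used for any given element set are not public,
  so real projects must supply their own via the config.
* **Terminator** (300 bp): exactly two cleavage sites (multiple
  polyadenylation sites are the norm in plant 3' UTRs), each an A
  preceded by a pyrimidine (YA dinucleotide) with an `AATAAA`
  near-upstream element ending a seeded 10-30 bp upstream, and a run of
  >= 8 T's ending immediately before the distal site (T-rich tracts mark
  plant cleavage sites). Site separation defaults to 60 bp, matching the
  two-peak spacing observed for this element class.

`validateElement()` re-checks every constraint independently and lists all
violations with intervals; it never throws on content, so it can score
arbitrary sequences (including knockout variants, which are expected to
fail). The designer always round-trips through the validator before
returning.

# Diversity and ORF screening

Novelty is screened with the summary statistic that the element class is
evaluated by: the longest run of continuous sequence identity between the
candidate and any reference sequence or its reverse complement, computed
exactly (rolling-row dynamic programming in C++; leftmost witness on
ties). The default ceiling is 22 bp, the identity-run scale reported for
elements of this kind; it is a configurable default, not a claim that 22
is special. Full local-alignment statistics (BLAST scores/E-values) are
out of scope — they depend on full genome databases — but a
Smith-Waterman score (match +1, mismatch -1, gap -2) is reported for
context without a threshold. `scanOrfs()` reports all ATG-initiated
frames to the first in-frame stop on both strands, for screening
unintended coding content.

# Knockout variants

`transversionMap()` fixes the substitution A<->C, G<->T: every change is a
purine<->pyrimidine transversion, the map is its own inverse, and AT-rich
motifs map to GC-rich sequence (`TATAAA` -> `GCGCCC`), which is exactly
how TATA boxes are ablated. The alternative transversion pairing (A<->T)
would preserve AT content and is deliberately not offered.
`makeVariant()` rewrites exactly the named feature intervals and logs the
edits; Hamming distance to the original equals the summed interval
lengths.

# Transcript metrics

Alignments are consumed as plain-text SAM (converted through Rsamtools;
CIGAR M/=/X and D consume reference within a block, N opens a junction
gap, I/S/H do not shift blocks). Unique mapping means MAPQ >= 1 (configurable)
and not secondary/supplementary; multiple SAM inputs are pooled. Adapter
provenance comes from an optional tag (default `XA`: `5`, `3` or `53`),
with escape hatches for pre-filtered pipelines.

Splice-site usage follows the published accounting exactly:

* donor = first intronic base, acceptor = last intronic base;
* at the intended 5' position, reads are partitioned into expected
  junction, unspliced (a single block covering both boundary bases
  contiguously; reads ending exactly at the boundary are uninformative
  and excluded), and unexpected junctions sharing the donor;
* percentages are 100 x count over the sum of the three categories,
  rounded half-up to one decimal (unrounded values retained internally);
  the 3' side mirrors this with the acceptor;
* junctions touching neither intended position are reported but enter no
  denominator; a zero denominator reports NA, never 0.

The minimum read support for reporting a junction defaults to 1 (the
publication threshold behind the worked-example table is unstated) and is
configurable. One printed cell of that table (5.7% for the (723,814)
junction) is inconsistent with the convention that reproduces every other
cell (1036/20759 = 5.0%); the package follows the consistent convention.

TSS and polyA distributions use only adapter-carrying reads (first aligned
base of the first block, last aligned base of the last block), with
percentages to two decimals and the modal site (smallest coordinate on
ties) as the dominant site. `windowFraction()` reports the maximal read
mass in any contiguous window (default 10 bp), the statistic behind
"90% of initiation within a 10 bp window". Read-through is
100 x 2^-(dCt(READTHROUGH) - dCt(GUS)) per sample with dCt against the
mean of the normalizers; the normalizer terms cancel within a sample but
the normalized relative expressions are kept for cross-sample comparison.

# The read simulator

`simulateReads()` draws, per read, a TSS, a splice outcome per intended
intron (expected / unspliced / named alternative junction), and a polyA
site, then emits an error-free exact-match alignment of the transcript
anchored at its 5' end (5'-adapter reads) or 3' end (3'-adapter reads),
plus FASTQ and a truth table. The idealizations are deliberate: RLM-RACE
captures true 5' ends and oligo-dT priming true 3' ends, and the
quantities measured downstream (junction coordinates, end positions) would
only be blurred, not changed, by a sequencing-error model. PCR
duplication, adapter mis-ligation and mapping ambiguity are not modeled.
Consequently, passing tests demonstrate the correctness of the accounting
and the estimators, not robustness to alignment artifacts in real
libraries.

`makeToyGenome()` provides the matching upstream fixture: non-overlapping
multi-exon genes on alternating strands with canonical GT..AG introns,
optional planted positional motifs at stated offsets and penetrance, and
enough intergenic room that no training window is skipped.

# Numerical choices

* Report rounding is half away from zero (half-up) at 1 decimal for usage
  percentages and 2 decimals for site distributions, matching the style of
  the published tables; base R's round-half-even would flip boundary
  cells.
* Fisher p-values come from `phyper`; the test suite checks them against
  direct tail enumeration from binomial coefficients over every 2x2 table
  with both group sizes up to 60.
* Ties: motif merging and enrichment ordering break ties lexicographically
  by (word, bin start); identity-run witnesses are leftmost in query then
  reference; dominant sites and best windows are leftmost.
* Degenerate inputs: empty training sets, zero informative reads, missing
  qPCR targets and malformed SAM lines are hard errors; zero-denominator
  percentages are NA.

# Problem sizes used by the test-suite

The suite verifies the stochastic properties at sizes a laptop handles in
seconds-to-minutes, chosen as the package's own test design: simulator
recovery at 10,000 reads against 3-binomial-SE bands; oracle equivalence
on 100 random query/reference pairs (200 nt vs 5 kb), 1,000 simulated
reads, all 2x2 tables with group sizes <= 60, and ten random 1 kb ORF
scans; designer properties over 100 seeds per element class. The
published junction-count table is reproduced cell-by-cell from its printed
counts, which is exact and instantaneous.

# Known limitations

* The generative model is positional-profile sampling with motif
  stamping; it recapitulates positional composition and hard constraints
  but does not learn higher-order dependencies, and it makes no claim to
  reproduce any proprietary design procedure or any specific published
  element sequence.
* Expression level and tissue specificity of designs are not predicted;
  in-planta measurements are outside what a sequence pipeline can state.
* The diversity screen's identity-run statistic is not a BLAST E-value;
  elements passing the 22 bp ceiling can still share diffuse similarity
  with a genome.
* Expression-based clustering to define co-expressed training sets, and
  EST-based annotation adjustment, are upstream of this package: gene-ID
  lists are accepted as given.
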