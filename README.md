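# plantElements

Design and molecular characterization of synthetic plant expression
elements: promoters with 5′ UTR leaders, introns, and 3′ UTR terminators.

Crop biotechnology cassettes need regulatory elements that drive
predictable transgene expression while sharing as little literal sequence
as possible with the host genome and with each other (sequence redundancy
destabilizes trait stacks). `plantElements` is for scientists building or
evaluating such elements. It covers the whole desk-side workflow:

* **Training windows** — strand-aware extraction of anchored windows from
  a genome + GFF3 annotation: promoters (TSS −1000/+50, 1,050 nt),
  introns (±5 bp exonic flanks), terminators (polyA −400/+200, 600 nt).
* **Positional motif enrichment** — per-bin k-mer presence counts
  (default k = 6, 25 bp bins), one-sided Fisher (hypergeometric tail)
  foreground-vs-background tests with Benjamini–Hochberg control,
  Hamming-1 word merging into IUPAC consensus motifs, and 4 × L
  positional nucleotide profiles.
* **Element design** — profile sampling + motif stamping under hard
  constraints, with a validator that reports every violation:
  promoters with a TATA box exactly 30 bp upstream of a
  pyrimidine–purine initiator and an ATG-free leader; introns with
  canonical `GT..AG` sites, clean interiors (no donor-like `GTAAG`, no
  pyrimidine-tract `CAG`) and an intron-mediated-enhancement motif;
  terminators with two YA cleavage sites, `AATAAA` near-upstream
  elements 10–30 bp upstream and a T-rich tract at the distal site.
* **Screening** — exact longest shared identity run against reference
  genomes (strand-aware, default ceiling 22 bp) and 6-frame ORF scans.
* **Knockout variants** — transversion rewriting (A↔C, G↔T; an
  involution; `TATAAA` → `GCGCCC`) of named feature intervals.
* **Transcript characterization** — from spliced SAM alignments:
  splice-junction usage accounting (expected / unspliced / unexpected per
  intended site, with the published denominator conventions),
  adapter-anchored TSS and polyadenylation-site distributions, and qPCR
  read-through by `100·2^−(ΔCt(RT) − ΔCt(GUS))`.
* **Read simulation** — adapter-tagged RACE/amplicon reads with known
  TSS, splice-outcome and polyA distributions, emitted as SAM/FASTQ with
  a truth table, so everything above is testable offline.

The central statistic, splice-site usage at an intended junction
(p5, p3), is

```
%expected(5′) = 100 · n_expected / (n_expected + n_unspliced(5′) + Σ n_alt-donor)
```

with donor = first intronic base, acceptor = last intronic base,
unspliced = contiguous coverage of the boundary, and the mirrored
definition at the 3′ side; percentages are rounded half-up to one
decimal.

## Worked example

```r
library(plantElements)

## toy genome with a TATAAA planted 30 bp upstream of 80% of TSSs
toy <- makeToyGenome(seed = 1, nGenes = 20, chromLength = 60000,
                     plantMotif = list(pattern = "TATAAA", offset = -30,
                                       penetrance = 0.8))
ts <- extractPromoterWindows(toy$genome, toy$models, toy$geneIds)
#> TrainingSet anchor=TSS (-1000/+50), 20 records

## enrichment against a dinucleotide-shuffled background
bg  <- shuffleTrainingSet(ts, seed = 2)
enr <- scoreEnrichment(countPositionalWords(ts), countPositionalWords(bg))
motifs <- mergeWordsToMotifs(enr)
motifs[1, c("consensus", "bin_start", "bin_end", "q_value")]
#>   consensus bin_start bin_end      q_value
#> 1    TATAAA       950     975 3.233076e-05
```

The planted word is recovered in the bin covering window offset 970
(30 bp upstream of the TSS anchor at offset 1000). Designing from the
profile and screening against the source genome:

```r
el <- designPromoter(buildPositionalProfile(ts), motifs = motifs, seed = 7)
#> DesignedElement GSP_s7 [PROMOTER], 500 bp, 3 features
screenDiversity(el, toy$genome)[, c("max_run_length", "passed")]
#>   max_run_length passed
#> 1             13   TRUE
```

The design's longest identity run against its own training genome is
13 bp, under the 22 bp ceiling. Characterizing simulated reads from a
cassette with one intended intron (511, 814):

```r
cass <- cassetteModel("cas1", 1400, intendedTss = 481,
                      intendedJunctions = data.frame(p5 = 511, p3 = 814),
                      intendedPolyaSites = c(1126, 1186))
params <- simulationParams(cass, tssDist = c(`481` = 0.9, `483` = 0.1),
  spliceOutcomes = list(c(EXPECTED = 0.93, UNSPLICED = 0.03,
                          `ALT:511-790` = 0.04)),
  polyaDist = c(`1126` = 0.6, `1186` = 0.4),
  nReads = 10000, readLength = 1500, seed = 99)
sam <- tempfile(fileext = ".sam")
simulateReads(params, sam)
reads <- parseAlignments(sam, cass)
spliceUsage(reads, cass)
#>    p5  p3 expected_count unspliced5_count unspliced3_count  den5  den3
#> 1 511 814           9326              283              674 10000 10000
#>   pct_expected_5 pct_unspliced_5 pct_expected_3 pct_unspliced_3
#> 1           93.3             2.8           93.3             6.7
windowFraction(tssDistribution(reads))
#> $window_start  [1] 481
#> $fraction_pct  [1] 100
```

93.3% expected splicing at both sites recovers the simulated 93% rate
(the alternative junction's retained 3′ segment feeds the unspliced-at-3′
category, as it would for a real aligner), and all transcription
initiation falls in one 10 bp window at the intended TSS.

A command-line shell over the same functions ships in
`inst/scripts/plant-elements.R` (subcommands `extract`, `motifs`,
`design`, `screen`, `variant`, `simulate`, `characterize`,
`readthrough`; see `--help`).

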