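# Fixtures built in code at test time; nothing is read from disk except
# files the tests themselves write to tempdir().

# A 3,000 nt chromosome with one plus- and one minus-strand two-exon gene
# placed so that all window extractions fit. Sequence is seeded for
# reproducible coordinates.
tinyGenome <- function(seed = 42) {
  set.seed(seed)
  chrom <- randomDna(3000)
  genome <- Biostrings::DNAStringSet(chrom)
  names(genome) <- "chr1"
  genome
}

# Gene models matching the worked coordinate examples: a plus-strand gene
# with TSS 1500 and a minus-strand gene with TSS 1500 are built on demand.
tinyModels <- function(plusTss = 1500L, minusTss = 1500L, chromLen = 3000L) {
  # plus gene: exon1 1500..1700, intron 1701..1900, exon2 1901..2100
  # minus gene: transcription right-to-left starting at minusTss
  genes <- data.frame(
    gene_id = c("gplus", "gminus"),
    chrom = "chr1", strand = c("+", "-"),
    tss = c(plusTss, minusTss),
    polya_site = c(2100L, 900L),
    stringsAsFactors = FALSE)
  exons <- list(
    gplus = IRanges::IRanges(c(plusTss, 1901L), c(1700L, 2100L)),
    gminus = IRanges::IRanges(c(1301L, 900L), c(minusTss, 1200L)))
  geneModels(genes, exons, seqlengths = c(chr1 = chromLen))
}

# Standard test cassette: promoter/leader to 510, one intended intron
# 511..814, CDS, 3' UTR with two intended polyA sites.
testCassette <- function() {
  cassetteModel("cas1", 1400L, intendedTss = 481L,
                intendedJunctions = data.frame(p5 = 511L, p3 = 814L),
                intendedPolyaSites = c(1126L, 1186L))
}

simulateTestReads <- function(nReads, seed,
                              outcomes = c(EXPECTED = 0.93, UNSPLICED = 0.03,
                                           `ALT:511-790` = 0.04),
                              tssDist = c(`481` = 0.9, `483` = 0.1),
                              polyaDist = c(`1126` = 0.6, `1186` = 0.4),
                              readLength = 1500L,
                              frac5 = 0.5, frac3 = 0.5) {
  cass <- testCassette()
  params <- simulationParams(cass, tssDist = tssDist,
                             spliceOutcomes = list(outcomes),
                             polyaDist = polyaDist, nReads = nReads,
                             readLength = readLength,
                             fraction5prime = frac5,
                             fraction3prime = frac3, seed = seed)
  sam <- tempfile(fileext = ".sam")
  sim <- simulateReads(params, sam)
  list(cassette = cass, sam = sam, truth = sim$truth,
       reads = parseAlignments(sam, cass))
}

# write a SAM file from raw alignment rows for parser tests
writeTestSam <- function(path, rows, refName = "cas1", refLen = 1400L) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", refName, refLen))
  writeLines(c(hdr, rows), path)
  path
}

samRow <- function(qname, pos, cigar, flag = 0L, mapq = 60L, tag = NULL,
                   refName = "cas1", seqLen = NULL) {
  if (is.null(seqLen)) {
    # reference-consuming M ops only is enough for these fixtures
    ops <- gregexpr("\\d+[MIS]", cigar)[[1]]
    lens <- as.integer(gsub("[MIS]", "",
                            regmatches(cigar, gregexpr("\\d+[MIS]", cigar))[[1]]))
    seqLen <- sum(lens)
  }
  fields <- c(qname, flag, refName, pos, mapq, cigar, "*", 0, 0,
              strrep("A", seqLen), strrep("I", seqLen))
  if (!is.null(tag)) fields <- c(fields, tag)
  paste(fields, collapse = "\t")
}
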