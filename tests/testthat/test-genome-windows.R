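test_that("promoter windows have the documented coordinates on both strands", {
  genome <- tinyGenome()
  models <- tinyModels()
  ts <- extractPromoterWindows(genome, models, c("gplus", "gminus"))
  r <- as.data.frame(trainingRecords(ts))
  expect_equal(length(ts), 2L)
  expect_true(all(BiocGenerics::width(trainingSequences(ts)) == 1050L))
  # plus strand, tss = 1500: genomic 500..1549
  expect_equal(r$gstart[r$gene_id == "gplus"], 500L)
  expect_equal(r$gend[r$gene_id == "gplus"], 1549L)
  expect_equal(r$anchor_offset[1], 1000L)
  # minus strand, tss = 1500: reverse complement of genomic 1451..2500
  expect_equal(r$gstart[r$gene_id == "gminus"], 1451L)
  expect_equal(r$gend[r$gene_id == "gminus"], 2500L)
  expected <- rcomp(as.character(
    Biostrings::subseq(genome[["chr1"]], 1451, 2500)))
  expect_equal(as.character(trainingSequences(ts)[["gminus"]]), expected)
  # the anchor offset maps back to the TSS on both strands
  expect_equal(substr(as.character(trainingSequences(ts)[["gplus"]]),
                      1001, 1001),
               substr(as.character(genome[["chr1"]]), 1500, 1500))
})

test_that("out-of-bounds promoter windows are skipped with a warning", {
  genome <- tinyGenome()
  models <- tinyModels(plusTss = 800L)   # only 799 nt upstream available
  expect_warning(ts <- extractPromoterWindows(genome, models, "gplus"),
                 "outside chromosome")
  expect_equal(length(ts), 0L)
})

test_that("unknown gene ids and non-N ambiguity codes are hard errors", {
  genome <- tinyGenome()
  models <- tinyModels()
  expect_error(extractPromoterWindows(genome, models, "nope"),
               "unknown gene_id")
  dirty <- Biostrings::DNAStringSet("ACGTRYACGT")
  names(dirty) <- "chr1"
  expect_error(extractPromoterWindows(dirty, models, "gplus"),
               "ambiguity codes")
})

test_that("terminator windows are 600 nt with the polyA site at offset 400", {
  genome <- tinyGenome()
  models <- tinyModels()
  ts <- extractTerminatorWindows(genome, models, c("gplus", "gminus"))
  r <- as.data.frame(trainingRecords(ts))
  expect_true(all(BiocGenerics::width(trainingSequences(ts)) == 600L))
  expect_true(all(r$anchor_offset == 400L))
  # plus strand polya 2100: genomic 1700..2299
  expect_equal(r$gstart[r$gene_id == "gplus"], 1700L)
  expect_equal(r$gend[r$gene_id == "gplus"], 2299L)
  # minus strand polya 900: revcomp of genomic 701..1300
  expect_equal(r$gstart[r$gene_id == "gminus"], 701L)
  expect_equal(r$gend[r$gene_id == "gminus"], 1300L)
})

test_that("polyA sites too close to the chromosome start are skipped", {
  genome <- tinyGenome()
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                      tss = 150L, polya_site = 350L)
  models <- geneModels(genes, list(g1 = IRanges::IRanges(150L, 350L)),
                       seqlengths = c(chr1 = 3000L))
  expect_warning(ts <- extractTerminatorWindows(genome, models, "g1"),
                 "outside chromosome")
  expect_equal(length(ts), 0L)
})

test_that("intron windows carry donor/acceptor offsets and flanks", {
  genome <- tinyGenome()
  # force a canonical intron at genomic 2001..2300 in a plus-strand gene
  chrom <- as.character(genome[["chr1"]])
  substr(chrom, 2001, 2002) <- "GT"
  substr(chrom, 2299, 2300) <- "AG"
  genome2 <- Biostrings::DNAStringSet(chrom)
  names(genome2) <- "chr1"
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                      tss = 1801L, polya_site = 2500L)
  models <- geneModels(genes,
                       list(g1 = IRanges::IRanges(c(1801L, 2301L),
                                                  c(2000L, 2500L))),
                       seqlengths = c(chr1 = 3000L))
  ts <- extractIntronWindows(genome2, models, "g1", flank = 5L)
  r <- as.data.frame(trainingRecords(ts))
  expect_equal(nrow(r), 1L)
  expect_equal(r$gstart, 1996L)
  expect_equal(r$gend, 2305L)
  expect_equal(BiocGenerics::width(trainingSequences(ts))[1], 310L)
  expect_equal(r$donor_offset, 5L)      # 0-based
  expect_equal(r$acceptor_offset, 304L)
  s <- as.character(trainingSequences(ts)[[1]])
  expect_equal(substr(s, 6, 7), "GT")   # 1-based window positions 6..7
  expect_equal(substr(s, 304, 305), "AG")
  expect_true(r$canonical)
})

test_that("single-exon genes yield no intron records", {
  genome <- tinyGenome()
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                      tss = 1000L, polya_site = 1400L)
  models <- geneModels(genes, list(g1 = IRanges::IRanges(1000L, 1400L)),
                       seqlengths = c(chr1 = 3000L))
  ts <- extractIntronWindows(genome, models, "g1")
  expect_equal(length(ts), 0L)
})

test_that("minus-strand intron extraction matches a brute-force revcomp extractor", {
  # brute force: reverse complement the whole chromosome, recompute all
  # coordinates on the flipped axis, extract as plus strand
  out <- makeToyGenome(seed = 13, nGenes = 8, chromLength = 30000)
  g <- as.data.frame(out$models@genes)
  minusIds <- g$gene_id[g$strand == "-"]
  ts <- extractIntronWindows(out$genome, out$models, minusIds)
  chromLen <- 30000L
  flippedChrom <- rcomp(as.character(out$genome[["chr1"]]))
  flippedGenome <- Biostrings::DNAStringSet(flippedChrom)
  names(flippedGenome) <- "chr1"
  flip <- function(x) chromLen - x + 1L
  gm <- g[g$strand == "-", ]
  flippedExons <- lapply(setNames(gm$gene_id, gm$gene_id), function(id) {
    ex <- out$models@exons[[id]]
    IRanges::IRanges(flip(BiocGenerics::end(ex)),
                     flip(BiocGenerics::start(ex)))
  })
  flippedGenes <- data.frame(gene_id = gm$gene_id, chrom = "chr1",
                             strand = "+", tss = flip(gm$tss),
                             polya_site = flip(gm$polya_site))
  flippedModels <- geneModels(flippedGenes, flippedExons,
                              seqlengths = c(chr1 = chromLen))
  tsFlip <- extractIntronWindows(flippedGenome, flippedModels, minusIds)
  expect_equal(as.character(trainingSequences(ts)),
               as.character(trainingSequences(tsFlip)))
  expect_equal(trainingRecords(ts)$donor_offset,
               trainingRecords(tsFlip)$donor_offset)
})

test_that("plus/minus extraction is symmetric under full genome reversal", {
  out <- makeToyGenome(seed = 5, nGenes = 6, chromLength = 25000)
  ts <- extractPromoterWindows(out$genome, out$models, out$geneIds)
  chromLen <- 25000L
  flip <- function(x) chromLen - x + 1L
  g <- as.data.frame(out$models@genes)
  flippedGenome <- Biostrings::DNAStringSet(
    rcomp(as.character(out$genome[["chr1"]])))
  names(flippedGenome) <- "chr1"
  flippedExons <- lapply(setNames(g$gene_id, g$gene_id), function(id) {
    ex <- out$models@exons[[id]]
    IRanges::IRanges(flip(BiocGenerics::end(ex)),
                     flip(BiocGenerics::start(ex)))
  })
  flippedGenes <- data.frame(gene_id = g$gene_id, chrom = "chr1",
                             strand = ifelse(g$strand == "+", "-", "+"),
                             tss = flip(g$tss),
                             polya_site = flip(g$polya_site))
  flippedModels <- geneModels(flippedGenes, flippedExons,
                              seqlengths = c(chr1 = chromLen))
  tsFlip <- extractPromoterWindows(flippedGenome, flippedModels,
                                   out$geneIds)
  expect_equal(as.character(trainingSequences(ts)),
               as.character(trainingSequences(tsFlip)))
})

test_that("training sets round-trip through FASTA with key=value headers", {
  out <- makeToyGenome(seed = 3, nGenes = 5, chromLength = 22000)
  ts <- extractPromoterWindows(out$genome, out$models, out$geneIds)
  fa <- tempfile(fileext = ".fa"); tsv <- tempfile(fileext = ".tsv")
  writeTrainingSet(ts, fa, tsv)
  back <- readTrainingSet(fa)
  expect_equal(as.character(trainingSequences(back)),
               as.character(trainingSequences(ts)))
  expect_equal(as.data.frame(trainingRecords(back)),
               as.data.frame(trainingRecords(ts))[,
                 colnames(trainingRecords(back))])
  expect_equal(windowAnchor(back), "TSS")
  idx <- read.delim(tsv)
  expect_equal(nrow(idx), length(ts))
})

test_that("gene models read back from GFF3 match the generating models", {
  dir <- tempfile(); dir.create(dir)
  out <- makeToyGenome(seed = 21, nGenes = 4, chromLength = 20000,
                       dir = dir)
  models <- readGeneModels(out$files$gff3)
  g1 <- as.data.frame(out$models@genes)
  g2 <- as.data.frame(models@genes)
  expect_equal(g2[order(g2$gene_id), c("gene_id", "strand", "tss",
                                       "polya_site")],
               g1[order(g1$gene_id), c("gene_id", "strand", "tss",
                                       "polya_site")],
               ignore_attr = TRUE)
  ids <- readGeneList(out$files$geneList)
  expect_equal(ids, out$geneIds)   # comment line is dropped
})
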