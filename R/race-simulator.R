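#' Simulation parameters for adapter-tagged RACE/amplicon reads
#'
#' Categorical distributions are named numeric vectors summing to 1
#' (names = cassette positions for \code{tssDist}/\code{polyaDist};
#' outcome labels for \code{spliceOutcomes}). Splice outcomes per intended
#' intron are \code{"EXPECTED"}, \code{"UNSPLICED"}, or \code{"ALT:d-a"}
#' (an alternative junction from donor d to acceptor a).
#'
#' @param cassette a \linkS4class{CassetteModel}.
#' @param tssDist named probability vector over TSS positions.
#' @param spliceOutcomes list (one element per intended junction) of named
#'   probability vectors over outcomes.
#' @param polyaDist named probability vector over polyA positions.
#' @param nReads number of reads.
#' @param readLength maximum read length (reads longer than their
#'   transcript are truncated to the transcript, noted in the truth
#'   table).
#' @param fraction5prime,fraction3prime fraction of reads anchored at the
#'   transcript 5' end (5' adapter) and 3' end (3' adapter); any
#'   remainder becomes internal reads without adapters.
#' @param seed integer seed.
#' @return a validated parameter list of class \code{"SimulationParams"}.
#' @export
simulationParams <- function(cassette, tssDist, spliceOutcomes, polyaDist,
                             nReads, readLength, fraction5prime = 0.5,
                             fraction3prime = 0.5, seed = 1L) {
  checkCat <- function(p, what) {
    if (any(p < 0)) stop(what, ": probabilities must be >= 0")
    if (abs(sum(p) - 1) > 1e-9) stop(what, ": probabilities must sum to 1")
  }
  checkCat(tssDist, "tssDist")
  checkCat(polyaDist, "polyaDist")
  if (length(spliceOutcomes) != nrow(intendedJunctions(cassette)))
    stop("spliceOutcomes must have one entry per intended junction")
  for (p in spliceOutcomes) checkCat(p, "spliceOutcomes")
  if (nReads <= 0) stop("nReads must be positive")
  if (fraction5prime + fraction3prime > 1 + 1e-9)
    stop("adapter fractions must sum to at most 1")
  structure(list(cassette = cassette, tssDist = tssDist,
                 spliceOutcomes = spliceOutcomes, polyaDist = polyaDist,
                 nReads = as.integer(nReads),
                 readLength = as.integer(readLength),
                 fraction5prime = fraction5prime,
                 fraction3prime = fraction3prime,
                 seed = as.integer(seed)),
            class = "SimulationParams")
}

sampleCat <- function(p, n) {
  v <- names(p)
  v[sample.int(length(p), n, replace = TRUE, prob = p)]
}

# transcript block structure on the cassette for one read's latent draws
transcriptBlocks <- function(tss, polya, removed) {
  tr <- IRanges::IRanges(tss, polya)
  if (length(removed) > 0)
    tr <- IRanges::setdiff(tr, removed)
  tr
}

# clip a transcript block structure to its first (from5 = TRUE) or last
# `len` transcribed bases
clipBlocks <- function(blocks, len, from5 = TRUE) {
  w <- BiocGenerics::width(blocks)
  total <- sum(w)
  if (len >= total) return(list(blocks = blocks, truncated = len > total))
  keepLen <- len
  st <- BiocGenerics::start(blocks); en <- BiocGenerics::end(blocks)
  if (!from5) { st <- rev(st); en <- rev(en); w <- rev(w) }
  outS <- integer(0); outE <- integer(0)
  for (i in seq_along(w)) {
    take <- min(w[i], keepLen)
    if (from5) { outS <- c(outS, st[i]); outE <- c(outE, st[i] + take - 1L) }
    else { outS <- c(outS, en[i] - take + 1L); outE <- c(outE, en[i]) }
    keepLen <- keepLen - take
    if (keepLen == 0) break
  }
  if (!from5) { outS <- rev(outS); outE <- rev(outE) }
  list(blocks = IRanges::IRanges(outS, outE), truncated = FALSE)
}

blocksToCigar <- function(blocks) {
  st <- BiocGenerics::start(blocks); en <- BiocGenerics::end(blocks)
  w <- en - st + 1L
  parts <- sprintf("%dM", w[1])
  if (length(w) > 1) {
    gaps <- st[-1] - en[-length(en)] - 1L
    for (i in seq_along(gaps))
      parts <- c(parts, sprintf("%dN", gaps[i]), sprintf("%dM", w[i + 1L]))
  }
  paste(parts, collapse = "")
}

#' Simulate adapter-tagged reads from a cassette model
#'
#' Each read independently samples a TSS, a splice outcome per intended
#' intron, and a polyA site; the transcript's block structure on the
#' cassette follows (EXPECTED removes the intended intron, UNSPLICED keeps
#' it, ALT:d-a removes d..a). 5'-adapter reads start exactly at the
#' sampled TSS and 3'-adapter reads end exactly at the sampled polyA site
#' (RLM-RACE / oligo-dT idealization); reads are error-free exact-match
#' alignments emitted as SAM (with \code{@SQ} header and adapter tags) and
#' FASTQ, with a truth table of every read's latent variables.
#' Deterministic for a fixed seed.
#'
#' @param params a \code{"SimulationParams"} list.
#' @param samPath,fastqPath,truthPath output paths (FASTQ and truth TSV
#'   skipped when NULL).
#' @param cassetteSeq optional cassette sequence (character or
#'   \linkS4class{DNAString}); a seed-derived random sequence of the
#'   cassette length is used when absent.
#' @param adapterTag SAM tag carrying adapter provenance (default "XA").
#' @return invisibly, a list: \code{sam}, \code{fastq}, \code{truth}
#'   (data.frame of latent variables).
#' @export
simulateReads <- function(params, samPath, fastqPath = NULL,
                          truthPath = NULL, cassetteSeq = NULL,
                          adapterTag = "XA") {
  stopifnot(inherits(params, "SimulationParams"))
  cass <- params$cassette
  L <- cass@length
  withSeed(params$seed, {
    if (is.null(cassetteSeq))
      cassetteSeq <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                           collapse = "")
    cassetteSeq <- toupper(as.character(cassetteSeq))
    if (nchar(cassetteSeq) != L)
      stop("cassetteSeq length does not match the cassette model")
    n <- params$nReads
    jdf <- as.data.frame(intendedJunctions(cass))
    tss <- as.integer(sampleCat(params$tssDist, n))
    polya <- as.integer(sampleCat(params$polyaDist, n))
    outcomes <- lapply(params$spliceOutcomes, sampleCat, n = n)
    u <- runif(n)
    anchor <- ifelse(u < params$fraction5prime, "5",
                     ifelse(u < params$fraction5prime + params$fraction3prime,
                            "3", "internal"))
    samLines <- character(n)
    fqLines <- if (!is.null(fastqPath)) character(4L * n) else NULL
    truth <- vector("list", n)
    for (r in seq_len(n)) {
      removedS <- integer(0); removedE <- integer(0)
      for (k in seq_len(nrow(jdf))) {
        oc <- outcomes[[k]][r]
        if (oc == "EXPECTED") {
          removedS <- c(removedS, jdf$p5[k]); removedE <- c(removedE, jdf$p3[k])
        } else if (startsWith(oc, "ALT:")) {
          da <- as.integer(strsplit(sub("^ALT:", "", oc), "-")[[1]])
          removedS <- c(removedS, da[1]); removedE <- c(removedE, da[2])
        }
      }
      tr <- transcriptBlocks(tss[r], polya[r],
                             IRanges::IRanges(removedS, removedE))
      trLen <- sum(BiocGenerics::width(tr))
      truncated <- FALSE
      if (anchor[r] == "5") {
        cl <- clipBlocks(tr, params$readLength, from5 = TRUE)
        blocks <- cl$blocks
        truncated <- params$readLength > trLen
      } else if (anchor[r] == "3") {
        cl <- clipBlocks(tr, params$readLength, from5 = FALSE)
        blocks <- cl$blocks
        truncated <- params$readLength > trLen
      } else {
        maxOff <- max(trLen - params$readLength, 0L)
        off <- if (maxOff > 0) sample.int(maxOff + 1L, 1L) - 1L else 0L
        cl <- clipBlocks(tr, off + params$readLength, from5 = TRUE)
        cl <- clipBlocks(cl$blocks, params$readLength, from5 = FALSE)
        blocks <- cl$blocks
        truncated <- params$readLength > trLen
      }
      qname <- sprintf("read%06d", r)
      seqStr <- paste(vapply(seq_along(blocks), function(i)
        substr(cassetteSeq, BiocGenerics::start(blocks)[i],
               BiocGenerics::end(blocks)[i]), character(1)), collapse = "")
      tag <- switch(anchor[r],
                    "5" = sprintf("%s:Z:5", adapterTag),
                    "3" = sprintf("%s:Z:3", adapterTag),
                    NULL)
      fields <- c(qname, "0", cassetteId(cass),
                  as.character(BiocGenerics::start(blocks)[1]), "60",
                  blocksToCigar(blocks), "*", "0", "0", seqStr,
                  strrep("I", nchar(seqStr)))
      if (!is.null(tag)) fields <- c(fields, tag)
      samLines[r] <- paste(fields, collapse = "\t")
      if (!is.null(fqLines)) {
        fqLines[4L * r - 3L] <- paste0("@", qname)
        fqLines[4L * r - 2L] <- seqStr
        fqLines[4L * r - 1L] <- "+"
        fqLines[4L * r] <- strrep("I", nchar(seqStr))
      }
      truth[[r]] <- data.frame(
        read_id = qname, adapter = anchor[r], tss = tss[r],
        polya = polya[r],
        outcome = if (nrow(jdf) > 0)
          paste(vapply(outcomes, `[`, character(1), r), collapse = ";")
        else "", truncated = truncated, stringsAsFactors = FALSE)
    }
    hdr <- c("@HD\tVN:1.6\tSO:unknown",
             sprintf("@SQ\tSN:%s\tLN:%d", cassetteId(cass), L),
             sprintf("@PG\tID:plantElements\tPN:plantElements\tVN:%s",
                     as.character(packageVersion("plantElements"))))
    writeLines(c(hdr, samLines), samPath)
    if (!is.null(fastqPath)) writeLines(fqLines, fastqPath)
    truthDf <- do.call(rbind, truth)
    if (!is.null(truthPath))
      write.table(truthDf, truthPath, sep = "\t", quote = FALSE,
                  row.names = FALSE)
    invisible(list(sam = samPath, fastq = fastqPath, truth = truthDf))
  })
}

#' Generate a toy genome with annotated multi-exon genes
#'
#' Emits a random chromosome carrying non-overlapping genes on alternating
#' strands, each with 2-3 exons and canonical GT..AG introns, with enough
#' intergenic room for promoter (-1000/+50) and terminator (-400/+200)
#' windows. A positional motif can be planted on the transcription strand
#' at a stated offset relative to the TSS with a stated penetrance.
#' Deterministic per seed; a geometry that cannot fit the requested genes
#' is a hard error.
#'
#' @param seed integer seed.
#' @param nGenes number of genes.
#' @param chromLength chromosome length in bp.
#' @param plantMotif optional list: \code{pattern} (IUPAC), \code{offset}
#'   (relative to the TSS, negative = upstream), \code{penetrance}
#'   (fraction of genes carrying it).
#' @param dir optional output directory; when given, writes
#'   \code{genome.fa}, \code{genes.gff3} and \code{genes.txt}.
#' @return a list: \code{genome} (\linkS4class{DNAStringSet}),
#'   \code{models} (\linkS4class{GeneModels}), \code{geneIds},
#'   \code{planted} (logical per gene), and file paths when \code{dir} is
#'   given.
#' @export
makeToyGenome <- function(seed, nGenes = 20L, chromLength = 60000L,
                          plantMotif = NULL, dir = NULL) {
  withSeed(seed, {
    upPad <- 1050L; downPad <- 650L
    geneSpan <- 900L
    pitch <- upPad + geneSpan + downPad + 100L
    if (nGenes * pitch + upPad > chromLength)
      stop("infeasible geometry: ", nGenes, " genes do not fit in ",
           chromLength, " bp")
    ch <- sample(c("A", "C", "G", "T"), chromLength, replace = TRUE,
                 prob = c(0.3, 0.2, 0.2, 0.3))
    ids <- sprintf("gene%03d", seq_len(nGenes))
    strands <- rep(c("+", "-"), length.out = nGenes)
    planted <- rep(FALSE, nGenes)
    genes <- list(); exonsList <- list()
    for (i in seq_len(nGenes)) {
      left <- upPad + (i - 1L) * pitch + 1L
      nEx <- sample(2:3, 1L)
      exLens <- sample(120:250, nEx, replace = TRUE)
      inLens <- sample(80:250, nEx - 1L, replace = TRUE)
      # lay out left-to-right in genomic coordinates
      starts <- integer(nEx); ends <- integer(nEx)
      cur <- left
      for (k in seq_len(nEx)) {
        starts[k] <- cur; ends[k] <- cur + exLens[k] - 1L
        if (k < nEx) cur <- ends[k] + inLens[k] + 1L
      }
      strand <- strands[i]
      # canonical splice dinucleotides on the transcription strand
      for (k in seq_len(nEx - 1L)) {
        iS <- ends[k] + 1L; iE <- starts[k + 1L] - 1L
        if (strand == "+") {
          ch[iS:(iS + 1L)] <- c("G", "T"); ch[(iE - 1L):iE] <- c("A", "G")
        } else {
          # transcription runs right to left: donor at the right edge
          ch[(iE - 1L):iE] <- c("A", "C")   # revcomp("GT")
          ch[iS:(iS + 1L)] <- c("C", "T")   # revcomp("AG")
        }
      }
      tss <- if (strand == "+") starts[1] else ends[nEx]
      pa <- if (strand == "+") ends[nEx] else starts[1]
      if (!is.null(plantMotif) && runif(1) < plantMotif$penetrance) {
        word <- concretizeIupac(plantMotif$pattern)
        wch <- strsplit(word, "")[[1]]
        if (strand == "+") {
          p0 <- tss + plantMotif$offset
          ch[p0:(p0 + length(wch) - 1L)] <- wch
        } else {
          p0 <- tss - plantMotif$offset
          rc <- strsplit(revcompChar(word), "")[[1]]
          ch[(p0 - length(wch) + 1L):p0] <- rc
        }
        planted[i] <- TRUE
      }
      exonOrder <- if (strand == "+") seq_len(nEx) else rev(seq_len(nEx))
      genes[[i]] <- data.frame(gene_id = ids[i], chrom = "chr1",
                               strand = strand, tss = tss, polya_site = pa,
                               stringsAsFactors = FALSE)
      exonsList[[ids[i]]] <- IRanges::IRanges(starts[exonOrder],
                                              ends[exonOrder])
    }
    genome <- Biostrings::DNAStringSet(paste(ch, collapse = ""))
    names(genome) <- "chr1"
    models <- geneModels(do.call(rbind, genes), exonsList,
                         seqlengths = c(chr1 = chromLength))
    out <- list(genome = genome, models = models, geneIds = ids,
                planted = planted)
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      fa <- file.path(dir, "genome.fa")
      Biostrings::writeXStringSet(genome, fa)
      gff <- file.path(dir, "genes.gff3")
      writeToyGff3(models, gff)
      lst <- file.path(dir, "genes.txt")
      writeLines(c("# toy genome gene list", ids), lst)
      out$files <- list(genome = fa, gff3 = gff, geneList = lst)
    }
    out
  })
}

writeToyGff3 <- function(models, path) {
  g <- as.data.frame(models@genes)
  rows <- character(0)
  for (i in seq_len(nrow(g))) {
    ex <- models@exons[[i]]
    gs <- min(BiocGenerics::start(ex)); ge <- max(BiocGenerics::end(ex))
    rows <- c(rows, sprintf("%s\ttoy\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                            g$chrom[i], gs, ge, g$strand[i], g$gene_id[i]))
    for (k in seq_along(ex))
      rows <- c(rows,
                sprintf("%s\ttoy\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
                        g$chrom[i], BiocGenerics::start(ex)[k],
                        BiocGenerics::end(ex)[k], g$strand[i],
                        g$gene_id[i], k, g$gene_id[i]))
  }
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}
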