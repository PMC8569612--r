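#' Extract anchored training windows around transcription start sites
#'
#' For each requested gene, extracts the window from \code{upstream} bases
#' strictly 5' of the TSS through \code{downstream} bases starting at and
#' including the TSS (default -1000/+50, a 1,050 nt window), in
#' transcription orientation; minus-strand windows are reverse-complemented.
#' Windows extending beyond a chromosome boundary are skipped with a
#' warning so that all records stay length-aligned for positional
#' statistics.
#'
#' @param genome a named \linkS4class{DNAStringSet} (see
#'   \code{\link{readGenome}}).
#' @param models a \linkS4class{GeneModels} object.
#' @param geneIds character vector of gene IDs; every ID must be present in
#'   \code{models} (unknown IDs are a hard error).
#' @param upstream,downstream window extent in bp around the anchor.
#' @return a \linkS4class{TrainingSet} with the anchor base at 0-based
#'   offset \code{upstream}.
#' @export
extractPromoterWindows <- function(genome, models, geneIds,
                                   upstream = 1000L, downstream = 50L) {
  extractAnchoredWindows(genome, models, geneIds, "TSS",
                         as.integer(upstream), as.integer(downstream))
}

#' Extract anchored training windows around polyadenylation sites
#'
#' As \code{\link{extractPromoterWindows}} but anchored at the
#' polyadenylation site (last transcribed base); default -400/+200, a
#' 600 nt window with the cleavage site at 0-based offset 400.
#'
#' @inheritParams extractPromoterWindows
#' @return a \linkS4class{TrainingSet}.
#' @export
extractTerminatorWindows <- function(genome, models, geneIds,
                                     upstream = 400L, downstream = 200L) {
  extractAnchoredWindows(genome, models, geneIds, "POLYA",
                         as.integer(upstream), as.integer(downstream))
}

extractAnchoredWindows <- function(genome, models, geneIds, anchor,
                                   upstream, downstream) {
  if (upstream < 0 || downstream < 0 || upstream + downstream <= 0)
    stop("upstream + downstream must be positive")
  assertPlainDNA(genome, "genome")
  g <- models@genes
  miss <- setdiff(geneIds, g$gene_id)
  if (length(miss) > 0)
    stop("unknown gene_id(s): ", paste(miss, collapse = ", "))
  idx <- match(geneIds, g$gene_id)
  recs <- list(); seqs <- character(0)
  for (i in idx) {
    chrom <- as.character(g$chrom[i])
    if (!chrom %in% names(genome))
      stop("chromosome not in genome: ", chrom)
    clen <- length(genome[[chrom]])
    a <- if (anchor == "TSS") g$tss[i] else g$polya_site[i]
    if (g$strand[i] == "+") {
      gstart <- a - upstream; gend <- a + downstream - 1L
    } else {
      gstart <- a - downstream + 1L; gend <- a + upstream
    }
    if (gstart < 1L || gend > clen) {
      warning(sprintf("window for %s (%s:%d-%d) outside chromosome; skipped",
                      g$gene_id[i], chrom, gstart, gend), call. = FALSE)
      next
    }
    s <- Biostrings::subseq(genome[[chrom]], gstart, gend)
    if (g$strand[i] == "-") s <- Biostrings::reverseComplement(s)
    seqs <- c(seqs, as.character(s))
    recs[[length(recs) + 1L]] <- data.frame(
      gene_id = as.character(g$gene_id[i]), chrom = chrom,
      gstart = gstart, gend = gend, strand = g$strand[i],
      anchor_offset = upstream, stringsAsFactors = FALSE)
  }
  records <- if (length(recs)) S4Vectors::DataFrame(do.call(rbind, recs))
             else emptyWindowRecords()
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- records$gene_id
  methods::new("TrainingSet", sequences = ss, records = records,
               anchor = anchor, upstream = upstream, downstream = downstream)
}

emptyWindowRecords <- function() {
  S4Vectors::DataFrame(gene_id = character(0), chrom = character(0),
                       gstart = integer(0), gend = integer(0),
                       strand = character(0), anchor_offset = integer(0))
}

#' Extract intron training windows with exonic flanks
#'
#' One record per intron: the intron sequence plus \code{flank} exonic bases
#' on each side, in transcription orientation. Each record carries the
#' donor (first intronic base) and acceptor (last intronic base) 0-based
#' offsets within the window, and a flag for canonical GT..AG boundaries.
#' Single-exon genes contribute no records; a flank exceeding the adjacent
#' exon length is truncated with a warning.
#'
#' @inheritParams extractPromoterWindows
#' @param flank exonic flank length in bp (default 5).
#' @return a \linkS4class{TrainingSet} with anchor \code{"SPLICE5"};
#'   window lengths vary with intron length.
#' @export
extractIntronWindows <- function(genome, models, geneIds, flank = 5L) {
  flank <- as.integer(flank)
  assertPlainDNA(genome, "genome")
  g <- models@genes
  miss <- setdiff(geneIds, g$gene_id)
  if (length(miss) > 0)
    stop("unknown gene_id(s): ", paste(miss, collapse = ", "))
  recs <- list(); seqs <- character(0)
  for (i in match(geneIds, g$gene_id)) {
    ex <- models@exons[[i]]
    if (length(ex) < 2L) next
    chrom <- as.character(g$chrom[i])
    if (!chrom %in% names(genome))
      stop("chromosome not in genome: ", chrom)
    clen <- length(genome[[chrom]])
    strand <- g$strand[i]
    for (k in seq_len(length(ex) - 1L)) {
      e1 <- ex[k]; e2 <- ex[k + 1L]   # transcription order
      if (strand == "+") {
        istart <- BiocGenerics::end(e1) + 1L
        iend <- BiocGenerics::start(e2) - 1L
      } else {
        istart <- BiocGenerics::end(e2) + 1L
        iend <- BiocGenerics::start(e1) - 1L
      }
      if (iend < istart) next       # abutting exons: no intron
      f5 <- min(flank, BiocGenerics::width(e1))
      f3 <- min(flank, BiocGenerics::width(e2))
      if (f5 < flank || f3 < flank)
        warning(sprintf("%s intron %d: flank truncated to fit exon",
                        g$gene_id[i], k), call. = FALSE)
      if (strand == "+") {
        gstart <- istart - f5; gend <- iend + f3
      } else {
        gstart <- istart - f3; gend <- iend + f5
      }
      if (gstart < 1L || gend > clen) {
        warning(sprintf("%s intron %d window outside chromosome; skipped",
                        g$gene_id[i], k), call. = FALSE)
        next
      }
      s <- Biostrings::subseq(genome[[chrom]], gstart, gend)
      if (strand == "-") s <- Biostrings::reverseComplement(s)
      sc <- as.character(s)
      ilen <- iend - istart + 1L
      donor <- f5                     # 0-based index of first intronic base
      acceptor <- f5 + ilen - 1L      # 0-based index of last intronic base
      canonical <- substr(sc, donor + 1L, donor + 2L) == "GT" &&
        substr(sc, acceptor, acceptor + 1L) == "AG"
      seqs <- c(seqs, sc)
      recs[[length(recs) + 1L]] <- data.frame(
        gene_id = as.character(g$gene_id[i]), chrom = chrom,
        gstart = gstart, gend = gend, strand = strand,
        anchor_offset = donor, donor_offset = donor,
        acceptor_offset = acceptor, canonical = canonical,
        stringsAsFactors = FALSE)
    }
  }
  records <- if (length(recs)) S4Vectors::DataFrame(do.call(rbind, recs))
  else S4Vectors::DataFrame(
    gene_id = character(0), chrom = character(0), gstart = integer(0),
    gend = integer(0), strand = character(0), anchor_offset = integer(0),
    donor_offset = integer(0), acceptor_offset = integer(0),
    canonical = logical(0))
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- records$gene_id
  methods::new("TrainingSet", sequences = ss, records = records,
               anchor = "SPLICE5", upstream = flank, downstream = flank)
}

#' Write a TrainingSet as FASTA plus a TSV index
#'
#' FASTA headers carry \code{key=value} pairs (gene_id, interval, strand,
#' anchor_offset) so the set round-trips through
#' \code{\link{readTrainingSet}}.
#'
#' @param ts a \linkS4class{TrainingSet}.
#' @param fastaPath,tsvPath output paths (the TSV is skipped when NULL).
#' @return invisibly, the FASTA path.
#' @export
writeTrainingSet <- function(ts, fastaPath, tsvPath = NULL) {
  r <- as.data.frame(ts@records)
  hdr <- sprintf("gene_id=%s interval=%s:%d-%d strand=%s anchor=%s anchor_offset=%d upstream=%d downstream=%d",
                 r$gene_id, r$chrom, r$gstart, r$gend, r$strand,
                 ts@anchor, r$anchor_offset, ts@upstream, ts@downstream)
  seqs <- ts@sequences
  names(seqs) <- hdr
  Biostrings::writeXStringSet(seqs, fastaPath)
  if (!is.null(tsvPath))
    write.table(r, tsvPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fastaPath)
}

#' Read a TrainingSet written by writeTrainingSet
#'
#' @param fastaPath FASTA produced by \code{\link{writeTrainingSet}}.
#' @return a \linkS4class{TrainingSet}.
#' @export
readTrainingSet <- function(fastaPath) {
  seqs <- Biostrings::readDNAStringSet(fastaPath)
  hdr <- names(seqs)
  pull <- function(key) sub(paste0(".*", key, "=([^ ]+).*"), "\\1", hdr)
  interval <- pull("interval")
  chrom <- sub(":.*$", "", interval)
  gstart <- as.integer(sub("^.*:(\\d+)-.*$", "\\1", interval))
  gend <- as.integer(sub("^.*-(\\d+)$", "\\1", interval))
  records <- S4Vectors::DataFrame(
    gene_id = pull("gene_id"), chrom = chrom, gstart = gstart, gend = gend,
    strand = pull("strand"), anchor_offset = as.integer(pull("anchor_offset")))
  names(seqs) <- records$gene_id
  methods::new("TrainingSet", sequences = seqs, records = records,
               anchor = pull("anchor")[1],
               upstream = as.integer(pull("upstream"))[1],
               downstream = as.integer(pull("downstream"))[1])
}
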