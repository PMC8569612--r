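#' Construct a GeneModels object
#'
#' @param genes data.frame with columns gene_id, chrom, strand, tss,
#'   polya_site (1-based genomic coordinates of the first and last
#'   transcribed base).
#' @param exons named list (by gene_id) of \linkS4class{IRanges} or
#'   two-column matrices of exon intervals, in transcription order.
#' @param seqlengths named integer vector of chromosome lengths.
#' @return a \linkS4class{GeneModels} object.
#' @export
geneModels <- function(genes, exons, seqlengths = integer(0)) {
  genes <- S4Vectors::DataFrame(genes)
  ex <- lapply(exons, function(e) {
    if (is.matrix(e)) IRanges::IRanges(e[, 1], e[, 2]) else e
  })
  irl <- IRanges::IRangesList(ex)
  names(irl) <- names(exons)
  irl <- irl[as.character(genes$gene_id)]
  sl <- setNames(as.integer(seqlengths), names(seqlengths))
  methods::new("GeneModels", genes = genes,
               exons = methods::as(irl, "CompressedIRangesList"),
               seqlengths = sl)
}

#' Read gene models from a GFF3 annotation
#'
#' Consumes the GFF3 subset used throughout the package: \code{gene}
#' features carrying an \code{ID} attribute and \code{exon} features
#' carrying a \code{Parent} attribute; strand is required. The TSS is the
#' first base of the transcription-order first exon and the polyadenylation
#' site the last base of the last exon.
#'
#' @param path path to a GFF3 file.
#' @param seqlengths optional named chromosome lengths; taken from the
#'   genome when windows are extracted if not given here.
#' @return a \linkS4class{GeneModels} object.
#' @export
readGeneModels <- function(path, seqlengths = integer(0)) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  genes <- gr[type == "gene"]
  exons <- gr[type == "exon"]
  if (length(genes) == 0) stop("no gene features in ", path)
  if (any(as.character(BiocGenerics::strand(genes)) == "*"))
    stop("strand is required for every gene")
  parent <- as.character(S4Vectors::unstrsplit(exons$Parent, ","))
  ids <- as.character(genes$ID)
  exl <- split(IRanges::ranges(exons), factor(parent, levels = ids))
  gstrand <- as.character(BiocGenerics::strand(genes))
  exl <- methods::as(lapply(seq_along(exl), function(i) {
    e <- exl[[i]]
    e <- e[order(BiocGenerics::start(e), decreasing = gstrand[i] == "-")]
    e
  }), "CompressedIRangesList")
  names(exl) <- ids
  tss <- ifelse(gstrand == "+",
                vapply(exl, function(e) BiocGenerics::start(e)[1], integer(1)),
                vapply(exl, function(e) BiocGenerics::end(e)[1], integer(1)))
  pa <- ifelse(gstrand == "+",
               vapply(exl, function(e) BiocGenerics::end(e)[length(e)], integer(1)),
               vapply(exl, function(e) BiocGenerics::start(e)[length(e)], integer(1)))
  df <- S4Vectors::DataFrame(
    gene_id = ids,
    chrom = as.character(GenomeInfoDb::seqnames(genes)),
    strand = gstrand, tss = as.integer(tss), polya_site = as.integer(pa))
  methods::new("GeneModels", genes = df, exons = exl,
               seqlengths = setNames(as.integer(seqlengths),
                                     names(seqlengths)))
}

#' Read a gene-ID list
#'
#' Plain text, one ID per line; \code{#} starts a comment; blank lines are
#' ignored.
#' @param path file path.
#' @return character vector of gene IDs.
#' @export
readGeneList <- function(path) {
  if (!file.exists(path)) stop("gene list not found: ", path)
  x <- readLines(path)
  x <- sub("#.*$", "", x)
  x <- trimws(x)
  x[nzchar(x)]
}

#' Read a genome FASTA
#'
#' Multi-record, wrapped or unwrapped, case-insensitive; any ambiguity code
#' other than N is a hard error.
#' @param path FASTA path.
#' @return a named \linkS4class{DNAStringSet}.
#' @export
readGenome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  assertPlainDNA(g, "genome")
  g
}
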