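#' Parse spliced SAM alignments against a cassette
#'
#' Consumes plain-text SAM (with \code{@SQ} header) produced by a
#' splice-aware aligner or by \code{\link{simulateReads}}. CIGAR
#' M/=/X ops consume both sequences, I consumes the read only, D consumes
#' the reference within a block, N opens a junction gap, and S/H are
#' ignored for block construction. Reads failing the unique-mapping
#' criterion (MAPQ below \code{minMapq}, or flagged secondary /
#' supplementary / unmapped) are excluded. Adapter provenance is read from
#' a configurable optional tag (default \code{XA}, values "5", "3" or
#' "53"); set \code{assumeAll5prime}/\code{assumeAll3prime} for pipelines
#' that pre-filter reads instead of tagging them. Multiple SAM files are
#' pooled (reads pooled across events).
#'
#' @param samPaths one or more SAM file paths.
#' @param cassette a \linkS4class{CassetteModel}; the SAM reference name
#'   must match \code{cassetteId(cassette)} (anything else is a hard
#'   error).
#' @param adapterTag name of the SAM optional tag carrying adapter
#'   provenance.
#' @param minMapq minimum MAPQ for the unique-mapping criterion (default 1).
#' @param assumeAll5prime,assumeAll3prime treat every retained read as
#'   adapter-carrying (escape hatch for pre-filtered inputs).
#' @return a \linkS4class{CassetteAlignments}.
#' @export
parseAlignments <- function(samPaths, cassette, adapterTag = "XA",
                            minMapq = 1L, assumeAll5prime = FALSE,
                            assumeAll3prime = FALSE) {
  stopifnot(methods::is(cassette, "CassetteModel"))
  allId <- character(0)
  allBlocks <- list()
  allTag <- character(0)
  for (sam in samPaths) {
    if (!file.exists(sam)) stop("SAM file not found: ", sam)
    validateSamFile(sam)
    bam <- tryCatch(
      Rsamtools::asBam(sam, destination = tempfile(), overwrite = TRUE,
                       indexDestination = FALSE),
      error = function(e) stop("malformed SAM '", sam, "': ",
                               conditionMessage(e), call. = FALSE))
    hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
    if (!cassetteId(cassette) %in% names(hdr))
      stop("unknown reference in ", sam, ": expected ",
           cassetteId(cassette), ", found ",
           paste(names(hdr), collapse = ", "))
    param <- Rsamtools::ScanBamParam(
      what = c("qname", "flag", "mapq"), tag = adapterTag,
      flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                    isSupplementaryAlignment = FALSE,
                                    isUnmappedQuery = FALSE))
    gal <- GenomicAlignments::readGAlignments(bam, param = param)
    keep <- !is.na(S4Vectors::mcols(gal)$mapq) &
      S4Vectors::mcols(gal)$mapq >= minMapq &
      as.character(GenomeInfoDb::seqnames(gal)) == cassetteId(cassette)
    gal <- gal[keep]
    tagv <- S4Vectors::mcols(gal)[[adapterTag]]
    if (is.null(tagv)) tagv <- rep(NA_character_, length(gal))
    blocks <- GenomicAlignments::cigarRangesAlongReferenceSpace(
      GenomicAlignments::cigar(gal), pos = BiocGenerics::start(gal),
      ops = c("M", "=", "X", "D"), reduce.ranges = TRUE)
    allId <- c(allId, S4Vectors::mcols(gal)$qname)
    allBlocks <- c(allBlocks, as.list(blocks))
    allTag <- c(allTag, as.character(tagv))
    unlink(c(bam, paste0(bam, ".bai")))
  }
  has5 <- if (assumeAll5prime) rep(TRUE, length(allId))
          else !is.na(allTag) & grepl("5", allTag, fixed = TRUE)
  has3 <- if (assumeAll3prime) rep(TRUE, length(allId))
          else !is.na(allTag) & grepl("3", allTag, fixed = TRUE)
  methods::new("CassetteAlignments", readId = allId,
               blocks = methods::as(IRanges::IRangesList(allBlocks),
                                    "CompressedIRangesList"),
               has5 = has5, has3 = has3,
               cassetteId = cassetteId(cassette))
}

# htslib downgrades SAM parse errors to warnings and truncates; enforce the
# hard-error contract (with a line number) by a light structural check
# before conversion. Alignment semantics are still handled by Rsamtools.
validateSamFile <- function(sam) {
  lines <- readLines(sam)
  body <- which(!startsWith(lines, "@"))
  if (!any(startsWith(lines, "@SQ")))
    stop("malformed SAM '", sam, "': missing @SQ header")
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    ok <- length(f) >= 11 &&
      grepl("^\\d+$", f[2]) && grepl("^\\d+$", f[4]) &&
      grepl("^\\d+$", f[5]) &&
      grepl("^(\\*|([0-9]+[MIDNSHP=X])+)$", f[6])
    if (!ok)
      stop("malformed SAM '", sam, "' at line ", i, ": ",
           substr(lines[i], 1, 60))
  }
  invisible(TRUE)
}

#' Tabulate splice junctions from parsed alignments
#'
#' Every gap between consecutive aligned blocks of a read contributes one
#' count to its (donor, acceptor) key, with donor = first intronic base
#' (block end + 1) and acceptor = last intronic base (next block start -
#' 1). Multi-gap reads contribute to each of their gaps.
#'
#' @param reads a \linkS4class{CassetteAlignments}.
#' @return a \code{data.frame} junction table: donor, acceptor, count,
#'   sorted by (donor, acceptor).
#' @export
extractJunctions <- function(reads) {
  bl <- readBlocks(reads)
  nb <- S4Vectors::elementNROWS(bl)
  multi <- which(nb > 1)
  if (length(multi) == 0)
    return(data.frame(donor = integer(0), acceptor = integer(0),
                      count = integer(0)))
  st <- BiocGenerics::start(bl)[multi]
  en <- BiocGenerics::end(bl)[multi]
  donors <- unlist(lapply(en, function(e) e[-length(e)] + 1L))
  acceptors <- unlist(lapply(st, function(s) s[-1] - 1L))
  dt <- data.table::data.table(donor = donors, acceptor = acceptors)
  cnt <- dt[, list(count = .N), by = list(donor, acceptor)]
  data.table::setorder(cnt, donor, acceptor)
  as.data.frame(cnt)
}

# counts of reads whose single contiguous block spans positions p and p+1
# (unspliced coverage of a splice boundary), per position in `p`
countBoundarySpanning <- function(reads, p) {
  bl <- readBlocks(reads)
  st <- unlist(BiocGenerics::start(bl))
  en <- unlist(BiocGenerics::end(bl))
  vapply(p, function(pos) sum(st <= pos & en >= pos + 1L), integer(1))
}

#' Splice-site usage accounting from printed or derived counts
#'
#' The core usage computation: for each intended junction (p5, p3), reads
#' informative at the intended 5' position are partitioned into expected
#' splicing (junction (p5, p3)), unspliced (contiguous coverage across the
#' 5' boundary) and unexpected junctions sharing the donor p5; the percent
#' observed in each category is 100 x count / (sum of the three), rounded
#' half-up to one decimal. The 3' side mirrors this with the acceptor p3.
#' Junctions using neither intended position appear in the category table
#' without entering any intended-position denominator. A zero denominator
#' yields NA percentages (undefined, not 0).
#'
#' @param junctions junction table (data.frame: donor, acceptor, count).
#' @param intended data.frame with columns p5, p3 (one row per intended
#'   intron).
#' @param unspliced5,unspliced3 integer vectors, one count per intended
#'   junction: reads covering the 5'/3' splice boundary contiguously.
#' @return a \linkS4class{SpliceUsageReport}.
#' @export
spliceUsageFromCounts <- function(junctions, intended, unspliced5,
                                  unspliced3) {
  stopifnot(nrow(intended) >= 1,
            length(unspliced5) == nrow(intended),
            length(unspliced3) == nrow(intended))
  jkey <- paste(junctions$donor, junctions$acceptor)
  rows <- list(); cats <- list()
  usedJunction <- rep(FALSE, nrow(junctions))
  for (i in seq_len(nrow(intended))) {
    p5 <- intended$p5[i]; p3 <- intended$p3[i]
    expIdx <- which(junctions$donor == p5 & junctions$acceptor == p3)
    expected <- if (length(expIdx)) junctions$count[expIdx] else 0L
    un5idx <- which(junctions$donor == p5 & junctions$acceptor != p3)
    un3idx <- which(junctions$donor != p5 & junctions$acceptor == p3)
    usedJunction[c(expIdx, un5idx, un3idx)] <- TRUE
    den5 <- expected + unspliced5[i] + sum(junctions$count[un5idx])
    den3 <- expected + unspliced3[i] + sum(junctions$count[un3idx])
    pct <- function(cnt, den) if (den > 0) roundHalfUp(100 * cnt / den, 1L)
                              else NA_real_
    rows[[i]] <- data.frame(
      p5 = p5, p3 = p3, expected_count = expected,
      unspliced5_count = unspliced5[i], unspliced3_count = unspliced3[i],
      den5 = den5, den3 = den3,
      pct_expected_5 = pct(expected, den5),
      pct_unspliced_5 = pct(unspliced5[i], den5),
      pct_expected_3 = pct(expected, den3),
      pct_unspliced_3 = pct(unspliced3[i], den3))
    cats[[length(cats) + 1L]] <- data.frame(
      intron = i, donor = p5, acceptor = p3, category = "expected",
      count = expected, pct_5 = pct(expected, den5),
      pct_3 = pct(expected, den3))
    cats[[length(cats) + 1L]] <- data.frame(
      intron = i, donor = p5, acceptor = p3, category = "unspliced",
      count = NA_integer_, pct_5 = pct(unspliced5[i], den5),
      pct_3 = pct(unspliced3[i], den3))
    for (j in un5idx)
      cats[[length(cats) + 1L]] <- data.frame(
        intron = i, donor = junctions$donor[j],
        acceptor = junctions$acceptor[j], category = "unexpected",
        count = junctions$count[j],
        pct_5 = pct(junctions$count[j], den5), pct_3 = NA_real_)
    for (j in un3idx)
      cats[[length(cats) + 1L]] <- data.frame(
        intron = i, donor = junctions$donor[j],
        acceptor = junctions$acceptor[j], category = "unexpected",
        count = junctions$count[j],
        pct_5 = NA_real_, pct_3 = pct(junctions$count[j], den3))
  }
  # junctions touching no intended position: reported, no denominator
  for (j in which(!usedJunction))
    cats[[length(cats) + 1L]] <- data.frame(
      intron = NA_integer_, donor = junctions$donor[j],
      acceptor = junctions$acceptor[j], category = "unexpected",
      count = junctions$count[j], pct_5 = NA_real_, pct_3 = NA_real_)
  methods::new("SpliceUsageReport",
               intended = S4Vectors::DataFrame(do.call(rbind, rows)),
               categories = S4Vectors::DataFrame(do.call(rbind, cats)),
               junctions = S4Vectors::DataFrame(junctions))
}

#' Splice-site usage accounting from parsed alignments
#'
#' Derives the junction table and boundary-spanning (unspliced) counts from
#' the reads, then applies \code{\link{spliceUsageFromCounts}}. Reads whose
#' block ends exactly at a splice boundary are uninformative there and
#' enter no denominator. Junctions supported by fewer than
#' \code{minSupport} reads are dropped from the table.
#'
#' @param reads a \linkS4class{CassetteAlignments}.
#' @param cassette a \linkS4class{CassetteModel} with >= 1 intended
#'   junction.
#' @param junctions optional pre-computed junction table (defaults to
#'   \code{extractJunctions(reads)}).
#' @param minSupport minimum read support for a junction (default 1).
#' @return a \linkS4class{SpliceUsageReport}.
#' @export
spliceUsage <- function(reads, cassette, junctions = NULL, minSupport = 1L) {
  intended <- as.data.frame(intendedJunctions(cassette))
  if (nrow(intended) == 0)
    stop("cassette has no intended junctions")
  if (is.null(junctions)) junctions <- extractJunctions(reads)
  junctions <- junctions[junctions$count >= minSupport, , drop = FALSE]
  un5 <- countBoundarySpanning(reads, intended$p5 - 1L)
  un3 <- countBoundarySpanning(reads, intended$p3)
  spliceUsageFromCounts(junctions, intended, un5, un3)
}

siteDistributionFrom <- function(sites, kind) {
  tb <- table(sites)
  pos <- as.integer(names(tb))
  cnt <- as.integer(tb)
  total <- sum(cnt)
  pct <- roundHalfUp(100 * cnt / total, 2L)
  methods::new("SiteDistribution", kind = kind, total = total,
               table = S4Vectors::DataFrame(position = pos, count = cnt,
                                            pct = pct),
               dominantSite = min(pos[cnt == max(cnt)]))
}

#' Transcription start site distribution from 5'-adapter reads
#'
#' Informative reads are the uniquely mapped reads carrying the 5' adapter;
#' each contributes its first aligned base. Percentages are
#' 100 x count / total, rounded to two decimals; the dominant site is the
#' modal position (smallest coordinate on ties).
#'
#' @param reads a \linkS4class{CassetteAlignments}.
#' @return a \linkS4class{SiteDistribution} of kind "TSS".
#' @export
tssDistribution <- function(reads) {
  keep <- hasAdapter5(reads)
  if (!any(keep)) stop("no reads with the 5' adapter")
  bl <- readBlocks(reads)[keep]
  first <- vapply(as.list(BiocGenerics::start(bl)), `[`, integer(1), 1L)
  siteDistributionFrom(first, "TSS")
}

#' Polyadenylation site distribution from 3'-adapter reads
#'
#' As \code{\link{tssDistribution}} but over reads carrying the 3' adapter,
#' each contributing the last aligned base of its last block.
#'
#' @param reads a \linkS4class{CassetteAlignments}.
#' @return a \linkS4class{SiteDistribution} of kind "POLYA".
#' @export
polyaDistribution <- function(reads) {
  keep <- hasAdapter3(reads)
  if (!any(keep)) stop("no reads with the 3' adapter")
  bl <- readBlocks(reads)[keep]
  last <- vapply(as.list(BiocGenerics::end(bl)),
                 function(e) e[length(e)], integer(1))
  siteDistributionFrom(last, "POLYA")
}

#' Best read-mass window of a site distribution
#'
#' The maximal fraction of informative reads falling in any contiguous
#' window of \code{width} positions (leftmost window on ties) -- the
#' statistic behind "x% of transcription initiation within a 10-bp
#' window".
#'
#' @param dist a \linkS4class{SiteDistribution}.
#' @param width window width in bp (default 10).
#' @return list: \code{window_start}, \code{fraction_pct} (rounded to one
#'   decimal).
#' @export
windowFraction <- function(dist, width = 10L) {
  tb <- siteTable(dist)
  pos <- tb$position; cnt <- tb$count
  lo <- min(pos); hi <- max(pos)
  starts <- seq(lo, max(lo, hi - width + 1L))
  mass <- vapply(starts, function(s)
    sum(cnt[pos >= s & pos <= s + width - 1L]), integer(1))
  best <- which.max(mass)   # which.max returns the first (leftmost) maximum
  list(window_start = starts[best],
       fraction_pct = roundHalfUp(100 * mass[best] / sum(cnt), 1L))
}

#' Read a qPCR Ct table
#'
#' TSV with columns \code{sample_id}, \code{target}, \code{ct}; targets
#' are GUS, READTHROUGH and one or more normalizers (any target named
#' \code{NORMALIZER} or prefixed \code{NORMALIZER_}).
#'
#' @param path TSV path.
#' @return a data.frame.
#' @export
readQpcrTable <- function(path) {
  if (!file.exists(path)) stop("qPCR table not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "target", "ct")
  if (!all(need %in% colnames(df)))
    stop("qPCR table needs columns ", paste(need, collapse = ", "))
  df
}

#' Read-through percentage by the 2^-ddCt method
#'
#' Per sample, dCt(target) = Ct(target) - mean(Ct of normalizers) and
#' \%readthrough = 100 x 2^-(dCt(READTHROUGH) - dCt(GUS)). The normalizer
#' terms cancel inside a sample but the normalized relative expressions
#' (2^-dCt) are retained for cross-sample comparison.
#'
#' @param qpcr a qPCR table (see \code{\link{readQpcrTable}}): sample_id,
#'   target, ct; Ct values must be positive and every sample must carry
#'   GUS, READTHROUGH and at least one normalizer.
#' @return data.frame per sample: sample_id, dct_gus, dct_readthrough,
#'   rel_gus, rel_readthrough, pct_readthrough.
#' @export
readthroughPercent <- function(qpcr) {
  if (any(qpcr$ct <= 0)) stop("Ct values must be positive")
  out <- lapply(split(qpcr, qpcr$sample_id), function(d) {
    norm <- d$ct[grepl("^NORMALIZER", d$target)]
    gus <- d$ct[d$target == "GUS"]
    rt <- d$ct[d$target == "READTHROUGH"]
    if (length(gus) != 1 || length(rt) != 1 || length(norm) < 1)
      stop("sample ", d$sample_id[1],
           ": need one GUS, one READTHROUGH and >= 1 NORMALIZER row")
    dctG <- gus - mean(norm)
    dctR <- rt - mean(norm)
    data.frame(sample_id = d$sample_id[1], dct_gus = dctG,
               dct_readthrough = dctR, rel_gus = 2^(-dctG),
               rel_readthrough = 2^(-dctR),
               pct_readthrough = 100 * 2^(-(dctR - dctG)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write report tables
#'
#' Writers for the table-style outputs: splice usage (long category form),
#' site distributions and read-through.
#'
#' @param report a \linkS4class{SpliceUsageReport}.
#' @param path TSV path.
#' @return invisibly, the path.
#' @export
writeSpliceUsage <- function(report, path) {
  write.table(as.data.frame(usageCategories(report)), path, sep = "\t",
              quote = FALSE, row.names = FALSE, na = "-")
  invisible(path)
}

#' @rdname writeSpliceUsage
#' @param dist a \linkS4class{SiteDistribution}.
#' @export
writeSiteDistribution <- function(dist, path) {
  write.table(as.data.frame(siteTable(dist)), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSpliceUsage
#' @param readthrough output of \code{\link{readthroughPercent}}.
#' @export
writeReadthrough <- function(readthrough, path) {
  write.table(readthrough, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
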