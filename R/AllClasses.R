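#' @importClassesFrom Biostrings DNAStringSet DNAString
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom IRanges IRanges CompressedIRangesList
NULL

#' GeneModels: minimal strand-resolved gene structures
#'
#' Holds, per gene, the chromosome, strand, transcription start site (first
#' transcribed base), polyadenylation site (last transcribed base) and the
#' ordered exon intervals, all 1-based inclusive in genomic coordinates.
#' Exons are stored in transcription order (descending genomic coordinates on
#' the minus strand).
#'
#' @slot genes a \linkS4class{DataFrame} with columns \code{gene_id},
#'   \code{chrom}, \code{strand}, \code{tss}, \code{polya_site}.
#' @slot exons a \linkS4class{CompressedIRangesList} named by gene_id, exon
#'   intervals in transcription order.
#' @slot seqlengths named integer vector of chromosome lengths (may be NA
#'   when unknown).
#' @exportClass GeneModels
setClass("GeneModels",
  representation(genes = "DataFrame", exons = "CompressedIRangesList",
                 seqlengths = "integer"))

setValidity("GeneModels", function(object) {
  g <- object@genes
  msgs <- character(0)
  need <- c("gene_id", "chrom", "strand", "tss", "polya_site")
  if (!all(need %in% colnames(g)))
    return(paste("genes must have columns", paste(need, collapse = ", ")))
  if (!all(g$strand %in% c("+", "-")))
    msgs <- c(msgs, "strand must be '+' or '-'")
  if (nrow(g) != length(object@exons) ||
      !identical(as.character(g$gene_id), names(object@exons)))
    return("exons must be named by gene_id, in the same order as genes")
  for (i in seq_len(nrow(g))) {
    ex <- object@exons[[i]]
    if (length(ex) == 0) { msgs <- c(msgs, "gene with no exons"); next }
    gs <- BiocGenerics::start(ex); ge <- BiocGenerics::end(ex)
    if (g$strand[i] == "+") {
      if (is.unsorted(gs, strictly = TRUE) || any(gs[-1] <= ge[-length(ge)] + 0))
        msgs <- c(msgs, paste0(g$gene_id[i], ": exons overlap or unsorted"))
      if (g$tss[i] != gs[1] || g$polya_site[i] != ge[length(ge)])
        msgs <- c(msgs, paste0(g$gene_id[i], ": tss/polya_site do not match exon bounds"))
    } else {
      if (is.unsorted(rev(gs), strictly = TRUE))
        msgs <- c(msgs, paste0(g$gene_id[i], ": exons overlap or unsorted"))
      if (g$tss[i] != ge[1] || g$polya_site[i] != gs[length(gs)])
        msgs <- c(msgs, paste0(g$gene_id[i], ": tss/polya_site do not match exon bounds"))
    }
    sl <- object@seqlengths[as.character(g$chrom[i])]
    if (!is.na(sl) && (min(gs) < 1 || max(ge) > sl))
      msgs <- c(msgs, paste0(g$gene_id[i], ": exon outside chromosome"))
  }
  if (length(msgs)) msgs else TRUE
})

#' TrainingSet: anchored, strand-resolved sequence windows
#'
#' A set of DNA windows extracted around a common anchor (TSS, 5' splice
#' site, or polyadenylation site), given in transcription orientation
#' (minus-strand windows reverse-complemented). For TSS/POLYA anchors all
#' windows share length \code{upstream + downstream} with the anchor base at
#' 0-based offset \code{upstream}; intron sets (SPLICE5 anchor) vary in
#' length and carry per-record donor/acceptor offsets.
#'
#' @slot sequences a \linkS4class{DNAStringSet}, one window per record.
#' @slot records a \linkS4class{DataFrame}: \code{gene_id}, \code{chrom},
#'   \code{gstart}, \code{gend} (genomic interval), \code{strand},
#'   \code{anchor_offset} (0-based index of the anchor base), plus for intron
#'   sets \code{donor_offset}, \code{acceptor_offset}, \code{canonical}.
#' @slot anchor one of "TSS", "SPLICE5", "POLYA".
#' @slot upstream,downstream the window specification in bp.
#' @exportClass TrainingSet
setClass("TrainingSet",
  representation(sequences = "DNAStringSet", records = "DataFrame",
                 anchor = "character", upstream = "integer",
                 downstream = "integer"))

setValidity("TrainingSet", function(object) {
  msgs <- character(0)
  if (!object@anchor %in% c("TSS", "SPLICE5", "POLYA"))
    msgs <- c(msgs, "anchor must be TSS, SPLICE5 or POLYA")
  if (length(object@sequences) != nrow(object@records))
    msgs <- c(msgs, "one record per sequence required")
  if (object@upstream < 0 || object@downstream < 0 ||
      object@upstream + object@downstream <= 0)
    msgs <- c(msgs, "upstream + downstream must be positive")
  if (length(object@sequences) > 0) {
    freq <- Biostrings::alphabetFrequency(object@sequences, collapse = TRUE)
    extra <- freq[setdiff(names(freq), c("A", "C", "G", "T", "N"))]
    if (any(extra > 0))
      msgs <- c(msgs, "sequences must be over {A,C,G,T,N}")
    if (object@anchor %in% c("TSS", "POLYA")) {
      L <- object@upstream + object@downstream
      if (!all(BiocGenerics::width(object@sequences) == L))
        msgs <- c(msgs, "all windows must have length upstream + downstream")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' PositionalProfile: per-offset nucleotide frequencies
#'
#' @slot profile 4 x L numeric matrix (rows A,C,G,T), each column summing
#'   to 1; built with a pseudocount, N bases excluded from counts.
#' @slot pseudocount the pseudocount used.
#' @slot anchorOffset 0-based offset of the training anchor within the
#'   window (NA when unknown).
#' @slot n number of training sequences.
#' @exportClass PositionalProfile
setClass("PositionalProfile",
  representation(profile = "matrix", pseudocount = "numeric",
                 anchorOffset = "integer", n = "integer"))

setValidity("PositionalProfile", function(object) {
  m <- object@profile
  if (!identical(rownames(m), c("A", "C", "G", "T")))
    return("profile rows must be A,C,G,T")
  if (ncol(m) > 0 && any(abs(colSums(m) - 1) > 1e-9))
    return("each profile column must sum to 1")
  TRUE
})

#' DesignedElement: a generated expression element with feature annotations
#'
#' @slot elementId element identifier.
#' @slot elementClass one of "PROMOTER", "INTRON", "TERMINATOR".
#' @slot sequence a \linkS4class{DNAString} over A,C,G,T.
#' @slot features an \linkS4class{IRanges} (1-based inclusive, element-local)
#'   with metadata column \code{feature} naming each interval (TATA_BOX,
#'   PREDICTED_TSS, LEADER, EXON_FLANK_5, DONOR_SITE, ACCEPTOR_SITE,
#'   IME_MOTIF, EXON_FLANK_3, NUE, CLEAVAGE_SITE, T_RICH_TRACT).
#' @slot provenance list: profile fingerprint, motif ids, constraints
#'   fingerprint, rng seed, attempt count.
#' @exportClass DesignedElement
setClass("DesignedElement",
  representation(elementId = "character", elementClass = "character",
                 sequence = "DNAString", features = "IRanges",
                 provenance = "list"))

FEATURE_NAMES <- c("TATA_BOX", "PREDICTED_TSS", "LEADER", "EXON_FLANK_5",
                   "DONOR_SITE", "ACCEPTOR_SITE", "IME_MOTIF", "EXON_FLANK_3",
                   "NUE", "CLEAVAGE_SITE", "T_RICH_TRACT")

setValidity("DesignedElement", function(object) {
  msgs <- character(0)
  if (!object@elementClass %in% c("PROMOTER", "INTRON", "TERMINATOR"))
    msgs <- c(msgs, "elementClass must be PROMOTER, INTRON or TERMINATOR")
  fr <- Biostrings::alphabetFrequency(object@sequence)
  if (sum(fr[c("A", "C", "G", "T")]) != length(object@sequence))
    msgs <- c(msgs, "sequence must be over {A,C,G,T}")
  feats <- object@features
  nm <- S4Vectors::mcols(feats)$feature
  if (is.null(nm))
    return("features must carry a 'feature' metadata column")
  if (!all(nm %in% FEATURE_NAMES))
    msgs <- c(msgs, "unknown feature name")
  if (length(feats) > 0 &&
      (min(BiocGenerics::start(feats)) < 1 ||
       max(BiocGenerics::end(feats)) > length(object@sequence)))
    msgs <- c(msgs, "feature outside element")
  w <- BiocGenerics::width(feats)
  if (any(nm %in% c("DONOR_SITE", "ACCEPTOR_SITE") & w != 2))
    msgs <- c(msgs, "DONOR_SITE/ACCEPTOR_SITE must have length 2")
  if (any(nm == "CLEAVAGE_SITE" & w != 1))
    msgs <- c(msgs, "CLEAVAGE_SITE must have length 1")
  if (length(msgs)) msgs else TRUE
})

#' CassetteModel: an expression cassette with intended transcript landmarks
#'
#' Coordinates are 1-based with the promoter 5'-most base = 1. Intended
#' junctions use the convention donor = first intronic base, acceptor = last
#' intronic base.
#'
#' @slot cassetteId reference name (matches the SAM \code{@SQ SN} field).
#' @slot length cassette length in bp.
#' @slot parts an \linkS4class{IRanges} with metadata column \code{part}
#'   (promoter, leader, intron, CDS, utr3, ...), ordered 5' to 3'.
#' @slot intendedTss intended transcription start coordinate.
#' @slot intendedJunctions \linkS4class{DataFrame} with columns \code{p5},
#'   \code{p3} (first and last intronic base of each intended intron).
#' @slot intendedPolyaSites integer vector of intended cleavage sites.
#' @exportClass CassetteModel
setClass("CassetteModel",
  representation(cassetteId = "character", length = "integer",
                 parts = "IRanges", intendedTss = "integer",
                 intendedJunctions = "DataFrame",
                 intendedPolyaSites = "integer"))

setValidity("CassetteModel", function(object) {
  msgs <- character(0)
  j <- object@intendedJunctions
  if (nrow(j) > 0) {
    if (!all(c("p5", "p3") %in% colnames(j)))
      return("intendedJunctions needs columns p5, p3")
    if (any(j$p5 >= j$p3))
      msgs <- c(msgs, "every junction must satisfy p5 < p3")
    if (any(j$p5 < 1 | j$p3 > object@length))
      msgs <- c(msgs, "junction outside cassette")
  }
  co <- c(object@intendedTss, object@intendedPolyaSites)
  if (any(co < 1 | co > object@length))
    msgs <- c(msgs, "coordinate outside cassette")
  if (length(msgs)) msgs else TRUE
})

#' CassetteAlignments: parsed spliced alignments against a cassette
#'
#' @slot readId read names.
#' @slot blocks \linkS4class{CompressedIRangesList}: per read, the aligned
#'   reference blocks (junction gaps between consecutive blocks).
#' @slot has5,has3 logical: read carries the 5'/3' sequencing adapter.
#' @slot cassetteId reference the reads were aligned to.
#' @exportClass CassetteAlignments
setClass("CassetteAlignments",
  representation(readId = "character", blocks = "CompressedIRangesList",
                 has5 = "logical", has3 = "logical", cassetteId = "character"))

setValidity("CassetteAlignments", function(object) {
  n <- length(object@readId)
  if (length(object@blocks) != n || length(object@has5) != n ||
      length(object@has3) != n)
    return("parallel slots must have one entry per read")
  st <- BiocGenerics::start(object@blocks)
  en <- BiocGenerics::end(object@blocks)
  multi <- S4Vectors::elementNROWS(object@blocks) > 1
  if (any(multi)) {
    gapok <- mapply(function(s, e) all(s[-1] - e[-length(e)] >= 2),
                    st[multi], en[multi])
    if (!all(gapok))
      return("blocks must be sorted with junction gaps >= 1")
  }
  TRUE
})

#' SpliceUsageReport: per intended splice position usage accounting
#'
#' Mirrors the published table layout: for each intended junction the
#' expected/unspliced/unexpected read counts and the percentages of reads
#' observed at the intended 5' and 3' splice positions, rounded half-up to
#' one decimal.
#'
#' @slot intended \linkS4class{DataFrame}: p5, p3, expected_count,
#'   unspliced5_count, unspliced3_count, den5, den3, pct_expected_5,
#'   pct_unspliced_5, pct_expected_3, pct_unspliced_3.
#' @slot categories \linkS4class{DataFrame} in long (table) form: intron
#'   index, donor, acceptor, category, count, pct_5, pct_3 (NA where a
#'   junction does not use the corresponding intended position).
#' @slot junctions \linkS4class{DataFrame}: the full junction table
#'   (donor, acceptor, count).
#' @exportClass SpliceUsageReport
setClass("SpliceUsageReport",
  representation(intended = "DataFrame", categories = "DataFrame",
                 junctions = "DataFrame"))

#' SiteDistribution: read-end distribution over cassette positions
#'
#' @slot kind "TSS" or "POLYA".
#' @slot total number of informative (adapter-carrying, uniquely mapped)
#'   reads.
#' @slot table \linkS4class{DataFrame}: position, count, pct (rounded to 2
#'   decimals).
#' @slot dominantSite modal position (smallest coordinate on ties).
#' @exportClass SiteDistribution
setClass("SiteDistribution",
  representation(kind = "character", total = "integer", table = "DataFrame",
                 dominantSite = "integer"))

setValidity("SiteDistribution", function(object) {
  if (!object@kind %in% c("TSS", "POLYA")) return("kind must be TSS or POLYA")
  tb <- object@table
  if (nrow(tb) > 0) {
    if (abs(sum(tb$pct) - 100) > 0.1)
      return("pct must sum to 100 +/- 0.1")
    mx <- max(tb$count)
    if (object@dominantSite != min(tb$position[tb$count == mx]))
      return("dominantSite must be the modal position (smallest on ties)")
  }
  TRUE
})
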