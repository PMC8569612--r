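#' Longest shared substring between a query and a reference set
#'
#' Exact longest common substring between the query and any reference or
#' its reverse complement, with one witness location per side. Ties are
#' broken leftmost-in-query then leftmost-in-reference; among references,
#' the first reference attaining the maximum wins, and for a single
#' reference the forward strand wins over the reverse complement on ties.
#' Reverse-complement witness intervals are reported in original reference
#' coordinates.
#'
#' @param query DNA sequence (character or \linkS4class{DNAString}),
#'   non-empty.
#' @param references a named character vector or
#'   \linkS4class{DNAStringSet}; empty set is a hard error.
#' @param queryId identifier used in the report.
#' @return a one-row \code{data.frame}: query_id, reference_id, strand,
#'   max_run_length, query_start, query_end, ref_start, ref_end.
#' @export
longestSharedSubstring <- function(query, references, queryId = "query") {
  q <- toupper(as.character(query))
  if (!nzchar(q)) stop("query must be non-empty")
  refs <- as.character(references)
  if (length(refs) == 0) stop("empty reference set")
  if (is.null(names(refs)))
    names(refs) <- sprintf("ref%d", seq_along(refs))
  best <- list(len = -1L)
  for (ri in seq_along(refs)) {
    r <- toupper(refs[[ri]])
    for (strand in c("+", "-")) {
      subject <- if (strand == "+") r else revcompChar(r)
      hit <- .lcsPair(q, subject)
      if (hit[1] > best$len) {
        rs <- hit[3]; re <- hit[3] + hit[1] - 1L
        if (strand == "-" && hit[1] > 0) {
          m <- nchar(r)
          tmp <- m - re + 1L
          re <- m - rs + 1L
          rs <- tmp
        }
        best <- list(len = hit[1], refId = names(refs)[ri], strand = strand,
                     qs = hit[2], qe = hit[2] + hit[1] - 1L,
                     rs = rs, re = re)
      }
    }
  }
  data.frame(query_id = queryId, reference_id = best$refId,
             strand = best$strand, max_run_length = best$len,
             query_start = best$qs, query_end = best$qe,
             ref_start = best$rs, ref_end = best$re,
             stringsAsFactors = FALSE)
}

#' Diversity screen of a designed element against reference genomes
#'
#' Pass/fail wrapper over \code{\link{longestSharedSubstring}}: the element
#' passes when its longest continuous identity run against any reference
#' (either strand) does not exceed \code{maxRun} bases (default 22).
#'
#' @param element a \linkS4class{DesignedElement} or DNA sequence.
#' @param references reference sequences (e.g. a toy genome).
#' @param maxRun maximum tolerated identity run in bp.
#' @return the identity-run report row with added columns
#'   \code{max_run_allowed} and \code{passed}.
#' @export
screenDiversity <- function(element, references, maxRun = 22L) {
  if (methods::is(element, "DesignedElement")) {
    rep <- longestSharedSubstring(elementSequence(element), references,
                                  queryId = elementId(element))
  } else {
    rep <- longestSharedSubstring(element, references)
  }
  rep$max_run_allowed <- as.integer(maxRun)
  rep$passed <- rep$max_run_length <= maxRun
  rep
}

#' Local alignment score against each reference (context only)
#'
#' Smith-Waterman score (match +1, mismatch -1, gap -2 per base) of the
#' query against each reference, both strands. Reported for context; no
#' threshold is attached.
#'
#' @param query DNA sequence.
#' @param references reference sequences.
#' @return data.frame: reference_id, strand, score.
#' @export
localAlignmentScores <- function(query, references) {
  q <- Biostrings::DNAString(toupper(as.character(query)))
  refs <- as.character(references)
  if (is.null(names(refs)))
    names(refs) <- sprintf("ref%d", seq_along(refs))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  rows <- lapply(seq_along(refs), function(ri) {
    r <- Biostrings::DNAString(toupper(refs[[ri]]))
    sc <- vapply(list(`+` = r, `-` = Biostrings::reverseComplement(r)),
                 function(subject)
                   Biostrings::pairwiseAlignment(
                     q, subject, type = "local",
                     substitutionMatrix = mat, gapOpening = 0,
                     gapExtension = 2, scoreOnly = TRUE),
                 numeric(1))
    data.frame(reference_id = names(refs)[ri], strand = c("+", "-"),
               score = as.numeric(sc), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Scan a sequence for ATG-initiated open reading frames
#'
#' Reports every ATG-initiated reading frame extending to the first
#' in-frame stop codon (TAA/TAG/TGA) or to the element end, with at least
#' \code{minCodons} codons (ATG plus sense codons; the stop codon is not
#' counted). Offsets are 1-based on the scanned strand's 5' to 3'
#' sequence.
#'
#' @param sequence DNA (character or \linkS4class{DNAString}).
#' @param minCodons minimum ORF length in codons.
#' @param bothStrands scan the reverse complement as well (default TRUE).
#' @return data.frame sorted by start offset: strand, frame (0-2), start,
#'   stop (last base of the ORF, stop codon included when present),
#'   length_codons, has_stop.
#' @export
scanOrfs <- function(sequence, minCodons = 10L, bothStrands = TRUE) {
  scanOne <- function(s, strandLabel) {
    n <- nchar(s)
    atg <- gregexpr("ATG", s, fixed = TRUE)[[1]]
    atg <- atg[atg != -1]
    if (length(atg) == 0)
      return(NULL)
    rows <- lapply(atg, function(a) {
      # walk codons from the ATG to the first in-frame stop
      stops <- c("TAA", "TAG", "TGA")
      i <- a
      ncod <- 0L
      hasStop <- FALSE
      stopEnd <- NA_integer_
      while (i + 2L <= n) {
        codon <- substr(s, i, i + 2L)
        if (ncod > 0L && codon %in% stops) {
          hasStop <- TRUE
          stopEnd <- i + 2L
          break
        }
        ncod <- ncod + 1L
        i <- i + 3L
      }
      if (!hasStop) stopEnd <- i - 1L   # last full codon base
      data.frame(strand = strandLabel,
                 frame = (a - 1L) %% 3L,
                 start = a, stop = stopEnd,
                 length_codons = ncod, has_stop = hasStop,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  s <- toupper(as.character(sequence))
  out <- scanOne(s, "+")
  if (bothStrands)
    out <- rbind(out, scanOne(revcompChar(s), "-"))
  if (is.null(out))
    return(data.frame(strand = character(0), frame = integer(0),
                      start = integer(0), stop = integer(0),
                      length_codons = integer(0), has_stop = logical(0)))
  out <- out[out$length_codons >= minCodons, , drop = FALSE]
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
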