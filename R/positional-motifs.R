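#' Count positional word occurrences in a training set
#'
#' Counts, for each DNA word of length \code{k} and each positional bin, the
#' number of sequences containing at least one occurrence whose start offset
#' falls in the bin (presence/absence counting: a sequence contributes at
#' most 1 to a (word, bin) pair, which stabilizes enrichment tests on
#' repetitive sequence). Bins tile the window as half-open intervals
#' \code{[0,binWidth), [binWidth,2*binWidth), ...} of start offsets. Words
#' containing N are skipped.
#'
#' @param ts a \linkS4class{TrainingSet} with length-aligned windows.
#' @param k word length (default 6).
#' @param binWidth bin width in bp (default 25; must be >= k).
#' @return a \code{data.frame} with columns \code{word}, \code{bin_start},
#'   \code{bin_end} (half-open, 0-based), \code{count}, and attributes
#'   \code{n} (number of sequences), \code{k}, \code{binWidth},
#'   \code{windowLength}.
#' @export
countPositionalWords <- function(ts, k = 6L, binWidth = 25L) {
  k <- as.integer(k); binWidth <- as.integer(binWidth)
  if (length(ts) == 0) stop("empty TrainingSet")
  L <- unique(BiocGenerics::width(ts@sequences))
  if (length(L) != 1) stop("windows must be length-aligned for word counting")
  if (k > L) stop("k exceeds window length")
  if (binWidth < k) stop("binWidth must be >= k")
  seqs <- as.character(ts@sequences)
  n <- length(seqs)
  nOff <- L - k + 1L
  # all words at all offsets, vectorized
  starts <- rep(seq_len(nOff), times = n)
  sidx <- rep(seq_len(n), each = nOff)
  words <- substring(rep(seqs, each = nOff), starts, starts + k - 1L)
  keep <- !grepl("N", words, fixed = TRUE)
  dt <- data.table::data.table(seq_idx = sidx[keep], word = words[keep],
                               bin_start = ((starts[keep] - 1L) %/% binWidth) *
                                 binWidth)
  dt <- unique(dt)
  cnt <- dt[, list(count = .N), by = list(word, bin_start)]
  data.table::setorder(cnt, bin_start, word)
  out <- data.frame(word = cnt$word, bin_start = cnt$bin_start,
                    bin_end = pmin(cnt$bin_start + binWidth, L),
                    count = cnt$count, stringsAsFactors = FALSE)
  attr(out, "n") <- n
  attr(out, "k") <- k
  attr(out, "binWidth") <- binWidth
  attr(out, "windowLength") <- L
  out
}

#' Score positional word enrichment between foreground and background
#'
#' One-sided Fisher (hypergeometric tail) test of
#' foreground-vs-background sequence counts per (word, bin), with
#' Benjamini-Hochberg adjustment across all tested pairs. Only words
#' present in the foreground are tested (one-sided enrichment). Pairs with
#' \code{q <= alpha} are returned sorted by p ascending, ties broken
#' lexicographically by (word, bin start).
#'
#' @param fg,bg positional word counts from
#'   \code{\link{countPositionalWords}}, computed with identical \code{k}
#'   and binning (mismatched binning is a hard error).
#' @param alpha FDR level (default 0.05).
#' @return a \code{data.frame}: word, bin_start, bin_end, fg_count, bg_count,
#'   fg_n, bg_n, fold_enrichment, p_value, q_value.
#' @export
scoreEnrichment <- function(fg, bg, alpha = 0.05) {
  for (a in c("k", "binWidth", "windowLength")) {
    if (!identical(attr(fg, a), attr(bg, a)))
      stop("foreground and background use different ", a)
  }
  fgN <- attr(fg, "n"); bgN <- attr(bg, "n")
  key <- function(x) paste(x$word, x$bin_start)
  bgc <- setNames(bg$count, key(bg))
  bcount <- bgc[key(fg)]
  bcount[is.na(bcount)] <- 0L
  k1 <- fg$count; k2 <- as.integer(bcount)
  m <- k1 + k2
  p <- phyper(k1 - 1L, m, fgN + bgN - m, fgN, lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")
  fold <- (k1 / fgN) / pmax(k2 / bgN, .Machine$double.xmin)
  res <- data.frame(word = fg$word, bin_start = fg$bin_start,
                    bin_end = fg$bin_end, fg_count = k1, bg_count = k2,
                    fg_n = fgN, bg_n = bgN, fold_enrichment = fold,
                    p_value = p, q_value = q, stringsAsFactors = FALSE)
  res <- res[res$q_value <= alpha, , drop = FALSE]
  res <- res[order(res$p_value, res$word, res$bin_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Merge enriched words into positional motifs
#'
#' Greedy agglomeration: seed with the most significant unassigned word;
#' absorb any unassigned word in the same bin within Hamming distance 1 of
#' the seed; the consensus is the per-position IUPAC union of the members.
#' The motif inherits the seed's p/q-value; the result is deterministic
#' because the input ordering (p ascending, then word, then bin) fixes every
#' tie.
#'
#' @param enriched output of \code{\link{scoreEnrichment}} (non-empty).
#' @return a \code{data.frame}: consensus, bin_start, bin_end, n_members,
#'   member_words (comma-separated), p_value, q_value, fold_enrichment.
#' @export
mergeWordsToMotifs <- function(enriched) {
  if (nrow(enriched) == 0) stop("no enriched words to merge")
  e <- enriched[order(enriched$p_value, enriched$word, enriched$bin_start), ]
  assigned <- rep(FALSE, nrow(e))
  out <- list()
  while (any(!assigned)) {
    i <- which(!assigned)[1]
    sameBin <- !assigned & e$bin_start == e$bin_start[i]
    member <- sameBin &
      vapply(e$word, function(w) hamming(w, e$word[i]) <= 1, logical(1))
    words <- sort(e$word[member])
    chars <- do.call(rbind, strsplit(words, ""))
    consensus <- paste(apply(chars, 2, iupacCode), collapse = "")
    out[[length(out) + 1L]] <- data.frame(
      consensus = consensus, bin_start = e$bin_start[i],
      bin_end = e$bin_end[i], n_members = length(words),
      member_words = paste(words, collapse = ","),
      p_value = e$p_value[i], q_value = e$q_value[i],
      fold_enrichment = e$fold_enrichment[i], stringsAsFactors = FALSE)
    assigned[member] <- TRUE
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build a positional nucleotide profile from a training set
#'
#' Per-offset base frequencies with a pseudocount:
#' \code{freq = (count + pseudocount) / (n_effective + 4 * pseudocount)},
#' where N bases are excluded from counts (\code{n_effective} is the number
#' of non-N observations at the offset). With no observations and a
#' positive pseudocount a column is uniform 0.25.
#'
#' @param ts a length-aligned \linkS4class{TrainingSet}.
#' @param pseudocount nonnegative pseudocount (default 1).
#' @return a \linkS4class{PositionalProfile}.
#' @export
buildPositionalProfile <- function(ts, pseudocount = 1) {
  if (length(ts) == 0) stop("empty TrainingSet")
  seqs <- ts@sequences
  L <- unique(BiocGenerics::width(seqs))
  if (length(L) != 1) {
    # variable-length sets (introns) share their anchor offset from the
    # window start, so the common prefix is position-aligned
    L <- min(L)
    seqs <- Biostrings::subseq(seqs, 1L, L)
  }
  cm <- Biostrings::consensusMatrix(seqs, baseOnly = TRUE)
  counts <- cm[c("A", "C", "G", "T"), , drop = FALSE]
  nEff <- colSums(counts)
  denom <- nEff + 4 * pseudocount
  if (any(denom == 0))
    stop("offset with no observations and zero pseudocount")
  prof <- sweep(counts + pseudocount, 2, denom, "/")
  rownames(prof) <- c("A", "C", "G", "T")
  methods::new("PositionalProfile", profile = prof,
               pseudocount = as.numeric(pseudocount),
               anchorOffset = ts@upstream, n = length(ts))
}

#' Dinucleotide-preserving shuffle of a training set
#'
#' Background-set utility: shuffles each window with an Eulerian-path
#' dinucleotide shuffle (first and last base fixed, dinucleotide
#' composition preserved), deterministic for a fixed seed.
#'
#' @param ts a \linkS4class{TrainingSet}.
#' @param seed integer seed.
#' @return a \linkS4class{TrainingSet} of shuffled windows.
#' @export
shuffleTrainingSet <- function(ts, seed) {
  withSeed(seed, {
    shuf <- vapply(as.character(ts@sequences), dinucShuffle, character(1))
  })
  ss <- Biostrings::DNAStringSet(unname(shuf))
  names(ss) <- names(ts@sequences)
  methods::new("TrainingSet", sequences = ss, records = ts@records,
               anchor = ts@anchor, upstream = ts@upstream,
               downstream = ts@downstream)
}

# Altschul-Erickson style dinucleotide shuffle via random last-edge
# selection; falls back to the identity for length < 3.
dinucShuffle <- function(s) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  if (n < 3) return(s)
  alphabet <- unique(ch)
  edges <- split(ch[-1], factor(ch[-n], levels = alphabet))
  last <- ch[n]
  # choose a random last edge into each vertex (except the terminal vertex)
  # such that the chosen edges form a tree rooted at the terminal; retry on
  # failure (connectivity is guaranteed for an observed walk, a rooted tree
  # sample almost surely succeeds within a few tries)
  for (tryi in 1:100) {
    lastEdge <- list()
    ok <- TRUE
    for (v in alphabet) {
      if (v == last) next
      outs <- edges[[v]]
      if (length(outs) == 0) { ok <- FALSE; break }
      lastEdge[[v]] <- sample(outs, 1L)
    }
    if (!ok) break
    # check the chosen edges lead every vertex to `last`
    reaches <- function(v) {
      seen <- character(0)
      while (v != last) {
        if (v %in% seen || is.null(lastEdge[[v]])) return(FALSE)
        seen <- c(seen, v)
        v <- lastEdge[[v]]
      }
      TRUE
    }
    if (all(vapply(setdiff(alphabet, last), reaches, logical(1)))) {
      # shuffle the remaining edges and walk
      pool <- lapply(setNames(alphabet, alphabet), function(v) {
        outs <- edges[[v]]
        if (v != last) {
          j <- match(lastEdge[[v]], outs)
          outs <- c(sample(outs[-j]), outs[j])
        } else outs <- sample(outs)
        outs
      })
      ptr <- setNames(rep(1L, length(alphabet)), alphabet)
      res <- character(n)
      res[1] <- ch[1]
      v <- ch[1]
      for (i in 2:n) {
        nxt <- pool[[v]][ptr[[v]]]
        ptr[[v]] <- ptr[[v]] + 1L
        res[i] <- nxt
        v <- nxt
      }
      return(paste(res, collapse = ""))
    }
  }
  # degenerate composition: plain permutation of interior
  paste(c(ch[1], sample(ch[2:(n - 1)]), ch[n]), collapse = "")
}

#' Write motif and profile tables
#'
#' @param motifs output of \code{\link{mergeWordsToMotifs}}.
#' @param path TSV path.
#' @return invisibly, the path.
#' @export
writeMotifTable <- function(motifs, path) {
  write.table(motifs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMotifTable
#' @param profile a \linkS4class{PositionalProfile}.
#' @export
writeProfileTable <- function(profile, path) {
  m <- t(profileMatrix(profile))
  df <- data.frame(offset = seq_len(nrow(m)) - 1L, m)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
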