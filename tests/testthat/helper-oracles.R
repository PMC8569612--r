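# Independent oracles used to cross-check package operations. Each is a
# deliberately different formulation from the implementation it checks.

rcomp <- function(x) as.character(
  Biostrings::reverseComplement(Biostrings::DNAString(x)))

randomDna <- function(n, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# Longest common substring length by scanning equality runs along every
# diagonal (the Rcpp implementation is a rolling-row DP; this is the same
# O(n*m) bound through a different decomposition).
oracleLcsLen <- function(q, r) {
  qc <- strsplit(q, "")[[1]]; rc <- strsplit(r, "")[[1]]
  n <- length(qc); m <- length(rc)
  best <- 0L
  for (d in (-(n - 1L)):(m - 1L)) {
    qi <- max(1L, 1L - d); ri <- qi + d
    len <- min(n - qi, m - ri) + 1L
    eq <- qc[qi:(qi + len - 1L)] == rc[ri:(ri + len - 1L)]
    rl <- rle(eq)
    hit <- rl$lengths[rl$values]
    if (length(hit) > 0) best <- max(best, max(hit))
  }
  best
}

oracleLcsStranded <- function(q, r) {
  max(oracleLcsLen(q, r), oracleLcsLen(q, rcomp(r)))
}

# One-sided Fisher p by direct tail enumeration from binomial coefficients
# (the implementation calls phyper).
oracleFisherP <- function(k1, k2, n1, n2) {
  m <- k1 + k2; N <- n1 + n2
  j <- k1:min(n1, m)
  sum(exp(lchoose(m, j) + lchoose(N - m, n1 - j) - lchoose(N, n1)))
}

# Six-frame ORF scan by per-frame codon translation (the implementation
# walks codons from each ATG).
oracleOrfs <- function(s, minCodons, bothStrands = TRUE) {
  stops <- c("TAA", "TAG", "TGA")
  out <- list()
  strands <- if (bothStrands) c("+", "-") else "+"
  for (strand in strands) {
    x <- if (strand == "+") s else rcomp(s)
    n <- nchar(x)
    for (f in 0:2) {
      cstarts <- seq(f + 1L, n - 2L, by = 3L)
      if (length(cstarts) == 0) next
      codons <- substring(x, cstarts, cstarts + 2L)
      atg <- which(codons == "ATG")
      stp <- which(codons %in% stops)
      for (a in atg) {
        later <- stp[stp > a]
        if (length(later) > 0) {
          k <- min(later)
          ncod <- k - a
          stopEnd <- cstarts[k] + 2L
          hasStop <- TRUE
        } else {
          ncod <- length(codons) - a + 1L
          stopEnd <- cstarts[length(codons)] + 2L
          hasStop <- FALSE
        }
        if (ncod >= minCodons)
          out[[length(out) + 1L]] <- data.frame(
            strand = strand, frame = f, start = cstarts[a], stop = stopEnd,
            length_codons = ncod, has_stop = hasStop,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(strand = character(0), frame = integer(0),
                      start = integer(0), stop = integer(0),
                      length_codons = integer(0), has_stop = logical(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Per-read junction tabulation with an environment as the counter (the
# implementation vectorizes with data.table).
oracleJunctions <- function(reads) {
  env <- new.env()
  bl <- readBlocks(reads)
  for (i in seq_along(bl)) {
    b <- bl[[i]]
    if (length(b) < 2) next
    for (k in seq_len(length(b) - 1L)) {
      key <- paste(BiocGenerics::end(b)[k] + 1L,
                   BiocGenerics::start(b)[k + 1L] - 1L)
      env[[key]] <- (env[[key]] %||oracle% 0L) + 1L
    }
  }
  keys <- ls(env)
  if (length(keys) == 0)
    return(data.frame(donor = integer(0), acceptor = integer(0),
                      count = integer(0)))
  parts <- do.call(rbind, strsplit(keys, " "))
  res <- data.frame(donor = as.integer(parts[, 1]),
                    acceptor = as.integer(parts[, 2]),
                    count = vapply(keys, function(k) env[[k]], integer(1)))
  res <- res[order(res$donor, res$acceptor), , drop = FALSE]
  rownames(res) <- NULL
  res
}

`%||oracle%` <- function(a, b) if (is.null(a)) b else a

# Presence/absence word counting by explicit triple loop.
oracleWordCounts <- function(seqs, k, binWidth) {
  seen <- new.env()
  L <- nchar(seqs[1])
  for (si in seq_along(seqs)) {
    s <- seqs[si]
    for (o in 1:(L - k + 1L)) {
      w <- substr(s, o, o + k - 1L)
      if (grepl("N", w, fixed = TRUE)) next
      bin <- ((o - 1L) %/% binWidth) * binWidth
      seen[[paste(si, w, bin)]] <- TRUE
    }
  }
  keys <- ls(seen)
  parts <- do.call(rbind, strsplit(keys, " "))
  df <- data.frame(word = parts[, 2], bin_start = as.integer(parts[, 3]))
  agg <- aggregate(list(count = rep(1L, nrow(df))),
                   by = list(word = df$word, bin_start = df$bin_start),
                   FUN = sum)
  agg <- agg[order(agg$bin_start, agg$word), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
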