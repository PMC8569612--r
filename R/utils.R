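#' @import methods
#' @importFrom stats phyper p.adjust runif setNames
#' @importFrom utils head tail packageVersion write.table read.delim
#' @useDynLib plantElements, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom data.table data.table setorder :=
NULL

.datatable.aware <- TRUE

# Round half away from zero at `digits` decimals (report convention; base
# round() is round-half-even). A tiny epsilon absorbs binary representation
# error on values like 82.55 arising from count ratios.
roundHalfUp <- function(x, digits = 1L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5 + 1e-9) / f
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores \code{.Random.seed} so seeded package operations do not
#' disturb the caller's RNG stream.
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Polynomial rolling hash over a deparsed object; used only for provenance
# fingerprints (not cryptographic).
fingerprint <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# IUPAC code for a set of concrete bases
iupacCode <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  codes <- c(A = "A", C = "C", G = "G", T = "T",
             AG = "R", CT = "Y", CG = "S", AT = "W", GT = "K", AC = "M",
             CGT = "B", AGT = "D", ACT = "H", ACG = "V", ACGT = "N")
  out <- codes[[key]]
  if (is.null(out)) stop("not a base set: ", key)
  out
}

# Does concrete base `b` match IUPAC code `code`?
iupacMatches <- function(b, code) b %in% IUPAC_SETS[[code]]

# Match an IUPAC pattern against a concrete sequence string; returns start
# offsets (1-based). Uses Biostrings with fixed=FALSE.
iupacFind <- function(pattern, subject) {
  if (nchar(subject) < nchar(pattern)) return(integer(0))
  m <- Biostrings::matchPattern(Biostrings::DNAString(pattern),
                                Biostrings::DNAString(subject),
                                fixed = FALSE)
  BiocGenerics::start(m)
}

# Concretize an IUPAC pattern by sampling each degenerate position uniformly
# (caller controls the RNG state).
concretizeIupac <- function(pattern) {
  ch <- strsplit(pattern, "")[[1]]
  paste(vapply(ch, function(b) {
    s <- IUPAC_SETS[[b]]
    if (is.null(s)) stop("unknown IUPAC code: ", b)
    if (length(s) == 1L) s else sample(s, 1L)
  }, character(1)), collapse = "")
}

revcompChar <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Assert DNA over A,C,G,T,N; hard error on other ambiguity codes.
assertPlainDNA <- function(seqs, what = "sequence") {
  freq <- Biostrings::alphabetFrequency(seqs, collapse = TRUE)
  bad <- freq[setdiff(names(freq), c("A", "C", "G", "T", "N", "other"))]
  bad <- bad[bad > 0]
  if (length(bad) > 0)
    stop(what, " contains ambiguity codes other than N: ",
         paste(names(bad), collapse = ", "))
  invisible(TRUE)
}

# data.table non-standard-eval columns
utils::globalVariables(c(
  "word", "bin_start", "seq_idx", "p_value", "q_value", "donor", "acceptor",
  "count", "N", "gene_id", "position", "pct", "target", "ct", "sample_id"
))
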