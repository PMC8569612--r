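#' ConstraintReport: result of validating an element against its
#' design constraints
#'
#' @slot violations \linkS4class{DataFrame}: constraint, start, end,
#'   message (1-based element-local intervals).
#' @slot passed TRUE iff there are no violations.
#' @exportClass ConstraintReport
setClass("ConstraintReport",
  representation(violations = "DataFrame", passed = "logical"))

setValidity("ConstraintReport", function(object) {
  if (object@passed != (nrow(object@violations) == 0))
    return("passed must be TRUE exactly when violations is empty")
  TRUE
})

setMethod("show", "ConstraintReport", function(object) {
  if (object@passed) cat("ConstraintReport: passed\n")
  else {
    cat("ConstraintReport:", nrow(object@violations), "violation(s)\n")
    print(as.data.frame(object@violations))
  }
})

#' @rdname accessors
#' @export
setGeneric("violations", function(x) standardGeneric("violations"))
#' @rdname accessors
#' @export
setMethod("violations", "ConstraintReport", function(x) x@violations)

#' @rdname accessors
#' @export
setGeneric("passed", function(x) standardGeneric("passed"))
#' @rdname accessors
#' @export
setMethod("passed", "ConstraintReport", function(x) x@passed)

designDefaults <- function(elementClass) {
  common <- list(maxAttempts = 1000L, maxRepairs = 10L, lengthTolerance = 0L)
  cls <- switch(elementClass,
    PROMOTER = list(
      targetLength = 500L,
      tataPattern = "TATAAA",      # stamped TATA box
      tataToTssSpacing = 30L,      # bases strictly between TATA box and TSS
      leaderLength = 50L,          # 5' UTR leader incl. the TSS base
      inrPattern = "YA"),          # pyrimidine-purine initiator, TSS base A
    INTRON = list(
      targetLength = 300L,         # intron length between the splice sites
      flankLength = 5L,
      donorConsensus = "GT",
      acceptorConsensus = "AG",
      forbiddenInternal = "GTAAG", # donor-like words banned inside the intron
      forbidAcceptorLike = TRUE,   # CAG after a pyrimidine run
      pyRunMin = 6L,
      # Placeholder standing in for enhancement motifs whose exact sequences
      # are not fixed by the design procedure; supply real motifs in config.
      imeMotifs = "TTNGATYTG",
      imeWindow = c(10L, 150L)),   # placement window, 1-based within intron
    TERMINATOR = list(
      targetLength = 300L,
      nPolyaSites = 2L,
      nuePattern = "AATAAA",
      nueSpacing = c(10L, 30L),    # bases between NUE end and cleavage site
      tTractMinRun = 8L,
      siteSeparation = 60L,        # spacing between successive cleavage sites
      distalOffset = 40L),         # distal site this far before element end
    stop("elementClass must be PROMOTER, INTRON or TERMINATOR"))
  c(list(elementClass = elementClass), cls, common)
}

#' Design constraints for an element class
#'
#' Returns the full constraint set for one element class, starting from
#' built-in defaults and overriding any field passed as a named argument.
#' All fields are also settable from a YAML config file
#' (\code{\link{readDesignConfig}}); \code{\link{dumpDesignConfig}} prints
#' every default.
#'
#' @param elementClass "PROMOTER", "INTRON" or "TERMINATOR".
#' @param ... named overrides of the class defaults.
#' @return a named list of constraints (class \code{"DesignConstraints"}).
#' @export
designConstraints <- function(elementClass, ...) {
  cons <- designDefaults(elementClass)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cons))
  if (length(bad) > 0)
    stop("unknown constraint field(s): ", paste(bad, collapse = ", "))
  cons[names(dots)] <- dots
  if (cons$targetLength <= 0) stop("targetLength must be positive")
  if (elementClass == "TERMINATOR" && diff(cons$nueSpacing) < 0)
    stop("nueSpacing range is empty")
  structure(cons, class = "DesignConstraints")
}

#' Read design constraints from a YAML config file
#'
#' Top-level keys are element classes (\code{promoter}, \code{intron},
#' \code{terminator}); their values override the built-in defaults.
#'
#' @param path YAML file.
#' @param elementClass which class to extract.
#' @return a \code{"DesignConstraints"} list.
#' @export
readDesignConfig <- function(path, elementClass) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  key <- tolower(elementClass)
  ov <- cfg[[key]]
  if (is.null(ov)) ov <- list()
  do.call(designConstraints, c(list(elementClass = elementClass), ov))
}

#' Print all design constraint defaults as YAML
#'
#' @param file connection or path (default stdout).
#' @return invisibly, the YAML text.
#' @export
dumpDesignConfig <- function(file = stdout()) {
  cfg <- list(promoter = designDefaults("PROMOTER"),
              intron = designDefaults("INTRON"),
              terminator = designDefaults("TERMINATOR"))
  txt <- yaml::as.yaml(cfg)
  cat(txt, file = file)
  invisible(txt)
}

# Sample element bases from profile columns [profFrom, profFrom+len-1]
# (1-based columns); columns outside the profile fall back to the profile's
# overall base composition.
sampleFromProfile <- function(profile, profFrom, len) {
  m <- profileMatrix(profile)
  overall <- rowMeans(m)
  bases <- c("A", "C", "G", "T")
  cols <- seq(profFrom, length.out = len)
  vapply(cols, function(j) {
    p <- if (j >= 1 && j <= ncol(m)) m[, j] else overall
    sample(bases, 1L, prob = p)
  }, character(1))
}

# Resample position i from its profile column excluding `not` bases;
# uniform over the remaining bases if the column leaves no mass.
resampleBase <- function(ch, i, profile, profFrom, not) {
  m <- profileMatrix(profile)
  bases <- c("A", "C", "G", "T")
  j <- profFrom + i - 1L
  p <- if (j >= 1 && j <= ncol(m)) m[, j] else rowMeans(m)
  keep <- setdiff(bases, not)
  p <- p[keep]
  if (sum(p) <= 0) p <- rep(1, length(keep))
  ch[i] <- sample(keep, 1L, prob = p)
  ch
}

featureRanges <- function(starts, ends, names) {
  ir <- IRanges::IRanges(start = starts, end = ends)
  S4Vectors::mcols(ir)$feature <- names
  ir
}

newElement <- function(id, cls, ch, features, profile, motifIds, cons, seed,
                       attempts) {
  methods::new("DesignedElement", elementId = id, elementClass = cls,
               sequence = Biostrings::DNAString(paste(ch, collapse = "")),
               features = features,
               provenance = list(
                 profile_id = fingerprint(profileMatrix(profile)),
                 motif_ids = motifIds,
                 constraints_hash = fingerprint(unclass(cons)),
                 seed = seed, attempts = attempts))
}

# Stamp enriched motifs at bin-consistent element positions. `shift` maps a
# 0-based profile offset o to element position o - shift + 1. Intervals in
# `reserved` (IRanges) are never overwritten. Returns list(ch, stamped).
stampMotifs <- function(ch, motifs, shift, reserved) {
  stampedIds <- character(0)
  stamped <- IRanges::IRanges()
  if (is.null(motifs) || nrow(motifs) == 0)
    return(list(ch = ch, stamped = stamped, ids = stampedIds))
  L <- length(ch)
  for (r in seq_len(nrow(motifs))) {
    cons <- motifs$consensus[r]
    wlen <- nchar(cons)
    lo <- motifs$bin_start[r]; hi <- motifs$bin_end[r] - wlen
    if (hi < lo) next
    offs <- sample(seq(lo, hi), 1L)            # 0-based profile offset
    epos <- offs - shift + 1L                  # 1-based element position
    if (epos < 1L || epos + wlen - 1L > L) next
    cand <- IRanges::IRanges(epos, epos + wlen - 1L)
    if (length(reserved) > 0 &&
        sum(IRanges::countOverlaps(cand, reserved)) > 0) next
    if (length(stamped) > 0 &&
        sum(IRanges::countOverlaps(cand, stamped)) > 0) next
    word <- concretizeIupac(cons)
    ch[epos:(epos + wlen - 1L)] <- strsplit(word, "")[[1]]
    stamped <- c(stamped, cand)
    stampedIds <- c(stampedIds, sprintf("%s@%d", cons, offs))
  }
  list(ch = ch, stamped = stamped, ids = stampedIds)
}

#' Design a promoter + 5' UTR leader element
#'
#' Generates a promoter of \code{targetLength} bp by per-offset sampling
#' from a positional profile (anchored at the TSS) with enriched motifs
#' stamped at bin-consistent offsets, then places the structural core:
#' a TATA box, exactly \code{tataToTssSpacing} bases, the predicted TSS with
#' a pyrimidine-purine initiator (TSS base A), and an ATG-free leader to the
#' element 3' end. Start codons at or downstream of the predicted TSS are
#' repaired by local resampling (up to \code{maxRepairs} sweeps); if a
#' sampled attempt cannot be repaired a fresh attempt is drawn, up to
#' \code{maxAttempts}, after which the unsatisfiable constraint is named in
#' a hard error. Deterministic for fixed (inputs, seed).
#'
#' @param profile a \linkS4class{PositionalProfile} built from promoter
#'   training windows (window length must be >= targetLength).
#' @param motifs optional motif table from \code{\link{mergeWordsToMotifs}}
#'   (bins in profile window offsets).
#' @param constraints a \code{"DesignConstraints"} list of class PROMOTER.
#' @param seed integer seed (required).
#' @param elementId identifier for the design.
#' @return a \linkS4class{DesignedElement} that passes
#'   \code{\link{validateElement}}.
#' @export
designPromoter <- function(profile, motifs = NULL, constraints = designConstraints("PROMOTER"),
                           seed, elementId = sprintf("GSP_s%d", seed)) {
  stopifnot(constraints$elementClass == "PROMOTER")
  L <- constraints$targetLength
  if (ncol(profileMatrix(profile)) < L)
    stop("profile window length is smaller than targetLength")
  leaderLen <- constraints$leaderLength
  spacing <- constraints$tataToTssSpacing
  tata <- constraints$tataPattern
  tlen <- nchar(tata)
  tssPos <- L - leaderLen + 1L
  tataEnd <- tssPos - spacing - 1L
  tataStart <- tataEnd - tlen + 1L
  if (tataStart < 1L || tssPos < 2L)
    stop("infeasible promoter geometry: targetLength too small for ",
         "leaderLength + tataToTssSpacing + TATA box")
  a0 <- anchorOffset(profile)
  shift <- if (!is.na(a0)) a0 - (tssPos - 1L)
           else ncol(profileMatrix(profile)) - L
  profFrom <- shift + 1L
  withSeed(seed, {
    for (attempt in seq_len(constraints$maxAttempts)) {
      ch <- sampleFromProfile(profile, profFrom, L)
      reserved <- IRanges::IRanges(tataStart, L)  # structural core + leader
      st <- stampMotifs(ch, motifs, shift, reserved)
      ch <- st$ch
      # structural core
      ch[tataStart:tataEnd] <- strsplit(tata, "")[[1]]
      inr <- strsplit(constraints$inrPattern, "")[[1]]
      ch[tssPos - 1L] <- concretizeIupac(inr[1])
      ch[tssPos] <- concretizeIupac(inr[2])
      # repair ATGs at or downstream of the TSS
      ok <- FALSE
      for (sweep in seq_len(constraints$maxRepairs)) {
        hits <- findAtg(ch, tssPos)
        if (length(hits) == 0) { ok <- TRUE; break }
        for (h in hits) {
          i <- h + 1L                     # the 'T'; never the fixed TSS 'A'
          ch <- resampleBase(ch, i, profile, profFrom, not = "T")
        }
      }
      if (!ok) next
      feats <- featureRanges(
        c(tataStart, tssPos, tssPos),
        c(tataEnd, tssPos, L),
        c("TATA_BOX", "PREDICTED_TSS", "LEADER"))
      if (length(st$stamped) > 0) {
        S4Vectors::mcols(st$stamped)$feature <- NULL
        # stamped motifs are provenance, not named features
      }
      el <- newElement(elementId, "PROMOTER", ch, feats, profile, st$ids,
                       constraints, seed, attempt)
      rep <- validateElement(el, constraints = constraints)
      if (passed(rep)) return(el)
    }
  })
  stop("design_promoter: rejection-sampling budget exhausted ",
       "(unsatisfiable constraint: ATG_FREE_LEADER)")
}

findAtg <- function(ch, fromPos) {
  s <- paste(ch, collapse = "")
  hits <- gregexpr("ATG", s, fixed = TRUE)[[1]]
  hits <- hits[hits != -1]
  hits[hits >= fromPos]
}

#' Design an intron element with exonic flanks
#'
#' Element = 5' exonic flank + intron + 3' exonic flank, with a canonical
#' GT donor at the intron start and AG acceptor at the intron end, no
#' donor-like or acceptor-like forbidden pattern strictly between the
#' intended sites, and at least one enhancement (IME) motif placed inside
#' the intron within its placement window. Interior bases violating the
#' forbidden-pattern constraints are resampled locally before an attempt is
#' rejected.
#'
#' @inheritParams designPromoter
#' @param constraints class INTRON constraints; \code{targetLength} is the
#'   intron length, so the element has \code{targetLength + 2*flankLength}
#'   bases.
#' @return a \linkS4class{DesignedElement}.
#' @export
designIntron <- function(profile, motifs = NULL, constraints = designConstraints("INTRON"),
                         seed, elementId = sprintf("GSI_s%d", seed)) {
  stopifnot(constraints$elementClass == "INTRON")
  ilen <- constraints$targetLength
  fl <- constraints$flankLength
  total <- ilen + 2L * fl
  intronStart <- fl + 1L
  intronEnd <- fl + ilen
  if (ilen < 60L)
    stop("infeasible intron geometry: targetLength too small")
  # align profile donor anchor (offset = flank in training windows) to the
  # element donor
  a0 <- anchorOffset(profile)
  shift <- if (!is.na(a0)) a0 - (intronStart - 1L) else 0L
  profFrom <- shift + 1L
  ime <- constraints$imeMotifs
  win <- constraints$imeWindow
  withSeed(seed, {
    for (attempt in seq_len(constraints$maxAttempts)) {
      ch <- sampleFromProfile(profile, profFrom, total)
      st <- stampMotifs(ch, motifs, shift,
                        IRanges::IRanges(c(1L, intronEnd - 1L),
                                         c(intronStart + 1L, total)))
      ch <- st$ch
      # structural core
      ch[intronStart:(intronStart + 1L)] <- strsplit(constraints$donorConsensus, "")[[1]]
      ch[(intronEnd - 1L):intronEnd] <- strsplit(constraints$acceptorConsensus, "")[[1]]
      # place one IME motif inside the intron within its window
      motif <- if (length(ime) == 1L) ime else sample(ime, 1L)
      wlen <- nchar(motif)
      lo <- max(win[1], 3L)                       # clear of the donor
      hi <- min(win[2] - wlen + 1L, ilen - wlen - 1L)  # clear of the acceptor
      if (hi < lo)
        stop("infeasible IME placement window for motif ", motif)
      imeRel <- sample(seq(lo, hi), 1L)
      imeStart <- fl + imeRel                     # element coordinates
      imeEnd <- imeStart + wlen - 1L
      ch[imeStart:imeEnd] <- strsplit(concretizeIupac(motif), "")[[1]]
      protected <- IRanges::IRanges(
        c(intronStart, intronEnd - 1L, imeStart),
        c(intronStart + 1L, intronEnd, imeEnd))
      # repair forbidden internal patterns
      interior <- c(intronStart + 2L, intronEnd - 2L)
      ok <- FALSE
      for (sweep in seq_len(constraints$maxRepairs)) {
        hits <- findForbidden(ch, interior, constraints)
        if (nrow(hits) == 0) { ok <- TRUE; break }
        progressed <- FALSE
        for (r in seq_len(nrow(hits))) {
          cand <- seq(hits$start[r], hits$end[r])
          free <- cand[!IRanges::overlapsAny(
            IRanges::IRanges(cand, cand), protected)]
          if (length(free) == 0) next
          i <- free[(length(free) + 1L) %/% 2L]
          ch <- resampleBase(ch, i, profile, profFrom, not = ch[i])
          progressed <- TRUE
        }
        if (!progressed) break
      }
      if (!ok) next
      feats <- featureRanges(
        c(1L, intronStart, imeStart, intronEnd - 1L, intronEnd + 1L),
        c(fl, intronStart + 1L, imeEnd, intronEnd, total),
        c("EXON_FLANK_5", "DONOR_SITE", "IME_MOTIF", "ACCEPTOR_SITE",
          "EXON_FLANK_3"))
      el <- newElement(elementId, "INTRON", ch, feats, profile, st$ids,
                       constraints, seed, attempt)
      rep <- validateElement(el, constraints = constraints)
      if (passed(rep)) return(el)
    }
  })
  stop("design_intron: rejection-sampling budget exhausted ",
       "(unsatisfiable constraint: FORBIDDEN_INTERNAL)")
}

# Find forbidden pattern occurrences whose full interval lies inside
# region = c(from, to) (1-based inclusive element coordinates).
findForbidden <- function(ch, region, constraints) {
  s <- paste(ch, collapse = "")
  out <- list()
  for (pat in constraints$forbiddenInternal) {
    if (!nzchar(pat)) next
    hits <- iupacFind(pat, s)
    for (h in hits) {
      e <- h + nchar(pat) - 1L
      if (h >= region[1] && e <= region[2])
        out[[length(out) + 1L]] <- data.frame(start = h, end = e,
                                              what = pat)
    }
  }
  if (isTRUE(constraints$forbidAcceptorLike)) {
    k <- constraints$pyRunMin
    rex <- sprintf("(?=([CT]{%d}CAG))", k)
    m <- gregexpr(rex, s, perl = TRUE)[[1]]
    starts <- m[m != -1]
    for (h in starts) {
      e <- h + k + 2L
      if (h >= region[1] && e <= region[2])
        out[[length(out) + 1L]] <- data.frame(start = h, end = e,
                                              what = "acceptor-like")
    }
  }
  if (length(out) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      what = character(0)))
  unique(do.call(rbind, out))
}

#' Design a 3' UTR terminator element
#'
#' Generates a terminator carrying exactly \code{nPolyaSites} cleavage
#' sites. Each cleavage site is an A preceded by a pyrimidine (YA
#' dinucleotide) with a near-upstream element (\code{nuePattern}, default
#' AATAAA) ending a seeded 10-30 bases upstream; a T-rich tract of at least
#' \code{tTractMinRun} consecutive T's ends immediately before the distal
#' (3'-most) cleavage site.
#'
#' @inheritParams designPromoter
#' @param constraints class TERMINATOR constraints.
#' @return a \linkS4class{DesignedElement}.
#' @export
designTerminator <- function(profile, motifs = NULL, constraints = designConstraints("TERMINATOR"),
                             seed, elementId = sprintf("GST_s%d", seed)) {
  stopifnot(constraints$elementClass == "TERMINATOR")
  L <- constraints$targetLength
  nSites <- constraints$nPolyaSites
  sep <- constraints$siteSeparation
  run <- constraints$tTractMinRun
  sites <- L - constraints$distalOffset - sep * (nSites:1 - 1L)
  spMax <- constraints$nueSpacing[2]
  if (sites[1] - spMax - nchar(constraints$nuePattern) < 1L)
    stop("infeasible terminator geometry: first NUE before element start")
  if (nSites >= 2L && sep <= run + spMax)
    warning("cleavage sites closer than tract + NUE spacing may collide",
            call. = FALSE)
  a0 <- anchorOffset(profile)
  # align the distal cleavage site to the profile anchor when known
  shift <- if (!is.na(a0)) a0 - (sites[nSites] - 1L) else 0L
  profFrom <- shift + 1L
  withSeed(seed, {
    for (attempt in seq_len(constraints$maxAttempts)) {
      ch <- sampleFromProfile(profile, profFrom, L)
      st <- stampMotifs(ch, motifs, shift,
                        IRanges::IRanges(min(sites) - spMax - 6L, L))
      ch <- st$ch
      nue <- strsplit(constraints$nuePattern, "")[[1]]
      featS <- integer(0); featE <- integer(0); featN <- character(0)
      okGeom <- TRUE
      for (i in seq_len(nSites)) {
        ci <- sites[i]
        s <- sample(seq(constraints$nueSpacing[1], constraints$nueSpacing[2]), 1L)
        ne <- ci - s - 1L
        ns <- ne - length(nue) + 1L
        if (ns < 1L) { okGeom <- FALSE; break }
        ch[ns:ne] <- nue
        ch[ci] <- "A"
        if (i == nSites) {
          ch[(ci - run):(ci - 1L)] <- "T"   # tract ends at the distal site
          featS <- c(featS, ci - run); featE <- c(featE, ci - 1L)
          featN <- c(featN, "T_RICH_TRACT")
        } else if (!ch[ci - 1L] %in% c("C", "T")) {
          ch[ci - 1L] <- "T"
        }
        featS <- c(featS, ns, ci); featE <- c(featE, ne, ci)
        featN <- c(featN, "NUE", "CLEAVAGE_SITE")
      }
      if (!okGeom) next
      feats <- featureRanges(featS, featE, featN)
      el <- newElement(elementId, "TERMINATOR", ch, feats, profile, st$ids,
                       constraints, seed, attempt)
      rep <- validateElement(el, constraints = constraints)
      if (passed(rep)) return(el)
    }
  })
  stop("design_terminator: rejection-sampling budget exhausted ",
       "(unsatisfiable constraint: POLYA_GEOMETRY)")
}

#' Validate an element against its class constraints
#'
#' Checks every hard constraint of the corresponding design operation
#' independently and reports all violations with their intervals;
#' validation never throws on sequence content.
#'
#' @param x a \linkS4class{DesignedElement}, or a DNA sequence (character or
#'   \linkS4class{DNAString}) when \code{features} is supplied.
#' @param features an \linkS4class{IRanges} with metadata column
#'   \code{feature} (ignored when \code{x} is a DesignedElement).
#' @param constraints a \code{"DesignConstraints"} list.
#' @return a \linkS4class{ConstraintReport}.
#' @export
validateElement <- function(x, features = NULL, constraints) {
  if (methods::is(x, "DesignedElement")) {
    s <- as.character(elementSequence(x))
    features <- elementFeatures(x)
  } else {
    s <- as.character(x)
    if (is.null(features)) stop("features required when x is a sequence")
  }
  ch <- strsplit(s, "")[[1]]
  nm <- S4Vectors::mcols(features)$feature
  fstart <- BiocGenerics::start(features)
  fend <- BiocGenerics::end(features)
  v <- list()
  flag <- function(constraint, start, end, message)
    v[[length(v) + 1L]] <<- data.frame(constraint = constraint,
                                       start = start, end = end,
                                       message = message,
                                       stringsAsFactors = FALSE)
  featSeq <- function(i) substr(s, fstart[i], fend[i])
  L <- length(ch)
  tol <- constraints$lengthTolerance

  if (constraints$elementClass == "PROMOTER") {
    if (abs(L - constraints$targetLength) > tol)
      flag("TARGET_LENGTH", 1L, L,
           sprintf("length %d vs target %d", L, constraints$targetLength))
    it <- which(nm == "TATA_BOX"); is <- which(nm == "PREDICTED_TSS")
    if (length(it) != 1L || length(is) != 1L) {
      flag("STRUCTURE", 1L, L, "need one TATA_BOX and one PREDICTED_TSS")
    } else {
      if (!iupacSeqMatches(featSeq(it), constraints$tataPattern))
        flag("TATA_CONSENSUS", fstart[it], fend[it],
             sprintf("TATA box is %s, expected %s", featSeq(it),
                     constraints$tataPattern))
      gap <- fstart[is] - fend[it] - 1L
      if (gap != constraints$tataToTssSpacing)
        flag("TATA_TSS_SPACING", fend[it], fstart[is],
             sprintf("spacing %d, expected %d", gap,
                     constraints$tataToTssSpacing))
      inr <- strsplit(constraints$inrPattern, "")[[1]]
      tss <- fstart[is]
      if (tss < 2L || !iupacMatches(ch[tss - 1L], inr[1]) ||
          !iupacMatches(ch[tss], inr[2]))
        flag("INR_PATTERN", max(tss - 1L, 1L), tss,
             sprintf("initiator %s%s does not match %s",
                     if (tss >= 2) ch[tss - 1L] else "", ch[tss],
                     constraints$inrPattern))
      hits <- findAtg(ch, tss)
      for (h in hits)
        flag("ATG_FREE_LEADER", h, h + 2L,
             "start codon at or downstream of the predicted TSS")
    }
  } else if (constraints$elementClass == "INTRON") {
    expLen <- constraints$targetLength + 2L * constraints$flankLength
    if (abs(L - expLen) > tol)
      flag("TARGET_LENGTH", 1L, L,
           sprintf("length %d vs target %d", L, expLen))
    id <- which(nm == "DONOR_SITE"); ia <- which(nm == "ACCEPTOR_SITE")
    if (length(id) != 1L || length(ia) != 1L) {
      flag("STRUCTURE", 1L, L, "need one DONOR_SITE and one ACCEPTOR_SITE")
    } else {
      if (featSeq(id) != constraints$donorConsensus)
        flag("DONOR_CONSENSUS", fstart[id], fend[id],
             sprintf("donor is %s, expected %s", featSeq(id),
                     constraints$donorConsensus))
      if (featSeq(ia) != constraints$acceptorConsensus)
        flag("ACCEPTOR_CONSENSUS", fstart[ia], fend[ia],
             sprintf("acceptor is %s, expected %s", featSeq(ia),
                     constraints$acceptorConsensus))
      interior <- c(fend[id] + 1L, fstart[ia] - 1L)
      bad <- findForbidden(ch, interior, constraints)
      for (r in seq_len(nrow(bad)))
        flag("FORBIDDEN_INTERNAL", bad$start[r], bad$end[r],
             sprintf("forbidden pattern (%s) inside the intron", bad$what[r]))
      im <- which(nm == "IME_MOTIF")
      if (length(im) == 0) {
        flag("IME_PRESENT", 1L, L, "no IME_MOTIF feature")
      } else {
        okAny <- any(vapply(im, function(i) {
          any(vapply(constraints$imeMotifs, function(p)
            nchar(p) == (fend[i] - fstart[i] + 1L) &&
              iupacSeqMatches(featSeq(i), p), logical(1)))
        }, logical(1)))
        if (!okAny)
          flag("IME_CONSENSUS", fstart[im[1]], fend[im[1]],
               "IME_MOTIF sequence matches no configured motif")
        inWin <- any(fstart[im] - fstart[id] + 1L >= constraints$imeWindow[1] &
                     fend[im] - fstart[id] + 1L <= constraints$imeWindow[2])
        if (!inWin)
          flag("IME_WINDOW", fstart[im[1]], fend[im[1]],
               "IME_MOTIF outside its placement window")
      }
    }
  } else if (constraints$elementClass == "TERMINATOR") {
    if (abs(L - constraints$targetLength) > tol)
      flag("TARGET_LENGTH", 1L, L,
           sprintf("length %d vs target %d", L, constraints$targetLength))
    ic <- which(nm == "CLEAVAGE_SITE")
    if (length(ic) != constraints$nPolyaSites)
      flag("N_POLYA_SITES", 1L, L,
           sprintf("%d cleavage sites annotated, expected %d", length(ic),
                   constraints$nPolyaSites))
    for (i in ic) {
      ci <- fstart[i]
      if (ch[ci] != "A" || ci < 2L || !ch[ci - 1L] %in% c("C", "T"))
        flag("CLEAVAGE_YA", max(ci - 1L, 1L), ci,
             sprintf("cleavage site %s%s is not a YA dinucleotide",
                     if (ci >= 2) ch[ci - 1L] else "", ch[ci]))
      # an NUE must end nueSpacing bases upstream (sequence-level check)
      lo <- ci - constraints$nueSpacing[2] - 1L
      hi <- ci - constraints$nueSpacing[1] - 1L
      plen <- nchar(constraints$nuePattern)
      found <- FALSE
      for (e in seq(max(hi, 1L), max(lo, 1L))) {
        st0 <- e - plen + 1L
        if (st0 >= 1L &&
            iupacSeqMatches(substr(s, st0, e), constraints$nuePattern)) {
          found <- TRUE; break
        }
      }
      if (!found)
        flag("NUE_SPACING", max(lo, 1L), ci,
             sprintf("no %s ending %d-%d bases upstream of the cleavage site",
                     constraints$nuePattern, constraints$nueSpacing[1],
                     constraints$nueSpacing[2]))
    }
    if (length(ic) > 0) {
      distal <- ic[which.max(fstart[ic])]
      cd <- fstart[distal]
      run <- constraints$tTractMinRun
      tract <- cd > run && all(ch[(cd - run):(cd - 1L)] == "T")
      if (!tract)
        flag("T_RICH_TRACT", max(cd - run, 1L), cd - 1L,
             sprintf("no run of >= %d T's ending at the distal cleavage site",
                     run))
    }
  } else {
    flag("ELEMENT_CLASS", 1L, L, "unknown element class")
  }

  viol <- if (length(v)) S4Vectors::DataFrame(do.call(rbind, v))
          else S4Vectors::DataFrame(constraint = character(0),
                                    start = integer(0), end = integer(0),
                                    message = character(0))
  methods::new("ConstraintReport", violations = viol,
               passed = nrow(viol) == 0L)
}

# exact-length IUPAC comparison
iupacSeqMatches <- function(seq, pattern) {
  if (nchar(seq) != nchar(pattern)) return(FALSE)
  a <- strsplit(seq, "")[[1]]; b <- strsplit(pattern, "")[[1]]
  all(mapply(iupacMatches, a, b))
}

#' Read designed elements back from FASTA plus a features GFF3
#'
#' Inverse of \code{\link{writeElements}}. The element class is inferred
#' from the annotated features (DONOR_SITE implies INTRON, TATA_BOX
#' implies PROMOTER, CLEAVAGE_SITE implies TERMINATOR).
#'
#' @param fastaPath,gffPath paths written by \code{\link{writeElements}}.
#' @return a list of \linkS4class{DesignedElement}s.
#' @export
readElements <- function(fastaPath, gffPath) {
  seqs <- Biostrings::readDNAStringSet(fastaPath)
  gr <- rtracklayer::import(gffPath, format = "gff3")
  lapply(seq_along(seqs), function(i) {
    id <- names(seqs)[i]
    sel <- gr[as.character(GenomeInfoDb::seqnames(gr)) == id]
    feats <- IRanges::ranges(sel)
    nm <- as.character(sel$type)
    S4Vectors::mcols(feats)$feature <- nm
    cls <- if ("DONOR_SITE" %in% nm) "INTRON"
           else if ("TATA_BOX" %in% nm) "PROMOTER"
           else if ("CLEAVAGE_SITE" %in% nm) "TERMINATOR"
           else stop("cannot infer element class for ", id)
    methods::new("DesignedElement", elementId = id, elementClass = cls,
                 sequence = seqs[[i]], features = feats,
                 provenance = list(source = fastaPath))
  })
}

#' Write designed elements as FASTA plus a features GFF3
#'
#' Feature coordinates are element-local and 1-based in the file.
#'
#' @param elements a list of \linkS4class{DesignedElement}s (or one).
#' @param fastaPath,gffPath output paths.
#' @return invisibly, the FASTA path.
#' @export
writeElements <- function(elements, fastaPath, gffPath = NULL) {
  if (methods::is(elements, "DesignedElement")) elements <- list(elements)
  seqs <- Biostrings::DNAStringSet(vapply(elements, function(e)
    as.character(elementSequence(e)), character(1)))
  names(seqs) <- vapply(elements, elementId, character(1))
  Biostrings::writeXStringSet(seqs, fastaPath)
  if (!is.null(gffPath)) {
    rows <- lapply(elements, function(e) {
      f <- elementFeatures(e)
      data.frame(seqid = elementId(e), source = "plantElements",
                 type = S4Vectors::mcols(f)$feature,
                 start = BiocGenerics::start(f), end = BiocGenerics::end(f),
                 score = ".", strand = "+", phase = ".",
                 attributes = sprintf("ID=%s_%s_%d", elementId(e),
                                      S4Vectors::mcols(f)$feature,
                                      seq_along(f)),
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    con <- file(gffPath, "w")
    writeLines("##gff-version 3", con)
    write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    close(con)
  }
  invisible(fastaPath)
}
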