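#' Transversion map for motif knockouts
#'
#' Maps each base to a fixed transversion partner: A->C, C->A, G->T, T->G.
#' Every substitution is a purine<->pyrimidine change, the map is an
#' involution, and AT-rich sequence maps to GC-rich sequence (TATAAA ->
#' GCGCCC), which is the property used to ablate TATA boxes.
#'
#' @param base character vector of single bases (A, C, G or T); anything
#'   else is a hard error.
#' @return the transversion partner(s).
#' @export
transversionMap <- function(base) {
  map <- c(A = "C", C = "A", G = "T", T = "G")
  out <- map[toupper(base)]
  if (any(is.na(out)))
    stop("transversionMap: base outside {A,C,G,T}: ",
         paste(unique(base[is.na(out)]), collapse = ", "))
  unname(out)
}

transvertString <- function(s) {
  paste(transversionMap(strsplit(s, "")[[1]]), collapse = "")
}

#' Build a motif-knockout variant of a designed element
#'
#' Rewrites exactly the intervals of the named features by the transversion
#' map, leaving every other base byte-identical. All intervals of a named
#' feature are rewritten (e.g. both NUE copies of a terminator). The
#' variant's id is the original id suffixed with "_" and the joined feature
#' names; applying the same variant twice restores the original sequence.
#'
#' @param element a \linkS4class{DesignedElement}.
#' @param featureNames character vector of feature names to knock out;
#'   an unknown name is a hard error listing the available features.
#' @return a list with \code{element} (the variant
#'   \linkS4class{DesignedElement}) and \code{edits} (data.frame: start,
#'   end, before, after).
#' @export
makeVariant <- function(element, featureNames) {
  feats <- elementFeatures(element)
  nm <- S4Vectors::mcols(feats)$feature
  unknown <- setdiff(featureNames, nm)
  if (length(unknown) > 0)
    stop("unknown feature name(s): ", paste(unknown, collapse = ", "),
         "; available: ", paste(unique(nm), collapse = ", "))
  hit <- which(nm %in% featureNames)
  s <- as.character(elementSequence(element))
  ch <- strsplit(s, "")[[1]]
  edits <- lapply(hit, function(i) {
    st <- BiocGenerics::start(feats)[i]; en <- BiocGenerics::end(feats)[i]
    before <- substr(s, st, en)
    after <- transvertString(before)
    ch[st:en] <<- strsplit(after, "")[[1]]
    data.frame(feature = nm[i], start = st, end = en, before = before,
               after = after, stringsAsFactors = FALSE)
  })
  edits <- do.call(rbind, edits)
  variant <- methods::new(
    "DesignedElement",
    elementId = paste0(elementId(element), "_",
                       paste(featureNames, collapse = "_")),
    elementClass = elementClass(element),
    sequence = Biostrings::DNAString(paste(ch, collapse = "")),
    features = feats,
    provenance = c(provenance(element),
                   list(variant_of = elementId(element),
                        knocked_out = featureNames)))
  list(element = variant, edits = edits)
}

#' Write a variant's edit log as TSV
#'
#' @param edits the \code{edits} component of \code{\link{makeVariant}}.
#' @param path TSV path.
#' @return invisibly, the path.
#' @export
writeEdits <- function(edits, path) {
  write.table(edits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
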