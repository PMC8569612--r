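#' Construct a CassetteModel
#'
#' Coordinates are 1-based with the promoter 5'-most base = 1; junction
#' coordinates use donor = first intronic base, acceptor = last intronic
#' base.
#'
#' @param cassetteId reference name (must match the SAM \code{@SQ SN}).
#' @param length cassette length in bp.
#' @param intendedTss intended transcription start coordinate.
#' @param intendedJunctions data.frame with columns \code{p5}, \code{p3},
#'   one row per intended intron (may be empty).
#' @param intendedPolyaSites integer vector of intended cleavage sites.
#' @param parts optional \linkS4class{IRanges} of named cassette parts
#'   (metadata column \code{part}).
#' @return a \linkS4class{CassetteModel}.
#' @export
cassetteModel <- function(cassetteId, length, intendedTss,
                          intendedJunctions = data.frame(p5 = integer(0),
                                                         p3 = integer(0)),
                          intendedPolyaSites = integer(0),
                          parts = NULL) {
  if (is.null(parts)) {
    parts <- IRanges::IRanges()
    S4Vectors::mcols(parts)$part <- character(0)
  }
  methods::new("CassetteModel", cassetteId = as.character(cassetteId),
               length = as.integer(length),
               parts = parts, intendedTss = as.integer(intendedTss),
               intendedJunctions = S4Vectors::DataFrame(
                 p5 = as.integer(intendedJunctions$p5),
                 p3 = as.integer(intendedJunctions$p3)),
               intendedPolyaSites = as.integer(intendedPolyaSites))
}

#' Read a cassette model from GFF3 plus a YAML sidecar
#'
#' The GFF3 supplies the named parts (one seqid = the cassette); the YAML
#' sidecar supplies the intended landmarks:
#' \preformatted{
#' cassette_id: cas1
#' length: 3400
#' intended_tss: 481
#' intended_junctions:
#'   - {p5: 511, p3: 853}
#' intended_polya_sites: [3126, 3186]
#' }
#'
#' @param yamlPath sidecar path.
#' @param gffPath optional GFF3 of cassette parts.
#' @return a \linkS4class{CassetteModel}.
#' @export
readCassetteModel <- function(yamlPath, gffPath = NULL) {
  if (!file.exists(yamlPath)) stop("cassette sidecar not found: ", yamlPath)
  y <- yaml::read_yaml(yamlPath)
  jn <- y$intended_junctions
  jdf <- if (length(jn) == 0) data.frame(p5 = integer(0), p3 = integer(0))
         else data.frame(p5 = vapply(jn, function(j) as.integer(j$p5), integer(1)),
                         p3 = vapply(jn, function(j) as.integer(j$p3), integer(1)))
  parts <- NULL
  if (!is.null(gffPath)) {
    gr <- rtracklayer::import(gffPath, format = "gff3")
    parts <- IRanges::ranges(gr)
    nmv <- if (!is.null(gr$Name)) as.character(gr$Name)
           else as.character(gr$type)
    S4Vectors::mcols(parts)$part <- nmv
  }
  cassetteModel(y$cassette_id, y$length, y$intended_tss, jdf,
                unlist(y$intended_polya_sites), parts)
}

#' Write a cassette model's YAML sidecar
#'
#' @param cassette a \linkS4class{CassetteModel}.
#' @param yamlPath output path.
#' @return invisibly, the path.
#' @export
writeCassetteModel <- function(cassette, yamlPath) {
  j <- as.data.frame(intendedJunctions(cassette))
  y <- list(cassette_id = cassetteId(cassette),
            length = cassette@length,
            intended_tss = intendedTss(cassette),
            intended_junctions = lapply(seq_len(nrow(j)), function(i)
              list(p5 = j$p5[i], p3 = j$p3[i])),
            intended_polya_sites = as.list(intendedPolyaSites(cassette)))
  yaml::write_yaml(y, yamlPath)
  invisible(yamlPath)
}
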