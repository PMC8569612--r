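#' Accessors for plantElements classes
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("trainingSequences", function(x) standardGeneric("trainingSequences"))
#' @rdname accessors
#' @export
setMethod("trainingSequences", "TrainingSet", function(x) x@sequences)

#' @rdname accessors
#' @export
setGeneric("trainingRecords", function(x) standardGeneric("trainingRecords"))
#' @rdname accessors
#' @export
setMethod("trainingRecords", "TrainingSet", function(x) x@records)

#' @rdname accessors
#' @export
setGeneric("anchorOffset", function(x) standardGeneric("anchorOffset"))
#' @rdname accessors
#' @export
setMethod("anchorOffset", "TrainingSet", function(x) x@upstream)
#' @rdname accessors
#' @export
setMethod("anchorOffset", "PositionalProfile", function(x) x@anchorOffset)

#' @rdname accessors
#' @export
setGeneric("windowAnchor", function(x) standardGeneric("windowAnchor"))
#' @rdname accessors
#' @export
setMethod("windowAnchor", "TrainingSet", function(x) x@anchor)

#' @rdname accessors
#' @export
setGeneric("profileMatrix", function(x) standardGeneric("profileMatrix"))
#' @rdname accessors
#' @export
setMethod("profileMatrix", "PositionalProfile", function(x) x@profile)

#' @rdname accessors
#' @export
setGeneric("elementId", function(x) standardGeneric("elementId"))
#' @rdname accessors
#' @export
setMethod("elementId", "DesignedElement", function(x) x@elementId)

#' @rdname accessors
#' @export
setGeneric("elementClass", function(x) standardGeneric("elementClass"))
#' @rdname accessors
#' @export
setMethod("elementClass", "DesignedElement", function(x) x@elementClass)

#' @rdname accessors
#' @export
setGeneric("elementSequence", function(x) standardGeneric("elementSequence"))
#' @rdname accessors
#' @export
setMethod("elementSequence", "DesignedElement", function(x) x@sequence)

#' @rdname accessors
#' @export
setGeneric("elementFeatures", function(x) standardGeneric("elementFeatures"))
#' @rdname accessors
#' @export
setMethod("elementFeatures", "DesignedElement", function(x) x@features)

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setMethod("provenance", "DesignedElement", function(x) x@provenance)

#' @rdname accessors
#' @export
setGeneric("cassetteId", function(x) standardGeneric("cassetteId"))
#' @rdname accessors
#' @export
setMethod("cassetteId", "CassetteModel", function(x) x@cassetteId)
#' @rdname accessors
#' @export
setMethod("cassetteId", "CassetteAlignments", function(x) x@cassetteId)

#' @rdname accessors
#' @export
setGeneric("intendedJunctions", function(x) standardGeneric("intendedJunctions"))
#' @rdname accessors
#' @export
setMethod("intendedJunctions", "CassetteModel", function(x) x@intendedJunctions)

#' @rdname accessors
#' @export
setGeneric("intendedTss", function(x) standardGeneric("intendedTss"))
#' @rdname accessors
#' @export
setMethod("intendedTss", "CassetteModel", function(x) x@intendedTss)

#' @rdname accessors
#' @export
setGeneric("intendedPolyaSites", function(x) standardGeneric("intendedPolyaSites"))
#' @rdname accessors
#' @export
setMethod("intendedPolyaSites", "CassetteModel", function(x) x@intendedPolyaSites)

#' @rdname accessors
#' @export
setGeneric("readBlocks", function(x) standardGeneric("readBlocks"))
#' @rdname accessors
#' @export
setMethod("readBlocks", "CassetteAlignments", function(x) x@blocks)

#' @rdname accessors
#' @export
setGeneric("hasAdapter5", function(x) standardGeneric("hasAdapter5"))
#' @rdname accessors
#' @export
setMethod("hasAdapter5", "CassetteAlignments", function(x) x@has5)

#' @rdname accessors
#' @export
setGeneric("hasAdapter3", function(x) standardGeneric("hasAdapter3"))
#' @rdname accessors
#' @export
setMethod("hasAdapter3", "CassetteAlignments", function(x) x@has3)

#' @rdname accessors
#' @export
setGeneric("intendedUsage", function(x) standardGeneric("intendedUsage"))
#' @rdname accessors
#' @export
setMethod("intendedUsage", "SpliceUsageReport", function(x) x@intended)

#' @rdname accessors
#' @export
setGeneric("usageCategories", function(x) standardGeneric("usageCategories"))
#' @rdname accessors
#' @export
setMethod("usageCategories", "SpliceUsageReport", function(x) x@categories)

#' @rdname accessors
#' @export
setGeneric("junctionTable", function(x) standardGeneric("junctionTable"))
#' @rdname accessors
#' @export
setMethod("junctionTable", "SpliceUsageReport", function(x) x@junctions)

#' @rdname accessors
#' @export
setGeneric("siteTable", function(x) standardGeneric("siteTable"))
#' @rdname accessors
#' @export
setMethod("siteTable", "SiteDistribution", function(x) x@table)

#' @rdname accessors
#' @export
setGeneric("dominantSite", function(x) standardGeneric("dominantSite"))
#' @rdname accessors
#' @export
setMethod("dominantSite", "SiteDistribution", function(x) x@dominantSite)

setMethod("length", "TrainingSet", function(x) length(x@sequences))
setMethod("length", "CassetteAlignments", function(x) length(x@readId))

setMethod("show", "GeneModels", function(object) {
  cat("GeneModels with", nrow(object@genes), "genes on",
      length(unique(object@genes$chrom)), "chromosome(s)\n")
})

setMethod("show", "TrainingSet", function(object) {
  cat(sprintf("TrainingSet anchor=%s (-%d/+%d), %d records\n",
              object@anchor, object@upstream, object@downstream,
              length(object@sequences)))
})

setMethod("show", "PositionalProfile", function(object) {
  cat(sprintf(
    "PositionalProfile over %d offsets (anchor at %s), n=%d, pseudocount=%g\n",
    ncol(object@profile),
    ifelse(is.na(object@anchorOffset), "NA", object@anchorOffset),
    object@n, object@pseudocount))
})

setMethod("show", "DesignedElement", function(object) {
  cat(sprintf("DesignedElement %s [%s], %d bp, %d features\n",
              object@elementId, object@elementClass,
              length(object@sequence), length(object@features)))
  nm <- S4Vectors::mcols(object@features)$feature
  if (length(nm))
    cat(" features:", paste(unique(nm), collapse = ", "), "\n")
})

setMethod("show", "CassetteModel", function(object) {
  cat(sprintf("CassetteModel %s (%d bp): TSS %d, %d intended junction(s), %d polyA site(s)\n",
              object@cassetteId, object@length, object@intendedTss,
              nrow(object@intendedJunctions),
              length(object@intendedPolyaSites)))
})

setMethod("show", "CassetteAlignments", function(object) {
  cat(sprintf("CassetteAlignments on %s: %d reads (%d with 5' adapter, %d with 3' adapter)\n",
              object@cassetteId, length(object@readId), sum(object@has5),
              sum(object@has3)))
})

setMethod("show", "SpliceUsageReport", function(object) {
  cat("SpliceUsageReport for", nrow(object@intended), "intended junction(s)\n")
  print(as.data.frame(object@intended))
})

setMethod("show", "SiteDistribution", function(object) {
  cat(sprintf("SiteDistribution [%s]: %d informative reads over %d position(s); dominant %d\n",
              object@kind, object@total, nrow(object@table),
              object@dominantSite))
})
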