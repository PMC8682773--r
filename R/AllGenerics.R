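#' @include AllClasses.R
NULL

#' Accessors for package classes
#'
#' Small accessor generics so slots are never reached into directly:
#' `diMatrix` returns the L x L direct-information matrix, `contactMatrix`
#' the binary contact map, `distanceMatrix` the minimum heavy-atom distance
#' matrix, `targetSequence` the (ungapped) target nucleotides,
#' `effectiveSequences` the effective sequence number M_eff,
#' `secondaryPairs` the base-pair table, `nParameters` the number of free
#' filter weights, and `familyId` the training-pair identifier.
#'
#' @param x An object of the corresponding class.
#' @return The slot contents described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("diMatrix", function(x) standardGeneric("diMatrix"))
#' @rdname accessors
#' @export
setGeneric("contactMatrix", function(x) standardGeneric("contactMatrix"))
#' @rdname accessors
#' @export
setGeneric("distanceMatrix", function(x) standardGeneric("distanceMatrix"))
#' @rdname accessors
#' @export
setGeneric("targetSequence", function(x) standardGeneric("targetSequence"))
#' @rdname accessors
#' @export
setGeneric("effectiveSequences",
           function(x) standardGeneric("effectiveSequences"))
#' @rdname accessors
#' @export
setGeneric("secondaryPairs", function(x) standardGeneric("secondaryPairs"))
#' @rdname accessors
#' @export
setGeneric("nParameters", function(x) standardGeneric("nParameters"))
#' @rdname accessors
#' @export
setGeneric("familyId", function(x) standardGeneric("familyId"))

#' @rdname accessors
#' @export
setGeneric("msaMatrix", function(x) standardGeneric("msaMatrix"))
#' @rdname accessors
#' @export
setGeneric("targetIndex", function(x) standardGeneric("targetIndex"))
#' @rdname accessors
#' @export
setGeneric("columnMap", function(x) standardGeneric("columnMap"))

#' @rdname accessors
setMethod("msaMatrix", "RnaMsa", function(x) x@alignment)
#' @rdname accessors
setMethod("targetIndex", "RnaMsa", function(x) x@targetRow)
#' @rdname accessors
setMethod("columnMap", "RnaMsa", function(x) x@columnMap)

#' @rdname accessors
setMethod("targetSequence", "RnaMsa", function(x) {
  codes <- x@alignment[x@targetRow, ]
  rnaAlphabet()[codes[codes != rnaStates()]]
})
#' @rdname accessors
setMethod("targetSequence", "DIMap", function(x) x@targetSeq)

#' @rdname accessors
setMethod("diMatrix", "DIMap", function(x) x@di)
#' @rdname accessors
setMethod("effectiveSequences", "DIMap", function(x) x@meff)

#' @rdname accessors
setMethod("contactMatrix", "ContactMap", function(x) x@contact)
#' @rdname accessors
setMethod("distanceMatrix", "ContactMap", function(x) x@dist)

#' @rdname accessors
setMethod("secondaryPairs", "SecondaryStructure", function(x) x@pairs)

#' @rdname accessors
setMethod("nParameters", "FilterSet", function(x) {
  as.integer(length(x@filters)) * x@d * x@d
})

#' @rdname accessors
setMethod("diMatrix", "TrainingPair", function(x) x@di@di)
#' @rdname accessors
setMethod("contactMatrix", "TrainingPair", function(x) x@contacts@contact)
#' @rdname accessors
setMethod("familyId", "TrainingPair", function(x) x@familyId)

setMethod("show", "RnaMsa", function(object) {
  trimmed <- length(object@columnMap) > 0L
  cat(sprintf("RnaMsa: %d sequences x %d columns (%s)\n",
              nrow(object@alignment), ncol(object@alignment),
              if (trimmed) "trimmed to target" else "untrimmed"))
  cat(sprintf("  target row: %d; ambiguous symbols mapped to gap: %d\n",
              object@targetRow, object@ambiguousCount))
})

setMethod("show", "DIMap", function(object) {
  cat(sprintf("DIMap: %d x %d direct-information scores\n",
              nrow(object@di), ncol(object@di)))
  if (is.finite(object@meff)) {
    cat(sprintf("  M_eff = %.2f\n", object@meff))
  }
})

setMethod("show", "ContactMap", function(object) {
  n <- sum(object@contact[upper.tri(object@contact)], na.rm = TRUE)
  cat(sprintf("ContactMap: L = %d, cutoff = %g A, %d contacts (i < j)\n",
              nrow(object@dist), object@cutoff, n))
})

setMethod("show", "SecondaryStructure", function(object) {
  cat(sprintf("SecondaryStructure: L = %d, %d pairs (%d pseudoknotted)\n",
              object@length, nrow(object@pairs),
              sum(object@pairs$pseudoknot)))
})

setMethod("show", "FilterSet", function(object) {
  cat(sprintf("FilterSet: %s mode, %d x %d (%d free parameters)\n",
              object@mode, object@d, object@d, nParameters(object)))
})

setMethod("show", "TrainingPair", function(object) {
  cat(sprintf("TrainingPair '%s': L = %d\n", object@familyId,
              nrow(object@di@di)))
})

setMethod("show", "PlantedPottsModel", function(object) {
  cat(sprintf(
    "PlantedPottsModel: L = %d, %d stem pairs, %d tertiary pairs\n",
    object@L, nrow(object@stemPairs), nrow(object@tertiaryPairs)))
})
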