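#' @import methods
NULL

#' The fixed RNA alphabet
#'
#' Alignment columns are encoded over the five-state alphabet
#' (A, C, G, U, gap) with integer codes 1..5; the gap is state 5 and acts
#' as the reference state when couplings are computed in the reduced basis.
#'
#' @return Character vector of length 5.
#' @export
#' @examples
#' rnaAlphabet()
rnaAlphabet <- function() c("A", "C", "G", "U", "-")

#' Number of Potts states (5: four nucleotides plus gap)
#' @return Integer scalar.
#' @export
rnaStates <- function() 5L

#' @rdname RnaMsa
#' @export
setClass("RnaMsa",
  representation(
    alignment = "matrix",
    targetRow = "integer",
    columnMap = "integer",
    ambiguousCount = "integer"
  )
)

setValidity("RnaMsa", function(object) {
  a <- object@alignment
  if (!is.numeric(a) && !is.integer(a)) {
    return("alignment must be an integer matrix")
  }
  if (nrow(a) < 1L || ncol(a) < 1L) {
    return("alignment must have at least one row and one column")
  }
  if (anyNA(a) || any(a < 1L | a > rnaStates())) {
    return(sprintf("alignment codes must lie in 1..%d", rnaStates()))
  }
  if (length(object@targetRow) != 1L ||
      object@targetRow < 1L || object@targetRow > nrow(a)) {
    return("targetRow must index one alignment row")
  }
  if (length(object@columnMap) > 0L) {
    if (length(object@columnMap) != ncol(a)) {
      return("columnMap length must equal the number of columns")
    }
    if (any(diff(object@columnMap) <= 0L)) {
      return("columnMap must be strictly increasing")
    }
    if (any(a[object@targetRow, ] == rnaStates())) {
      return("trimmed alignment must have a gap-free target row")
    }
  }
  TRUE
})

#' MSA container with a designated target sequence
#'
#' Holds an integer-encoded RNA multiple sequence alignment (codes 1..5 over
#' A, C, G, U, gap) together with the index of the structural target row.
#' After [trimToTarget()] the `columnMap` slot records, for every retained
#' column, its 1-based position in the ungapped target sequence; an empty
#' `columnMap` marks an untrimmed alignment.
#'
#' @param alignment Integer matrix (sequences x columns), codes 1..5.
#' @param targetRow Index of the target sequence row.
#' @param columnMap Integer vector mapping columns to target positions
#'   (empty for untrimmed alignments).
#' @param ambiguousCount Number of non-ACGU symbols mapped to gap on input.
#' @return An object of class `RnaMsa`.
#' @export
RnaMsa <- function(alignment, targetRow = 1L, columnMap = integer(0),
                   ambiguousCount = 0L) {
  storage.mode(alignment) <- "integer"
  new("RnaMsa", alignment = alignment, targetRow = as.integer(targetRow),
      columnMap = as.integer(columnMap),
      ambiguousCount = as.integer(ambiguousCount))
}

#' @rdname DIMap
#' @export
setClass("DIMap",
  representation(
    di = "matrix",
    meff = "numeric",
    targetSeq = "character",
    params = "list"
  )
)

setValidity("DIMap", function(object) {
  d <- object@di
  if (nrow(d) != ncol(d)) return("di must be square")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    return("di must be symmetric")
  }
  if (any(d[!is.na(d)] < -1e-12)) return("direct information must be >= 0")
  if (length(object@targetSeq) != nrow(d)) {
    return("targetSeq length must equal the map dimension")
  }
  TRUE
})

#' Direct-information score map
#'
#' Symmetric L x L matrix of direct-information scores over target
#' coordinates (the coevolutionary layer), with the effective sequence
#' number and the target nucleotide sequence attached.
#'
#' @param di Symmetric numeric matrix of DI scores.
#' @param meff Effective number of sequences used to compute it.
#' @param targetSeq Character vector (length L) of target nucleotides.
#' @param params List of parameters used (threshold, lambda, tol).
#' @return An object of class `DIMap`.
#' @export
DIMap <- function(di, meff = NA_real_, targetSeq = character(0),
                  params = list()) {
  if (length(targetSeq) == 0L) targetSeq <- rep(NA_character_, nrow(di))
  new("DIMap", di = di, meff = as.numeric(meff), targetSeq = targetSeq,
      params = params)
}

#' @rdname ContactMap
#' @export
setClass("ContactMap",
  representation(
    dist = "matrix",
    contact = "matrix",
    cutoff = "numeric",
    mapping = "integer"
  )
)

setValidity("ContactMap", function(object) {
  d <- object@dist
  if (nrow(d) != ncol(d)) return("dist must be square")
  if (!identical(dim(d), dim(object@contact))) {
    return("dist and contact must share dimensions")
  }
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    return("dist must be symmetric")
  }
  ok <- !is.na(d)
  diag(ok) <- FALSE
  if (!all((d[ok] < object@cutoff) == object@contact[ok])) {
    return("contact must equal dist < cutoff (strict) off the diagonal")
  }
  if (object@cutoff <= 0) return("cutoff must be positive")
  TRUE
})

#' Structure-derived contact map
#'
#' Minimum heavy-atom distance matrix over target coordinates and the
#' binary contact map obtained by strict thresholding (`dist < cutoff`).
#' Positions with no mapped structure residue carry `NA` and are excluded
#' from evaluation. The diagonal is excluded by convention.
#'
#' @param dist Symmetric numeric matrix of minimum heavy-atom distances
#'   in Angstrom.
#' @param cutoff Contact cutoff in Angstrom (default 10).
#' @param mapping Integer vector: structure residue index for each target
#'   position (`NA` where unmapped).
#' @return An object of class `ContactMap`.
#' @export
ContactMap <- function(dist, cutoff = 10, mapping = integer(0)) {
  contact <- dist < cutoff
  diag(contact) <- NA
  if (length(mapping) == 0L) mapping <- seq_len(nrow(dist))
  new("ContactMap", dist = dist, contact = contact,
      cutoff = as.numeric(cutoff), mapping = as.integer(mapping))
}

#' @rdname SecondaryStructure
#' @export
setClass("SecondaryStructure",
  representation(
    pairs = "data.frame",
    length = "integer",
    source = "character"
  )
)

setValidity("SecondaryStructure", function(object) {
  p <- object@pairs
  if (!all(c("i", "j", "pseudoknot") %in% names(p))) {
    return("pairs needs columns i, j, pseudoknot")
  }
  if (nrow(p) > 0L) {
    if (any(p$i >= p$j)) return("pairs must satisfy i < j")
    if (any(p$i < 1L) || any(p$j > object@length)) {
      return("pair indices out of range")
    }
    nested <- c(p$i[!p$pseudoknot], p$j[!p$pseudoknot])
    if (anyDuplicated(nested)) {
      return("a position may appear in at most one nested pair")
    }
  }
  TRUE
})

#' Secondary-structure annotation
#'
#' Base pairs parsed from dot-bracket or CT annotation. Pairs in the
#' nested (round-bracket) tier are secondary (2D); pairs from other
#' bracket tiers are flagged as pseudoknots and treated as tertiary when
#' contacts are stratified.
#'
#' @param pairs `data.frame` with integer columns `i`, `j` (`i < j`) and a
#'   logical column `pseudoknot`.
#' @param length Sequence length the annotation refers to.
#' @param source Annotation origin, `"dot-bracket"` or `"ct"`.
#' @return An object of class `SecondaryStructure`.
#' @export
SecondaryStructure <- function(pairs, length, source = "dot-bracket") {
  new("SecondaryStructure", pairs = pairs, length = as.integer(length),
      source = source)
}

#' @rdname FilterSet
#' @export
setClass("FilterSet",
  representation(
    mode = "character",
    d = "integer",
    filters = "list"
  )
)

setValidity("FilterSet", function(object) {
  if (!object@mode %in% c("single", "dual")) {
    return("mode must be 'single' or 'dual'")
  }
  if (object@d %% 2L == 0L) return("filter size d must be odd")
  want <- if (object@mode == "single") "filter" else c("wc", "nonwc")
  if (!identical(names(object@filters), want)) {
    return(sprintf("filters must be named: %s", paste(want, collapse = ", ")))
  }
  for (f in object@filters) {
    if (!is.matrix(f) || !all(dim(f) == object@d)) {
      return("every filter must be a d x d numeric matrix")
    }
  }
  TRUE
})

#' Convolutional filter set
#'
#' One (`single` mode) or two (`dual` mode) d x d weight matrices. In dual
#' mode one filter convolves the Watson-Crick-masked score map and the
#' other the complementary map; the two convolutions are summed.
#'
#' @param filters A single d x d matrix, or a list of one matrix
#'   (single mode) or two matrices named `wc` and `nonwc` (dual mode).
#' @param mode `"single"` or `"dual"`; inferred from `filters` when missing.
#' @return An object of class `FilterSet`.
#' @export
#' @examples
#' FilterSet(diag(3) * 0 + 1)                    # single all-ones 3x3
#' FilterSet(list(wc = diag(3), nonwc = diag(3)))  # dual
FilterSet <- function(filters, mode = NULL) {
  if (is.matrix(filters)) filters <- list(filter = filters)
  if (is.null(mode)) {
    mode <- if (length(filters) == 2L) "dual" else "single"
  }
  if (mode == "single" && is.null(names(filters))) names(filters) <- "filter"
  d <- nrow(filters[[1L]])
  new("FilterSet", mode = mode, d = as.integer(d), filters = filters)
}

#' @rdname TrainingPair
#' @export
setClass("TrainingPair",
  representation(
    di = "DIMap",
    contacts = "ContactMap",
    wcMask = "matrix",
    ss = "ANY",
    familyId = "character"
  )
)

setValidity("TrainingPair", function(object) {
  L <- nrow(object@di@di)
  if (nrow(object@contacts@dist) != L) {
    return("di and contacts must share L")
  }
  if (!identical(dim(object@wcMask), c(L, L))) {
    return("wcMask must be L x L")
  }
  TRUE
})

#' Training example: a DI map with its structural labels
#'
#' Couples the coevolutionary score map of one RNA family with its
#' structure-derived contact map, Watson-Crick routing mask and (optional)
#' secondary-structure annotation. One object per family.
#'
#' @param di A [DIMap].
#' @param contacts A [ContactMap] of ground-truth labels.
#' @param wcMask Logical L x L Watson-Crick pair mask (see [wcMask()]);
#'   computed from the DI map's target sequence when missing.
#' @param ss Optional [SecondaryStructure] for tertiary stratification.
#' @param familyId Family identifier (one entry per family in any split).
#' @return An object of class `TrainingPair`.
#' @export
TrainingPair <- function(di, contacts, wcMask = NULL, ss = NULL,
                         familyId = "family") {
  if (is.null(wcMask)) wcMask <- wcMask(di@targetSeq)
  new("TrainingPair", di = di, contacts = contacts, wcMask = wcMask,
      ss = ss, familyId = familyId)
}

#' Planted pairwise Potts model
#'
#' Generative model for synthetic alignments: local fields `h` (L x q),
#' an edge list of coupled site pairs and one q x q coupling block per
#' edge, with the planted stem and tertiary pair topology and the
#' corresponding dot-bracket annotation recorded alongside.
#'
#' @name PlantedPottsModel-class
#' @aliases PlantedPottsModel
#' @seealso [plantedStemModel()], [sampleMsa()]
#' @export
setClass("PlantedPottsModel",
  representation(
    L = "integer",
    h = "matrix",
    edges = "matrix",
    couplings = "list",
    stemPairs = "matrix",
    tertiaryPairs = "matrix",
    dotBracket = "character"
  )
)

setValidity("PlantedPottsModel", function(object) {
  if (nrow(object@h) != object@L || ncol(object@h) != rnaStates()) {
    return("h must be L x q")
  }
  if (nrow(object@edges) != length(object@couplings)) {
    return("one coupling block per edge")
  }
  if (nrow(object@edges) > 0L && any(object@edges[, 1] >= object@edges[, 2])) {
    return("edges must satisfy i < j")
  }
  TRUE
})
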