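## coconet: the convolutional re-weighting layer and the top-n output
## layer applied to a direct-information map.

#' Zero-pad a score map
#'
#' Extends an L x L map by p = (d - 1) / 2 zeros on every side, so a d x d
#' window can be centred at every original entry. Zero padding preserves
#' the "no signal" meaning of the border.
#'
#' @param di A [DIMap] or plain numeric matrix.
#' @param d Odd filter size.
#' @return An (L + 2p) x (L + 2p) numeric matrix.
#' @export
padMap <- function(di, d) {
  checkOdd(d)
  m <- if (is(di, "DIMap")) diMatrix(di) else di
  p <- (d - 1L) %/% 2L
  if (p == 0L) return(m)
  L <- nrow(m)
  out <- matrix(0, L + 2L * p, L + 2L * p)
  out[p + seq_len(L), p + seq_len(L)] <- m
  out
}

## Cross-correlation (no kernel flip) of an L x L map with a d x d filter,
## via d^2 shifted additions over the zero-padded map.
crossCorrelate <- function(m, w) {
  d <- nrow(w)
  L <- nrow(m)
  P <- padMap(m, d)
  out <- matrix(0, L, L)
  for (u in seq_len(d)) {
    for (v in seq_len(d)) {
      if (w[u, v] != 0) {
        out <- out + w[u, v] *
          P[u:(u + L - 1L), v:(v + L - 1L), drop = FALSE]
      }
    }
  }
  out
}

#' Convolve a DI map with a filter set
#'
#' Single mode: out(i, j) = sum of the elementwise product of the filter
#' with the d x d window of the zero-padded map centred at (i, j)
#' (cross-correlation orientation; no kernel flip). Dual mode: the map is
#' split into its Watson-Crick part (`di * wcMask`) and its complement,
#' each part is convolved with its own filter, and the two results are
#' summed. The output is symmetrized as (out + t(out)) / 2 unless
#' `symmetrize = FALSE` (training uses the raw upper triangle so the
#' least-squares design stays full rank).
#'
#' @param di A [DIMap] or numeric L x L matrix.
#' @param filters A [FilterSet].
#' @param wcMask Logical L x L Watson-Crick mask; required in dual mode
#'   (taken from the DI map's target sequence when available).
#' @param symmetrize Average with the transpose (default `TRUE`).
#' @return Numeric L x L matrix of re-weighted scores.
#' @export
convolveMap <- function(di, filters, wcMask = NULL, symmetrize = TRUE) {
  m <- if (is(di, "DIMap")) diMatrix(di) else di
  if (filters@mode == "dual") {
    if (is.null(wcMask) && is(di, "DIMap") &&
        !anyNA(targetSequence(di))) {
      wcMask <- coconet::wcMask(targetSequence(di))
    }
    if (is.null(wcMask)) {
      stopInput("dual-filter convolution requires a Watson-Crick mask")
    }
    if (!identical(dim(wcMask), dim(m))) {
      stopInput("wcMask dimensions (%d x %d) do not match the map (%d x %d)",
                nrow(wcMask), ncol(wcMask), nrow(m), ncol(m))
    }
    out <- crossCorrelate(m * wcMask, filters@filters$wc) +
      crossCorrelate(m * !wcMask, filters@filters$nonwc)
  } else {
    out <- crossCorrelate(m, filters@filters$filter)
  }
  if (symmetrize) out <- (out + t(out)) / 2
  out
}

#' Select the top-ranked candidate contact pairs
#'
#' Candidates are pairs (i, j) with j > i + minSeparation; they are sorted
#' by decreasing score, ties broken by ascending (i, j), and the top
#' `min(n, #candidates)` are returned.
#'
#' @param scores Numeric L x L score matrix (upper triangle is used).
#' @param n Number of pairs to return (>= 1).
#' @param minSeparation Minimum sequence separation; pairs with
#'   `|i - j| <= minSeparation` are never candidates (default 4).
#' @return `data.frame` with columns `i`, `j`, `score`, ordered.
#' @export
selectTop <- function(scores, n, minSeparation = 4L) {
  if (n < 1L) stopInput("n must be >= 1")
  L <- nrow(scores)
  ij <- bandPairs(L, minSeparation)
  s <- scores[ij]
  ord <- order(-s, ij[, 1L], ij[, 2L])
  take <- utils::head(ord, n)
  data.frame(i = ij[take, 1L], j = ij[take, 2L], score = s[take],
             row.names = NULL)
}

#' Rank contacts for one alignment with a trained filter set
#'
#' Convenience pipeline: trim to target, compute the DI map, convolve
#' with the filters (dual filters routed by the target's Watson-Crick
#' mask) and return the ranked pairs with a WC flag per pair.
#'
#' @param msa An [RnaMsa].
#' @param filters A [FilterSet]; the identity filter reproduces the raw
#'   mean-field DCA ranking.
#' @param topN Number of pairs to report; default 2L.
#' @param minSeparation Sequence-separation exclusion band (default 4).
#' @param ... Passed to [directInformation()].
#' @return `data.frame` with columns `i`, `j`, `score`, `wc`.
#' @export
coconetPredict <- function(msa, filters, topN = NULL, minSeparation = 4L,
                           ...) {
  if (length(columnMap(msa)) == 0L) msa <- trimToTarget(msa)
  di <- directInformation(msa, ...)
  mask <- wcMask(targetSequence(di))
  scores <- convolveMap(di, filters, wcMask = mask)
  if (is.null(topN)) topN <- 2L * nrow(scores)
  ranked <- selectTop(scores, topN, minSeparation)
  ranked$wc <- mask[cbind(ranked$i, ranked$j)]
  ranked
}

#' Write ranked pairs as TSV
#'
#' Columns i, j, score and (when present) wc_flag; 1-based, i < j.
#'
#' @param ranked `data.frame` from [selectTop()] or [coconetPredict()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeRankedPairs <- function(ranked, path) {
  out <- ranked
  if ("wc" %in% names(out)) names(out)[names(out) == "wc"] <- "wc_flag"
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
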