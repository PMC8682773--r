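## evaluation: PPV-vs-rank curves, MCC at a rank, and the average
## coevolutionary window-pattern analysis.

## Candidate universe: pairs i < j with j - i > minSeparation, a defined
## (non-NA) label, and membership in the stratum when one is given.
candidateTruth <- function(truth, stratumMask = NULL, minSeparation = 4L) {
  cm <- if (is(truth, "ContactMap")) contactMatrix(truth) else truth
  L <- nrow(cm)
  ij <- bandPairs(L, minSeparation)
  lab <- cm[ij]
  keep <- !is.na(lab)
  if (!is.null(stratumMask)) keep <- keep & stratumMask[ij]
  list(ij = ij[keep, , drop = FALSE], labels = as.logical(lab[keep]))
}

## Restrict a ranked prediction table to the candidate universe, keeping
## the original order.
restrictRanked <- function(pred, cand) {
  key <- paste(pred$i, pred$j)
  keep <- key %in% paste(cand$ij[, 1L], cand$ij[, 2L])
  pred[keep, , drop = FALSE]
}

#' Positive predictive value as a function of rank
#'
#' PPV(n) = (number of true contacts among the n top-ranked candidate
#' pairs) / n. Candidates are restricted to |i - j| > minSeparation and,
#' when a stratum mask is supplied (e.g. tertiary eligibility), to the
#' stratum - both for the predictions and for the truth. If the requested
#' maximum rank exceeds the number of available candidates the curve is
#' truncated and flagged with a message.
#'
#' @param pred Ranked pairs `data.frame` (columns `i`, `j`, `score`).
#' @param truth A [ContactMap] or logical matrix of true contacts.
#' @param stratumMask Optional logical L x L mask.
#' @param nMax Maximum rank (default: number of prediction rows).
#' @param minSeparation Sequence-separation exclusion band.
#' @return `data.frame` with columns `rank`, `tp` (cumulative true
#'   positives) and `ppv`.
#' @export
ppvCurve <- function(pred, truth, stratumMask = NULL, nMax = NULL,
                     minSeparation = 4L) {
  cand <- candidateTruth(truth, stratumMask, minSeparation)
  pred <- restrictRanked(pred, cand)
  if (is.null(nMax)) nMax <- nrow(pred)
  if (nMax > nrow(pred)) {
    message(sprintf("PPV curve truncated at rank %d (%d requested)",
                    nrow(pred), nMax))
    nMax <- nrow(pred)
  }
  cm <- if (is(truth, "ContactMap")) contactMatrix(truth) else truth
  hits <- cm[cbind(pred$i, pred$j)][seq_len(nMax)]
  tp <- cumsum(as.integer(hits))
  data.frame(rank = seq_len(nMax), tp = tp, ppv = tp / seq_len(nMax))
}

#' Matthews correlation coefficient at a rank
#'
#' The 2 x 2 confusion table takes the top-n ranked candidate pairs as
#' predicted positives and all candidate pairs (|i - j| > minSeparation,
#' defined labels, stratum if given) as the universe. Degenerate margins
#' (an all-positive or all-negative row/column) yield MCC = 0 with a
#' message.
#'
#' @param pred Ranked pairs `data.frame`.
#' @param truth A [ContactMap] or logical matrix.
#' @param n Rank at which to evaluate.
#' @param stratumMask Optional logical L x L stratum mask.
#' @param minSeparation Sequence-separation exclusion band.
#' @return Scalar MCC in `[-1, 1]`.
#' @export
mccAtRank <- function(pred, truth, n, stratumMask = NULL,
                      minSeparation = 4L) {
  cand <- candidateTruth(truth, stratumMask, minSeparation)
  pred <- restrictRanked(pred, cand)
  if (n > nrow(pred)) {
    stopInput("rank %d exceeds the %d available candidates", n, nrow(pred))
  }
  top <- pred[seq_len(n), , drop = FALSE]
  predKey <- paste(top$i, top$j)
  candKey <- paste(cand$ij[, 1L], cand$ij[, 2L])
  predicted <- candKey %in% predKey
  tp <- sum(predicted & cand$labels)
  fp <- sum(predicted & !cand$labels)
  fn <- sum(!predicted & cand$labels)
  tn <- sum(!predicted & !cand$labels)
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (denom == 0) {
    message("degenerate confusion-table margin; MCC reported as 0")
    return(0)
  }
  (tp * tn - fp * fn) / denom
}

#' Average coevolutionary pattern around pairs, binned by distance
#'
#' For each spatial-distance bin, computes the elementwise mean of the
#' `window` x `window` patches of the zero-padded DI map centred at every
#' pair whose minimum heavy-atom distance falls in the bin. With a
#' secondary structure supplied, only pairs outside an
#' `exclusionWindow` x `exclusionWindow` square around every 2D pair are
#' averaged (the tertiary variant of the analysis). Empty bins yield a
#' patch of `NaN` and a message.
#'
#' @param di A [DIMap] or numeric matrix.
#' @param dist Numeric L x L distance matrix (Angstrom), e.g. from a
#'   [ContactMap].
#' @param window Odd patch size (default 7).
#' @param breaks Distance bin edges; default `c(0, 4, 10, Inf)` giving
#'   bins (0,4], (4,10] and (10,Inf).
#' @param ss Optional [SecondaryStructure] enabling the exclusion.
#' @param exclusionWindow Odd exclusion window around 2D pairs (default 9).
#' @param minSeparation Minimum |i - j| for averaged pairs (default 0:
#'   all off-diagonal pairs).
#' @return Named list of `window` x `window` mean patterns, one per bin,
#'   with an `n` attribute giving the number of pairs averaged.
#' @export
windowFeatureAverage <- function(di, dist, window = 7L,
                                 breaks = c(0, 4, 10, Inf), ss = NULL,
                                 exclusionWindow = 9L,
                                 minSeparation = 0L) {
  checkOdd(window, "pattern window")
  m <- if (is(di, "DIMap")) diMatrix(di) else di
  if (is(dist, "ContactMap")) dist <- distanceMatrix(dist)
  L <- nrow(m)
  P <- padMap(m, window)
  ij <- bandPairs(L, minSeparation)
  if (!is.null(ss)) {
    elig <- tertiaryMask(L, ss, exclusionWindow)
    ij <- ij[elig[ij], , drop = FALSE]
  }
  dv <- dist[ij]
  ok <- !is.na(dv)
  ij <- ij[ok, , drop = FALSE]
  dv <- dv[ok]
  bin <- cut(dv, breaks, include.lowest = FALSE, right = TRUE)
  out <- list()
  for (b in levels(bin)) {
    rows <- which(bin == b)
    if (length(rows) == 0L) {
      message(sprintf("no pairs in distance bin %s", b))
      pat <- matrix(NaN, window, window)
    } else {
      acc <- matrix(0, window, window)
      for (r in rows) {
        i <- ij[r, 1L]
        j <- ij[r, 2L]
        acc <- acc + P[i:(i + window - 1L), j:(j + window - 1L)]
      }
      pat <- acc / length(rows)
    }
    attr(pat, "n") <- length(rows)
    out[[b]] <- pat
  }
  out
}
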