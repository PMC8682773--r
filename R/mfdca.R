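## mfdca_core: sequence weights, regularized frequencies, mean-field
## couplings and direct-information scoring.
##
## Model: P(sigma) = exp(sum_{i<j} J_ij(a_i,a_j) + sum_i h_i(a_i)) / Z over
## the 5-state alphabet. The mean-field inverse solves J = -C^{-1} where C
## is the connected correlation matrix of the reweighted, pseudocounted
## frequencies, computed in a reduced (q-1)-state basis with the gap as the
## excluded reference state (the full-q C is gauge-singular).

#' @rdname SequenceWeights
#' @export
setClass("SequenceWeights",
  representation(omega = "numeric", meff = "numeric", threshold = "numeric"))

setValidity("SequenceWeights", function(object) {
  if (any(object@omega <= 0 | object@omega > 1)) {
    return("weights must lie in (0, 1]")
  }
  if (abs(object@meff - sum(object@omega)) > 1e-8) {
    return("meff must equal the sum of the weights")
  }
  TRUE
})

#' Similarity-based sequence weights
#'
#' Each sequence m receives weight 1 / (number of sequences, itself
#' included, whose identity fraction with m is at least the similarity
#' threshold); M_eff is the sum of these weights.
#'
#' @param omega Numeric vector of per-sequence weights in (0, 1].
#' @param threshold Similarity threshold used, in (0, 1].
#' @return An object of class `SequenceWeights`.
#' @export
SequenceWeights <- function(omega, threshold) {
  new("SequenceWeights", omega = omega, meff = sum(omega),
      threshold = threshold)
}

#' @rdname accessors
setMethod("effectiveSequences", "SequenceWeights", function(x) x@meff)

setMethod("show", "SequenceWeights", function(object) {
  cat(sprintf("SequenceWeights: M = %d, M_eff = %.2f (threshold %.2f)\n",
              length(object@omega), object@meff, object@threshold))
})

#' @rdname FrequencySet-class
#' @export
setClass("FrequencySet",
  representation(f1 = "matrix", f2 = "matrix", lambda = "numeric",
                 q = "integer"))

#' Reweighted, pseudocounted frequency counts
#'
#' Single-site frequencies f_i(a) = (lambda/q + sum_m omega_m
#' delta(a, a_i^m)) / (M_eff + lambda) and pair frequencies f_ij(a, b) =
#' (lambda/q^2 + sum_m omega_m delta(a, a_i^m) delta(b, a_j^m)) /
#' (M_eff + lambda), with the gap counted as an ordinary state. `f2` is
#' stored as an (L q) x (L q) block matrix; block (i, j) holds the q x q
#' table f_ij. Only off-diagonal site blocks follow the pair formula; the
#' diagonal blocks are replaced by single-site statistics when the
#' correlation matrix is built.
#'
#' @name FrequencySet-class
NULL

setMethod("show", "FrequencySet", function(object) {
  cat(sprintf("FrequencySet: L = %d, q = %d, lambda = %.4g\n",
              nrow(object@f1), object@q, object@lambda))
})

#' @rdname CouplingModel-class
#' @export
setClass("CouplingModel",
  representation(corr = "matrix", couplings = "matrix", L = "integer",
                 qReduced = "integer"))

#' Mean-field coupling model
#'
#' Connected correlation matrix C_ij(a,b) = f_ij(a,b) - f_i(a) f_j(b) in
#' the reduced (q-1)-state basis (gap excluded as reference state) and the
#' mean-field couplings J = -C^{-1}, both stored as L(q-1) x L(q-1) block
#' matrices.
#'
#' @name CouplingModel-class
NULL

setMethod("show", "CouplingModel", function(object) {
  cat(sprintf("CouplingModel: L = %d sites, %d reduced states\n",
              object@L, object@qReduced))
})

#' Compute similarity-based sequence weights
#'
#' The weight of sequence m is the reciprocal of the number of sequences
#' (itself included) whose fraction of identical alignment positions,
#' gaps compared like any other state, is at least `threshold`.
#'
#' @param msa A trimmed [RnaMsa].
#' @param threshold Identity fraction in (0, 1] above which two sequences
#'   count as similar. Default 0.8, the mean-field DCA standard.
#' @return A [SequenceWeights].
#' @export
computeWeights <- function(msa, threshold = 0.8) {
  if (threshold <= 0 || threshold > 1) {
    stopInput("similarity threshold must be in (0, 1], got %g", threshold)
  }
  a <- msaMatrix(msa)
  L <- ncol(a)
  oh <- oneHot(a)
  matches <- tcrossprod(oh)            # pairwise identical-position counts
  neighbors <- rowSums(matches / L >= threshold)
  SequenceWeights(1 / neighbors, threshold)
}

#' Compute reweighted, pseudocounted frequencies
#'
#' @param msa A trimmed [RnaMsa].
#' @param weights A [SequenceWeights] for the same alignment.
#' @param lambda Pseudocount, >= 0. A common choice is 0.5 * M_eff.
#' @return A [FrequencySet].
#' @export
computeFrequencies <- function(msa, weights, lambda) {
  if (lambda < 0) stopInput("pseudocount lambda must be >= 0, got %g", lambda)
  a <- msaMatrix(msa)
  q <- rnaStates()
  L <- ncol(a)
  omega <- weights@omega
  meff <- weights@meff
  oh <- oneHot(a)
  c1 <- as.vector(crossprod(oh, omega))            # weighted single counts
  c2 <- crossprod(oh, oh * omega)                  # weighted pair counts
  f1 <- t(matrix((lambda / q + c1) / (meff + lambda), nrow = q))
  f2 <- (lambda / q^2 + c2) / (meff + lambda)
  new("FrequencySet", f1 = f1, f2 = f2, lambda = lambda, q = as.integer(q))
}

#' Mean-field couplings from the inverse correlation matrix
#'
#' Builds the connected correlation matrix C over the reduced basis of
#' q - 1 = 4 states per site (the gap is the excluded reference state),
#' with diagonal site blocks diag(f_i) - f_i f_i^T, and returns
#' J = -C^{-1}.
#'
#' @param freqs A [FrequencySet].
#' @return A [CouplingModel].
#' @export
computeCouplings <- function(freqs) {
  q <- freqs@q
  qr <- q - 1L
  L <- nrow(freqs@f1)
  f1vec <- as.vector(t(freqs@f1))                  # site-major, q per site
  C <- freqs@f2 - tcrossprod(f1vec)
  for (i in seq_len(L)) {                          # single-site diagonal blocks
    idx <- (i - 1L) * q + seq_len(q)
    fi <- freqs@f1[i, ]
    C[idx, idx] <- diag(fi) - tcrossprod(fi)
  }
  keep <- which(rep(seq_len(q), L) != q)           # drop the gap state
  C <- C[keep, keep]
  J <- tryCatch(-solve(C), error = function(e) {
    stopNumerical("correlation matrix is singular (%s); use lambda > 0",
                  conditionMessage(e))
  })
  new("CouplingModel", corr = C, couplings = J, L = L,
      qReduced = as.integer(qr))
}

## Embed a reduced (q-1)x(q-1) coupling block into q x q with the gap
## row/column fixed at zero (the reference-state gauge).
expandCouplingBlock <- function(model, i, j) {
  qr <- model@qReduced
  q <- qr + 1L
  block <- matrix(0, q, q)
  ri <- (i - 1L) * qr + seq_len(qr)
  rj <- (j - 1L) * qr + seq_len(qr)
  block[seq_len(qr), seq_len(qr)] <- model@couplings[ri, rj]
  block
}

#' Fit the two-site direct model fields
#'
#' Finds fields h_i, h_j such that the two-site direct probability
#' p_ij(a, b) = exp(J_ij(a, b) + h_i(a) + h_j(b)) / Z_ij has marginals
#' matching the single-site frequencies f_i and f_j. Solved by an
#' alternating marginal-matching fixed point (iterative proportional
#' fitting in multiplicative form).
#'
#' @param J q x q coupling block (full basis; gap row/column zero).
#' @param fi,fj Strictly positive length-q marginals.
#' @param tol Convergence tolerance on the maximum marginal residual.
#' @param maxIter Maximum number of sweeps before failing.
#' @return List with `pdir` (q x q direct probability), `hi`, `hj`
#'   (fitted fields, up to additive gauge), `residual` and `iterations`.
#' @export
fitTwoSiteFields <- function(J, fi, fj, tol = 1e-6, maxIter = 500L) {
  if (any(fi <= 0) || any(fj <= 0)) {
    stopInput("marginals must be strictly positive (use lambda > 0)")
  }
  W <- exp(J)
  q <- length(fi)
  mi <- rep(1 / q, q)
  mj <- rep(1 / q, q)
  residual <- Inf
  for (it in seq_len(maxIter)) {
    mi <- fi / as.vector(W %*% mj)
    mj <- fj / as.vector(crossprod(W, mi))
    p <- (mi * W) * rep(mj, each = q)
    p <- p / sum(p)
    residual <- max(abs(rowSums(p) - fi), abs(colSums(p) - fj))
    if (residual < tol) {
      return(list(pdir = p, hi = log(mi), hj = log(mj),
                  residual = residual, iterations = it))
    }
  }
  stopNumerical(
    "two-site field fit did not converge: residual %.3g after %d iterations",
    residual, maxIter)
}

## DI contribution of one pair from its direct probability and marginals.
pairDirectInformation <- function(pdir, fi, fj) {
  ref <- tcrossprod(fi, fj)
  sum(pdir * log(pdir / ref))
}

#' Direct-information score map from an alignment
#'
#' Runs the full mean-field DCA pipeline: sequence weights, reweighted
#' pseudocounted frequencies, inverse-correlation couplings, per-pair
#' two-site field fitting, and the direct information
#' DI_ij = sum_ab p_ij(a,b) log(p_ij(a,b) / (f_i(a) f_j(b))), a
#' Kullback-Leibler divergence and hence nonnegative. The sum runs over
#' all q states including the gap.
#'
#' @param msa An [RnaMsa]; trimmed to target coordinates if it is not
#'   already.
#' @param threshold Similarity threshold for sequence weighting.
#' @param lambda Pseudocount; default `0.5 * M_eff`.
#' @param tol Marginal-matching tolerance for the per-pair field fit.
#' @param maxIter Iteration cap for the field fit.
#' @return A [DIMap] (symmetric, zero diagonal).
#' @export
#' @examples
#' model <- plantedStemModel(L = 24, nStems = 1, nTertiary = 1, seed = 7)
#' fam <- sampleMsa(model, M = 150, seed = 7)
#' di <- directInformation(fam$msa)
#' di
directInformation <- function(msa, threshold = 0.8, lambda = NULL,
                              tol = 1e-6, maxIter = 500L) {
  if (length(columnMap(msa)) == 0L) msa <- trimToTarget(msa)
  w <- computeWeights(msa, threshold)
  if (is.null(lambda)) lambda <- 0.5 * w@meff
  freqs <- computeFrequencies(msa, w, lambda)
  model <- computeCouplings(freqs)
  L <- model@L
  di <- matrix(0, L, L)
  for (i in seq_len(L - 1L)) {
    fi <- freqs@f1[i, ]
    for (j in seq(i + 1L, L)) {
      J <- expandCouplingBlock(model, i, j)
      fit <- fitTwoSiteFields(J, fi, freqs@f1[j, ], tol = tol,
                              maxIter = maxIter)
      di[i, j] <- di[j, i] <- pairDirectInformation(fit$pdir, fi,
                                                    freqs@f1[j, ])
    }
  }
  di <- pmax(di, 0)                     # clip numerical -1e-16 noise
  DIMap(di, meff = w@meff, targetSeq = targetSequence(msa),
        params = list(threshold = threshold, lambda = lambda, tol = tol))
}

#' Write a DI map as a TSV edge list or square matrix
#'
#' @param di A [DIMap].
#' @param path Output path.
#' @param format `"tsv"` (columns i, j, score over i < j; 1-based) or
#'   `"matrix"` (whitespace-delimited square matrix).
#' @return Invisibly, `path`.
#' @export
writeDiTsv <- function(di, path, format = c("tsv", "matrix")) {
  format <- match.arg(format)
  m <- diMatrix(di)
  if (format == "matrix") {
    utils::write.table(m, path, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
  } else {
    ij <- which(upper.tri(m), arr.ind = TRUE)
    ij <- ij[order(ij[, 1L], ij[, 2L]), , drop = FALSE]
    utils::write.table(
      data.frame(i = ij[, 1L], j = ij[, 2L], score = m[ij]),
      path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
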