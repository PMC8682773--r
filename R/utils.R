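## Internal helpers shared across modules.

stopInput <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("coconet_input_error", "error", "condition")))
}

stopNumerical <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("coconet_numerical_error", "error",
                                "condition")))
}

checkOdd <- function(d, what = "filter size") {
  if (length(d) != 1L || is.na(d) || d < 1L || d %% 2L == 0L) {
    stopInput("%s must be a positive odd integer (got %s)", what,
              paste(d, collapse = ","))
  }
  invisible(as.integer(d))
}

## Logical L x L mask of pairs with |i - j| > minSeparation (both triangles).
separationMask <- function(L, minSeparation = 4L) {
  idx <- seq_len(L)
  abs(outer(idx, idx, "-")) > minSeparation
}

## Upper-triangle (i < j) index pairs with j - i > minSeparation.
bandPairs <- function(L, minSeparation = 4L) {
  ij <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
  ij <- ij[ij[, 2L] - ij[, 1L] > minSeparation, , drop = FALSE]
  colnames(ij) <- c("i", "j")
  ij[order(ij[, 1L], ij[, 2L]), , drop = FALSE]
}

## One-hot encoding of an integer-coded alignment: M x (L * q) with the
## column block for site j occupying columns (j-1)*q + 1 .. j*q.
oneHot <- function(codes, q = rnaStates()) {
  M <- nrow(codes)
  L <- ncol(codes)
  oh <- matrix(0, M, L * q)
  cols <- (rep(seq_len(L) - 1L, each = M)) * q + as.vector(codes)
  oh[cbind(rep.int(seq_len(M), L), cols)] <- 1
  oh
}
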