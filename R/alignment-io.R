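## alignment_io: reading, encoding and target-trimming of RNA MSAs.

#' Encode RNA sequences as integer codes
#'
#' Uppercases, maps T to U, reads '.', '-' and '~' as the gap state, and
#' maps IUPAC ambiguity codes (N, R, Y, ...) and any other symbol to gap.
#' Codes are 1..5 in the fixed order A, C, G, U, gap.
#'
#' @param seqs Character vector of aligned sequences (equal lengths).
#' @return List with `codes` (integer matrix) and `ambiguous` (count of
#'   non-ACGU, non-gap symbols mapped to gap).
#' @export
encodeSequences <- function(seqs) {
  n <- unique(nchar(seqs))
  if (length(n) != 1L) {
    stopInput("alignment is ragged: sequence lengths %s",
              paste(sort(n), collapse = ", "))
  }
  chars <- toupper(do.call(rbind, strsplit(seqs, "", fixed = TRUE)))
  chars[chars == "T"] <- "U"
  chars[chars %in% c(".", "~")] <- "-"
  codes <- match(chars, rnaAlphabet())
  ambiguous <- sum(is.na(codes))
  codes[is.na(codes)] <- rnaStates()
  list(codes = matrix(codes, nrow = length(seqs)),
       ambiguous = as.integer(ambiguous))
}

#' Decode an encoded MSA back to character sequences
#'
#' @param msa An [RnaMsa].
#' @return Character vector of aligned sequences (with `-` for gaps).
#' @export
decodeMsa <- function(msa) {
  apply(msaMatrix(msa), 1L, function(r) {
    paste(rnaAlphabet()[r], collapse = "")
  })
}

readFastaSequences <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  list(ids = ids, seqs = as.character(set))
}

readStockholmSequences <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  seqs <- list()
  order <- character(0)
  for (ln in lines) {
    if (startsWith(ln, "#") || startsWith(ln, "//")) next  # annotations
    parts <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(parts) != 2L) {
      stopInput("malformed Stockholm sequence line: '%s'", ln)
    }
    id <- parts[1L]
    if (is.null(seqs[[id]])) {
      seqs[[id]] <- parts[2L]
      order <- c(order, id)
    } else {
      seqs[[id]] <- paste0(seqs[[id]], parts[2L])  # interleaved blocks
    }
  }
  if (length(seqs) == 0L) stopInput("no sequences found in '%s'", path)
  list(ids = order, seqs = unlist(seqs[order], use.names = FALSE))
}

#' Read an RNA alignment with a designated target sequence
#'
#' Parses FASTA or Stockholm (including interleaved blocks; `#=GC`/`#=GS`
#' annotation lines are ignored), encodes over the 5-state alphabet and
#' designates the target row. Duplicate identifiers are rejected; a count
#' of ambiguity symbols mapped to gap is recorded on the returned object
#' and reported via a message.
#'
#' @param path Path to the alignment file.
#' @param targetId Identifier of the structural target sequence; defaults
#'   to the first sequence.
#' @param format `"fasta"` or `"stockholm"`.
#' @return An untrimmed [RnaMsa].
#' @seealso [trimToTarget()]
#' @export
readMsa <- function(path, targetId = NULL,
                    format = c("fasta", "stockholm")) {
  format <- match.arg(format)
  parsed <- switch(format,
    fasta = readFastaSequences(path),
    stockholm = readStockholmSequences(path))
  ids <- parsed$ids
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stopInput("duplicate sequence identifiers: %s",
              paste(dup, collapse = ", "))
  }
  if (is.null(targetId)) targetId <- ids[1L]
  targetRow <- match(targetId, ids)
  if (is.na(targetRow)) {
    stopInput("target id '%s' not found; available ids: %s", targetId,
              paste(utils::head(ids, 20L), collapse = ", "))
  }
  enc <- encodeSequences(parsed$seqs)
  if (enc$ambiguous > 0L) {
    message(sprintf("%d ambiguous symbols mapped to gap", enc$ambiguous))
  }
  rownames(enc$codes) <- ids
  RnaMsa(enc$codes, targetRow = targetRow, ambiguousCount = enc$ambiguous)
}

#' Trim an alignment to the coordinates of its target sequence
#'
#' Removes every column in which the target row carries a gap, so the
#' resulting width equals the ungapped target length L and positions are
#' 1-based target coordinates recorded in `columnMap`. Idempotent.
#'
#' @param msa An [RnaMsa].
#' @return A trimmed [RnaMsa].
#' @export
trimToTarget <- function(msa) {
  a <- msaMatrix(msa)
  keep <- a[targetIndex(msa), ] != rnaStates()
  if (!any(keep)) stopInput("target row contains only gaps")
  RnaMsa(a[, keep, drop = FALSE], targetRow = targetIndex(msa),
         columnMap = seq_len(sum(keep)),
         ambiguousCount = msa@ambiguousCount)
}

#' Write an encoded MSA as FASTA
#'
#' Round-trip writer used for fixtures and interoperability.
#'
#' @param msa An [RnaMsa].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
writeMsaFasta <- function(msa, path) {
  ids <- rownames(msaMatrix(msa))
  if (is.null(ids)) ids <- sprintf("seq%d", seq_len(nrow(msaMatrix(msa))))
  txt <- paste0(">", ids, "\n", decodeMsa(msa))
  writeLines(txt, path)
  invisible(path)
}
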