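## structure_contacts: ground-truth contact maps from experimental
## structures, plus WC / tertiary stratification masks.

#' Contact map from an experimental structure
#'
#' Reads a PDB or mmCIF model, keeps heavy atoms only (element not H/D;
#' for alternate locations, the highest-occupancy conformer), and computes
#' the minimum heavy-atom distance for every residue pair of the selected
#' chain. Residues are mapped onto the target sequence by exact ungapped
#' subsequence match, or through an explicit `mapping`; silent pairwise
#' alignment is deliberately not attempted, since a misalignment would
#' corrupt training labels. Contacts use the strict inequality
#' `dist < cutoff`.
#'
#' @param path Path to a PDB or mmCIF file (format chosen by extension).
#' @param chain Chain identifier; defaults to the first chain present.
#' @param targetSeq Target nucleotide sequence, as a character vector of
#'   single letters or one string.
#' @param cutoff Contact cutoff in Angstrom (default 10).
#' @param mapping Optional integer vector, one entry per target position,
#'   giving the index of the corresponding chain residue (`NA` = unmapped).
#' @return A [ContactMap]; unmapped target positions have `NA` distances.
#' @export
contactMapFromStructure <- function(path, chain = NULL, targetSeq,
                                    cutoff = 10, mapping = NULL) {
  if (length(targetSeq) == 1L && nchar(targetSeq) > 1L) {
    targetSeq <- strsplit(targetSeq, "")[[1L]]
  }
  L <- length(targetSeq)
  pdb <- if (grepl("\\.cif$", path, ignore.case = TRUE)) {
    bio3d::read.cif(path)
  } else {
    bio3d::read.pdb(path)
  }
  atoms <- pdb$atom
  if (is.null(chain)) chain <- atoms$chain[1L]
  atoms <- atoms[atoms$chain %in% chain, , drop = FALSE]
  if (nrow(atoms) == 0L) stopInput("no atoms found for chain '%s'", chain)
  elem <- toupper(trimws(atoms$elesy))
  blank <- is.na(elem) | elem == ""
  if (any(blank)) {        # infer element from the atom name when missing
    elem[blank] <- substr(gsub("[0-9']", "", trimws(atoms$elety[blank])),
                          1L, 1L)
  }
  atoms <- atoms[!elem %in% c("H", "D"), , drop = FALSE]
  if (nrow(atoms) == 0L) {
    stopInput("chain '%s' has no heavy atoms", chain)
  }
  ## residue key preserves insertion codes
  ins <- atoms$insert
  ins[is.na(ins)] <- ""
  resKey <- paste(atoms$resno, ins, sep = "_")
  resLevels <- unique(resKey)
  ## altloc: keep highest-occupancy conformer per (residue, atom name)
  occ <- atoms$o
  occ[is.na(occ)] <- 1
  ord <- order(match(resKey, resLevels), atoms$elety, -occ)
  atoms <- atoms[ord, , drop = FALSE]
  resKey <- resKey[ord]
  dupAtom <- duplicated(paste(resKey, atoms$elety))
  atoms <- atoms[!dupAtom, , drop = FALSE]
  resKey <- resKey[!dupAtom]
  resIdx <- match(resKey, resLevels)
  nRes <- length(resLevels)

  ## chain residue sequence, for the subsequence match
  resName <- toupper(trimws(atoms$resid[!duplicated(resIdx)]))
  oneLetter <- c(A = "A", C = "C", G = "G", U = "U", T = "U",
                 ADE = "A", CYT = "C", GUA = "G", URA = "U", URI = "U")
  chainSeq <- unname(oneLetter[resName])
  chainSeq[is.na(chainSeq)] <- "X"

  if (is.null(mapping)) {
    hit <- regexpr(paste(chainSeq, collapse = ""),
                   paste(toupper(targetSeq), collapse = ""), fixed = TRUE)
    if (hit < 0L) {
      stopInput(paste0("chain sequence is not an exact subsequence of the ",
                       "target; supply an explicit mapping"))
    }
    mapping <- rep(NA_integer_, L)
    mapping[seq(hit, length.out = nRes)] <- seq_len(nRes)
  } else {
    if (length(mapping) != L) {
      stopInput("mapping must have one entry per target position")
    }
    mapping <- as.integer(mapping)
  }

  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  atomDist <- as.matrix(stats::dist(xyz))
  resDist <- matrix(Inf, nRes, nRes)
  ## minimum over atom pairs, aggregated by residue
  for (r in seq_len(nRes)) {
    rows <- which(resIdx == r)
    sub <- atomDist[rows, , drop = FALSE]
    mins <- vapply(seq_len(nRes), function(s) {
      min(sub[, resIdx == s, drop = FALSE])
    }, numeric(1))
    resDist[r, ] <- pmin(resDist[r, ], mins)
  }
  dist <- matrix(NA_real_, L, L)
  mapped <- which(!is.na(mapping))
  dist[mapped, mapped] <- resDist[mapping[mapped], mapping[mapped]]
  ContactMap(dist, cutoff = cutoff, mapping = mapping)
}

#' Parse dot-bracket secondary structure
#'
#' Round brackets form the nested (2D) tier; other bracket families
#' (`[]`, `{}`, `<>`, `Aa`, `Bb`, ...) are read as pseudoknot tiers and
#' flagged, so downstream stratification treats them as tertiary.
#'
#' @param x A dot-bracket string, or a path to a file whose last
#'   non-empty, non-header line is the dot-bracket string.
#' @return A [SecondaryStructure].
#' @export
readDotBracket <- function(x) {
  if (length(x) == 1L && file.exists(x)) {
    lines <- readLines(x, warn = FALSE)
    lines <- trimws(lines[!grepl("^\\s*$|^>|^#", lines)])
    db <- lines[grepl("^[.()\\[\\]{}<>A-Za-z]+$", lines)]
    if (length(db) == 0L) stopInput("no dot-bracket line found in '%s'", x)
    x <- db[length(db)]
  }
  chars <- strsplit(x, "")[[1L]]
  L <- length(chars)
  openers <- c("(", "[", "{", "<", LETTERS)
  closers <- c(")", "]", "}", ">", letters)
  pairs <- list()
  for (tier in seq_along(openers)) {
    op <- openers[tier]
    cl <- closers[tier]
    stack <- integer(0)
    for (k in seq_len(L)) {
      if (chars[k] == op) {
        stack <- c(stack, k)
      } else if (chars[k] == cl) {
        if (length(stack) == 0L) {
          stopInput("unbalanced '%s' at position %d", cl, k)
        }
        pairs[[length(pairs) + 1L]] <-
          c(stack[length(stack)], k, tier != 1L)
        stack <- stack[-length(stack)]
      }
    }
    if (length(stack) > 0L) {
      stopInput("unbalanced '%s' (%d unclosed)", op, length(stack))
    }
  }
  tab <- if (length(pairs) == 0L) {
    data.frame(i = integer(0), j = integer(0), pseudoknot = logical(0))
  } else {
    m <- do.call(rbind, pairs)
    data.frame(i = as.integer(m[, 1L]), j = as.integer(m[, 2L]),
               pseudoknot = as.logical(m[, 3L]))
  }
  tab <- tab[order(tab$i), , drop = FALSE]
  rownames(tab) <- NULL
  SecondaryStructure(tab, length = L, source = "dot-bracket")
}

#' Parse a CT-format secondary structure file
#'
#' Standard connectivity-table format: a header line with the length,
#' then one line per position whose fifth field is the paired position
#' (0 = unpaired). CT carries no pseudoknot tiers, so every pair is
#' reported as nested.
#'
#' @param path Path to the CT file.
#' @return A [SecondaryStructure].
#' @export
readCtFile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  L <- suppressWarnings(as.integer(header[1L]))
  if (is.na(L)) stopInput("CT header must start with the sequence length")
  body <- lines[-1L][seq_len(L)]
  fields <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), "[", 1:6))
  i <- as.integer(fields[, 1L])
  j <- as.integer(fields[, 5L])
  keep <- j > i                        # report each pair once, i < j
  tab <- data.frame(i = i[keep], j = j[keep],
                    pseudoknot = rep(FALSE, sum(keep)))
  SecondaryStructure(tab, length = L, source = "ct")
}

#' Watson-Crick pair mask of a target sequence
#'
#' `TRUE` at (i, j) iff the nucleotides form (A,U) or (C,G) in either
#' order. G-U wobble pairs are non-Watson-Crick by this definition.
#'
#' @param targetSeq Character vector of nucleotides, or one string.
#' @return Symmetric logical L x L matrix (diagonal `FALSE`).
#' @export
#' @examples
#' wcMask("GUAC")
wcMask <- function(targetSeq) {
  if (length(targetSeq) == 1L && nchar(targetSeq) > 1L) {
    targetSeq <- strsplit(targetSeq, "")[[1L]]
  }
  s <- toupper(targetSeq)
  s[s == "T"] <- "U"
  partner <- c(A = "U", U = "A", C = "G", G = "C")[s]
  mask <- outer(partner, s, "==")
  mask[is.na(mask)] <- FALSE
  diag(mask) <- FALSE
  dimnames(mask) <- NULL
  mask
}

#' Tertiary-contact eligibility mask
#'
#' A pair (i, j) is tertiary-eligible iff it is not a nested secondary
#' pair and its Chebyshev distance in the map to every 2D pair (and its
#' transpose) exceeds (window - 1) / 2. Pseudoknot pairs do not generate
#' exclusion windows (they are not 2D).
#'
#' @param contacts A [ContactMap] (or an integer L for just the geometry).
#' @param ss A [SecondaryStructure].
#' @param window Odd exclusion window size; 5 for evaluation
#'   stratification, 9 for the coevolutionary-pattern analysis.
#' @return Symmetric logical L x L matrix (diagonal `FALSE`).
#' @export
tertiaryMask <- function(contacts, ss, window = 5L) {
  checkOdd(window, "exclusion window")
  L <- if (is(contacts, "ContactMap")) nrow(contacts@dist) else
    as.integer(contacts)
  radius <- (window - 1L) %/% 2L
  eligible <- matrix(TRUE, L, L)
  diag(eligible) <- FALSE
  p <- secondaryPairs(ss)
  nested <- p[!p$pseudoknot, , drop = FALSE]
  for (k in seq_len(nrow(nested))) {
    for (center in list(c(nested$i[k], nested$j[k]),
                        c(nested$j[k], nested$i[k]))) {
      rows <- max(1L, center[1L] - radius):min(L, center[1L] + radius)
      cols <- max(1L, center[2L] - radius):min(L, center[2L] + radius)
      eligible[rows, cols] <- FALSE
    }
  }
  eligible
}

#' Write a contact map as a TSV edge list
#'
#' @param contacts A [ContactMap].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeContactTsv <- function(contacts, path) {
  m <- contactMatrix(contacts)
  d <- distanceMatrix(contacts)
  ij <- which(upper.tri(m) & !is.na(m) & m, arr.ind = TRUE)
  ij <- ij[order(ij[, 1L], ij[, 2L]), , drop = FALSE]
  utils::write.table(
    data.frame(i = ij[, 1L], j = ij[, 2L], dist = d[ij]),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
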