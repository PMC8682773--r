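## synthetic_fixtures: seeded Potts-model alignment generator with planted
## stems and tertiary contacts, paired with schematic ground truth, so the
## whole pipeline can be exercised without any external data.

wcCouplingBlock <- function(beta) {
  ## favours Watson-Crick combinations (A,U), (U,A), (C,G), (G,C)
  J <- matrix(0, rnaStates(), rnaStates())
  J[1L, 4L] <- J[4L, 1L] <- beta
  J[2L, 3L] <- J[3L, 2L] <- beta
  J
}

tertiaryCouplingBlock <- function(beta) {
  ## a non-Watson-Crick covariation pattern: (A,G), (G,A), (C,U), (U,C)
  J <- matrix(0, rnaStates(), rnaStates())
  J[1L, 3L] <- J[3L, 1L] <- beta
  J[2L, 4L] <- J[4L, 2L] <- beta
  J
}

#' Planted Potts model with stems and tertiary contacts
#'
#' Builds a pairwise Potts model over the 5-state RNA alphabet whose
#' coupling topology plants `nStems` hairpin stems (Watson-Crick
#' complementarity constraints between paired columns) and `nTertiary`
#' isolated long-range pairs carrying a weaker, non-Watson-Crick
#' covariation pattern - mimicking the observation that coevolutionary
#' signals of tertiary contacts are much weaker than those of stems.
#' Stems are laid out as one hairpin per equal-length segment; tertiary
#' pairs are drawn among unpaired positions, at sequence separation > 4
#' and at Chebyshev distance > 4 in the map from every stem pair, so they
#' remain scoreable and survive the stratification exclusion windows.
#'
#' @param L Sequence length.
#' @param nStems Number of planted hairpin stems.
#' @param stemLength Base pairs per stem.
#' @param nTertiary Number of planted tertiary pairs.
#' @param betaStem Coupling strength of stem pairs.
#' @param betaTertiary Coupling strength of tertiary pairs (must not
#'   exceed `betaStem`).
#' @param gapField Local field of the gap state (negative keeps gaps
#'   rare, as in curated seed alignments).
#' @param fieldSd Standard deviation of the random nucleotide fields.
#' @param seed RNG seed (fields and tertiary placement).
#' @return A [PlantedPottsModel-class] object.
#' @export
plantedStemModel <- function(L = 40L, nStems = 2L, stemLength = 5L,
                             nTertiary = 3L, betaStem = 2,
                             betaTertiary = 0.8, gapField = -2,
                             fieldSd = 0.2, seed = 1L) {
  L <- as.integer(L)
  if (betaTertiary > betaStem) {
    stopInput("tertiary couplings must not exceed stem couplings")
  }
  set.seed(seed)
  seg <- L %/% max(nStems, 1L)
  if (nStems > 0L && seg < 2L * stemLength + 7L) {
    stopInput("L = %d too short for %d stems of %d pairs", L, nStems,
              stemLength)
  }
  stemPairs <- matrix(0L, 0L, 2L)
  for (k in seq_len(nStems)) {
    start <- (k - 1L) * seg + 2L
    end <- k * seg - 1L
    t <- seq_len(stemLength) - 1L
    stemPairs <- rbind(stemPairs, cbind(start + t, end - t))
  }
  paired <- sort(unique(as.vector(stemPairs)))
  free <- setdiff(seq_len(L), paired)
  tertiaryPairs <- matrix(0L, 0L, 2L)
  used <- integer(0)
  tries <- 0L
  while (nrow(tertiaryPairs) < nTertiary) {
    tries <- tries + 1L
    if (tries > 2000L) {
      stopInput("could not place %d tertiary pairs; relax the topology",
                nTertiary)
    }
    cand <- sort(sample(setdiff(free, used), 2L))
    if (cand[2L] - cand[1L] <= 4L) next
    cheb <- pmin(
      apply(abs(sweep(stemPairs, 2L, cand, "-")), 1L, max),
      apply(abs(sweep(stemPairs[, 2:1, drop = FALSE], 2L, cand, "-")),
            1L, max))
    if (any(cheb <= 4L)) next
    tertiaryPairs <- rbind(tertiaryPairs, cand)
    used <- c(used, cand)
  }
  h <- cbind(matrix(stats::rnorm(4L * L, 0, fieldSd), L, 4L), gapField)
  edges <- rbind(stemPairs, tertiaryPairs)
  couplings <- c(
    replicate(nrow(stemPairs), wcCouplingBlock(betaStem),
              simplify = FALSE),
    replicate(nrow(tertiaryPairs), tertiaryCouplingBlock(betaTertiary),
              simplify = FALSE))
  db <- rep(".", L)
  db[stemPairs[, 1L]] <- "("
  db[stemPairs[, 2L]] <- ")"
  new("PlantedPottsModel", L = L, h = h,
      edges = matrix(as.integer(edges), ncol = 2L), couplings = couplings,
      stemPairs = matrix(as.integer(stemPairs), ncol = 2L),
      tertiaryPairs = matrix(as.integer(tertiaryPairs), ncol = 2L),
      dotBracket = paste(db, collapse = ""))
}

#' Exact distribution of a small planted model
#'
#' Enumerates all q^L states and returns their probabilities, for use as
#' an exact oracle against the Gibbs sampler on tiny systems.
#'
#' @param model A [PlantedPottsModel-class] with `L <= 8`.
#' @param allowGap Include the gap state (default `TRUE`).
#' @return List with `states` (q^L x L integer codes) and `prob`.
#' @export
enumeratePotts <- function(model, allowGap = TRUE) {
  q <- if (allowGap) rnaStates() else rnaStates() - 1L
  L <- model@L
  if (q^L > 4e5) stopInput("enumeration only supported for small q^L")
  states <- as.matrix(expand.grid(rep(list(seq_len(q)), L)))
  dimnames(states) <- NULL
  logw <- numeric(nrow(states))
  for (i in seq_len(L)) logw <- logw + model@h[i, states[, i]]
  for (e in seq_len(nrow(model@edges))) {
    i <- model@edges[e, 1L]
    j <- model@edges[e, 2L]
    J <- model@couplings[[e]]
    logw <- logw + J[cbind(states[, i], states[, j])]
  }
  w <- exp(logw - max(logw))
  list(states = states, prob = w / sum(w))
}

#' Sample an alignment family from a planted model
#'
#' Draws M sequences by single-site heat-bath Gibbs sampling (burn-in
#' `100 * L` sweeps, thinning 10 sweeps by default). The first row is the
#' designated target, drawn from the same model with the gap state
#' disallowed, so the returned alignment is already in target coordinates.
#' Ground truth is schematic: planted pairs sit at 3 A, the 8 map
#' neighbours (Chebyshev distance 1) of every stem pair at 8 A - giving
#' the thick anti-diagonal contact bands real stems produce at a 10 A
#' heavy-atom cutoff - chain neighbours at `2 |i - j|` A, and everything
#' else at 20 A. A dot-bracket annotation covers the stems.
#'
#' @param model A [PlantedPottsModel-class].
#' @param M Number of sequences (target included).
#' @param seed RNG seed.
#' @param burninSweeps Burn-in sweeps (default `100 * L`).
#' @param thinSweeps Sweeps between recorded samples (default 10).
#' @param cutoff Contact cutoff for the schematic ground truth (10 A).
#' @return List with `msa` ([RnaMsa], trimmed), `contacts` ([ContactMap]),
#'   `ss` ([SecondaryStructure]) and `model`.
#' @export
sampleMsa <- function(model, M = 2000L, seed = 1L, burninSweeps = NULL,
                      thinSweeps = 10L, cutoff = 10) {
  L <- model@L
  if (is.null(burninSweeps)) burninSweeps <- 100L * L
  set.seed(seed)
  target <- gibbsSamplePotts(L, rnaStates(), model@h, model@edges,
                             model@couplings, 1L, burninSweeps,
                             thinSweeps, FALSE)
  rest <- gibbsSamplePotts(L, rnaStates(), model@h, model@edges,
                           model@couplings, M - 1L, burninSweeps,
                           thinSweeps, TRUE)
  aln <- rbind(target, rest)
  rownames(aln) <- c("target", sprintf("seq%04d", seq_len(M - 1L)))
  msa <- RnaMsa(aln, targetRow = 1L, columnMap = seq_len(L))

  idx <- seq_len(L)
  sep <- abs(outer(idx, idx, "-"))
  dist <- pmin(2 * sep, 20)
  dist[sep == 0L] <- 0
  planted <- rbind(model@stemPairs, model@tertiaryPairs)
  for (k in seq_len(nrow(model@stemPairs))) {      # stem neighbourhoods
    i <- model@stemPairs[k, 1L]
    j <- model@stemPairs[k, 2L]
    rows <- max(1L, i - 1L):min(L, i + 1L)
    cols <- max(1L, j - 1L):min(L, j + 1L)
    dist[rows, cols] <- pmin(dist[rows, cols], 8)
    dist[cols, rows] <- pmin(dist[cols, rows], 8)
  }
  dist[planted] <- 3
  dist[planted[, 2:1, drop = FALSE]] <- 3
  contacts <- ContactMap(dist, cutoff = cutoff)
  ss <- readDotBracket(model@dotBracket)
  list(msa = msa, contacts = contacts, ss = ss, model = model)
}

#' Generate a synthetic training suite
#'
#' Seeded families of varied length, stem layout and tertiary-pair count,
#' each with a sampled alignment, DI map, schematic contact map and
#' secondary structure - everything [crossValidate()] needs. Passing a
#' vector for `M` (e.g. `c(2000, 60)`) spans the effective-sequence-number
#' regimes above and below the M_eff = 70 split used when stratifying
#' real families by alignment depth.
#'
#' @param nFamilies Number of families (>= 5 for 5-fold CV).
#' @param M Sequences per family (recycled across families).
#' @param seed Master seed; the whole suite is deterministic given it.
#' @param Lrange Inclusive range lengths are drawn from.
#' @param nStems,stemLength,nTertiary,betaStem,betaTertiary Passed to
#'   [plantedStemModel()].
#' @param threshold,lambda Passed to [directInformation()].
#' @return List of [TrainingPair] objects.
#' @export
makeTrainingSuite <- function(nFamilies = 10L, M = 2000L, seed = 1L,
                              Lrange = c(36L, 44L), nStems = 2L,
                              stemLength = 5L, nTertiary = 3L,
                              betaStem = 2, betaTertiary = 0.8,
                              threshold = 0.8, lambda = NULL) {
  if (nFamilies < 1L) stopInput("nFamilies must be >= 1")
  set.seed(seed)
  famSeeds <- sample.int(2^20, 2L * nFamilies)
  M <- rep_len(as.integer(M), nFamilies)
  Ls <- sample(seq(Lrange[1L], Lrange[2L]), nFamilies, replace = TRUE)
  lapply(seq_len(nFamilies), function(f) {
    model <- plantedStemModel(L = Ls[f], nStems = nStems,
                              stemLength = stemLength,
                              nTertiary = nTertiary, betaStem = betaStem,
                              betaTertiary = betaTertiary,
                              seed = famSeeds[2L * f - 1L])
    fam <- sampleMsa(model, M = M[f], seed = famSeeds[2L * f])
    di <- directInformation(fam$msa, threshold = threshold,
                            lambda = lambda)
    TrainingPair(di, fam$contacts, ss = fam$ss,
                 familyId = sprintf("SYN%03d", f))
  })
}

#' Write a dot-bracket annotation file
#'
#' @param ss A [SecondaryStructure] built from dot-bracket, or a
#'   dot-bracket string.
#' @param path Output path.
#' @param sequence Optional sequence line written above the structure.
#' @return Invisibly, `path`.
#' @export
writeDotBracket <- function(ss, path, sequence = NULL) {
  db <- if (is(ss, "SecondaryStructure")) {
    chars <- rep(".", ss@length)
    p <- secondaryPairs(ss)
    nested <- p[!p$pseudoknot, , drop = FALSE]
    chars[nested$i] <- "("
    chars[nested$j] <- ")"
    pk <- p[p$pseudoknot, , drop = FALSE]
    chars[pk$i] <- "["
    chars[pk$j] <- "]"
    paste(chars, collapse = "")
  } else {
    ss
  }
  writeLines(c(if (!is.null(sequence)) sequence, db), path)
  invisible(path)
}

#' Write a minimal synthetic PDB coordinate file
#'
#' Schematic coordinates for testing the structure reader: one P
#' pseudo-atom per residue along the x axis (6 A spacing, so only chain
#' neighbours are in contact), plus one extra C1' heavy atom on each
#' member of every planted pair, placed so the pair's minimum heavy-atom
#' distance is 3 A and distinct pairs never interfere. Purely synthetic
#' geometry - not a model of RNA shape.
#'
#' @param targetSeq Character vector or string of nucleotides (residue
#'   names in the file).
#' @param plantedPairs Integer matrix (n x 2) of pairs to bring close.
#' @param path Output path.
#' @param chain Chain identifier (default "A").
#' @return Invisibly, `path`.
#' @export
writeSyntheticPdb <- function(targetSeq, plantedPairs, path, chain = "A") {
  if (length(targetSeq) == 1L && nchar(targetSeq) > 1L) {
    targetSeq <- strsplit(targetSeq, "")[[1L]]
  }
  L <- length(targetSeq)
  rec <- function(serial, name, resid, resno, x, y, z, elem) {
    sprintf("ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, name, resid, chain, resno, x, y, z, 1, 0, elem)
  }
  lines <- character(0)
  serial <- 0L
  for (i in seq_len(L)) {
    serial <- serial + 1L
    lines <- c(lines, rec(serial, "P", targetSeq[i], i,
                          6 * (i - 1), 0, 0, "P"))
  }
  for (k in seq_len(nrow(plantedPairs))) {
    i <- plantedPairs[k, 1L]
    j <- plantedPairs[k, 2L]
    xm <- 3 * (i + j - 2)
    y <- 15 + 10 * k
    serial <- serial + 1L
    lines <- c(lines, rec(serial, "C1'", targetSeq[i], i,
                          xm - 1.5, y, 0, "C"))
    serial <- serial + 1L
    lines <- c(lines, rec(serial, "C1'", targetSeq[j], j,
                          xm + 1.5, y, 0, "C"))
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
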