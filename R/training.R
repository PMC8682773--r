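## training: convex least-squares filter learning over (DI map, contact
## map) training pairs, with repeated k-fold cross-validation.
##
## The objective is F = sum_R sum_{j > i + 4} (W * D_ij - delta_ij)^2,
## where W * D_ij is the raw cross-correlation of the filter with the
## d x d window of the padded DI map centred at (i, j) and delta_ij is
## the binary structural contact label. Because the convolution is linear
## in the filter weights this is an ordinary least-squares problem: each
## band pair contributes one design row holding its vectorized window.

## Training functions accept either a TrainingPair or a plain list with
## elements di (matrix), labels (matrix; may be continuous, e.g. for
## calibration against synthesized targets) and optionally wcMask.
asTrainingData <- function(pair) {
  if (is(pair, "TrainingPair")) {
    list(di = diMatrix(pair), labels = contactMatrix(pair),
         wcMask = pair@wcMask)
  } else if (is.list(pair) && !is.null(pair$di) && !is.null(pair$labels)) {
    pair
  } else {
    stopInput(
      "training entries must be TrainingPair objects or lists with 'di' and 'labels'")
  }
}

## Design matrix and label vector of one training pair. Columns follow
## column-major filter vectorization; dual mode concatenates the WC and
## non-WC blocks. Rows with NA labels (unmapped positions) are dropped.
buildDesign <- function(pair, d, mode, minSeparation = 4L) {
  td <- asTrainingData(pair)
  m <- td$di
  L <- nrow(m)
  ij <- bandPairs(L, minSeparation)
  y <- td$labels[ij]
  blockFor <- function(map) {
    P <- padMap(map, d)
    X <- matrix(0, nrow(ij), d * d)
    for (v in seq_len(d)) {
      for (u in seq_len(d)) {
        X[, (v - 1L) * d + u] <- P[cbind(ij[, 1L] + u - 1L,
                                         ij[, 2L] + v - 1L)]
      }
    }
    X
  }
  X <- if (mode == "dual") {
    if (is.null(td$wcMask)) stopInput("dual mode requires a wcMask")
    cbind(blockFor(m * td$wcMask), blockFor(m * !td$wcMask))
  } else {
    blockFor(m)
  }
  keep <- !is.na(y)
  list(X = X[keep, , drop = FALSE], y = as.numeric(y[keep]))
}

filterVector <- function(filters) {
  unlist(lapply(filters@filters, as.vector), use.names = FALSE)
}

vectorToFilters <- function(w, d, mode) {
  if (mode == "dual") {
    FilterSet(list(wc = matrix(w[seq_len(d * d)], d, d),
                   nonwc = matrix(w[d * d + seq_len(d * d)], d, d)))
  } else {
    FilterSet(matrix(w, d, d))
  }
}

#' Least-squares cost of a filter set on a training set
#'
#' Exact sum of squared residuals between the convolved score and the
#' binary contact label over every family and every pair with
#' j > i + minSeparation (upper triangle only).
#'
#' @param filters A [FilterSet].
#' @param pairs List of [TrainingPair] objects.
#' @param minSeparation Sequence-separation band excluded from the sum.
#' @return Scalar cost.
#' @export
filterCost <- function(filters, pairs, minSeparation = 4L) {
  if (length(pairs) == 0L) stopInput("training set is empty")
  w <- filterVector(filters)
  total <- 0
  for (pair in pairs) {
    dn <- buildDesign(pair, filters@d, filters@mode, minSeparation)
    total <- total + sum((dn$X %*% w - dn$y)^2)
  }
  total
}

#' Analytic gradient of the training cost
#'
#' Gradient of [filterCost()] with respect to the filter weights
#' (column-major vectorization; dual mode concatenates the WC block then
#' the non-WC block): the residual back-correlated onto each window
#' entry, 2 * X' (X w - y).
#'
#' @inheritParams filterCost
#' @return Numeric gradient vector of length d^2 (single) or 2 d^2 (dual).
#' @export
filterCostGradient <- function(filters, pairs, minSeparation = 4L) {
  if (length(pairs) == 0L) stopInput("training set is empty")
  w <- filterVector(filters)
  g <- numeric(length(w))
  for (pair in pairs) {
    dn <- buildDesign(pair, filters@d, filters@mode, minSeparation)
    g <- g + 2 * as.vector(crossprod(dn$X, dn$X %*% w - dn$y))
  }
  g
}

#' Train filter weights by convex least squares
#'
#' Minimizes the single-batch squared-residual objective with L-BFGS-B
#' using the analytic gradient. The objective is convex (quadratic), so
#' the minimizer is independent of the initialization whenever the design
#' has full column rank; a rank-deficient design triggers a warning and
#' the returned filter is the optimization path's minimizer from the
#' given start (zero by default).
#'
#' @param pairs List of [TrainingPair] objects.
#' @param mode `"single"` or `"dual"` (Watson-Crick routed) convolution.
#' @param d Odd filter size (3, 5 or 7 are the standard choices).
#' @param init Optional initial [FilterSet] or numeric weight vector;
#'   defaults to zero weights.
#' @param minSeparation Sequence-separation band excluded from training.
#' @param pgtol Projected-gradient tolerance for L-BFGS-B.
#' @param maxit Iteration cap.
#' @return A [FilterSet] with attributes `cost` (final objective) and
#'   `convergence` (optim convergence code).
#' @export
trainFilters <- function(pairs, mode = c("single", "dual"), d = 3L,
                         init = NULL, minSeparation = 4L, pgtol = 1e-8,
                         maxit = 1000L) {
  mode <- match.arg(mode)
  checkOdd(d)
  if (length(pairs) == 0L) stopInput("training set is empty")
  p <- if (mode == "dual") 2L * d * d else d * d
  XtX <- matrix(0, p, p)
  Xty <- numeric(p)
  yty <- 0
  nRows <- 0L
  for (pair in pairs) {
    dn <- buildDesign(pair, d, mode, minSeparation)
    XtX <- XtX + crossprod(dn$X)
    Xty <- Xty + as.vector(crossprod(dn$X, dn$y))
    yty <- yty + sum(dn$y^2)
    nRows <- nRows + length(dn$y)
  }
  if (nRows < p) {
    warning(sprintf("only %d in-band pairs for %d parameters", nRows, p))
  }
  if (qr(XtX)$rank < p) {
    warning(paste("rank-deficient training design: the least-squares",
                  "minimizer is not unique; returning the solution",
                  "reached from the supplied start"))
  }
  w0 <- if (is.null(init)) {
    numeric(p)
  } else if (is(init, "FilterSet")) {
    filterVector(init)
  } else {
    as.numeric(init)
  }
  if (length(w0) != p) stopInput("init has %d weights, expected %d",
                                 length(w0), p)
  fn <- function(w) as.numeric(crossprod(w, XtX %*% w)) -
    2 * sum(w * Xty) + yty
  gr <- function(w) 2 * as.vector(XtX %*% w - Xty)
  fit <- stats::optim(w0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit, pgtol = pgtol,
                                     factr = 10))
  gradNorm <- max(abs(gr(fit$par)))
  if (fit$convergence != 0L && gradNorm > 1e-5) {
    warning(sprintf("L-BFGS-B did not fully converge (code %d, |grad| %.3g): %s",
                    fit$convergence, gradNorm, fit$message))
  }
  out <- vectorToFilters(fit$par, d, mode)
  attr(out, "cost") <- fit$value
  attr(out, "convergence") <- fit$convergence
  attr(out, "gradientNorm") <- gradNorm
  out
}

## Per-family held-out metrics for one trained filter set.
heldOutMetrics <- function(pair, filters, minSeparation = 4L,
                           tertiaryWindow = 5L) {
  L <- nrow(diMatrix(pair))
  scores <- convolveMap(pair@di, filters, wcMask = pair@wcMask)
  ranked <- selectTop(scores, 2L * L, minSeparation)
  curve <- ppvCurve(ranked, pair@contacts, minSeparation = minSeparation)
  res <- data.frame(family = familyId(pair), L = L,
                    ppvTopL = curve$ppv[min(L, nrow(curve))],
                    mccAtL = mccAtRank(ranked, pair@contacts, min(L, nrow(curve)),
                                       minSeparation = minSeparation))
  if (is(pair@ss, "SecondaryStructure")) {
    mask3d <- tertiaryMask(pair@contacts, pair@ss, tertiaryWindow)
    curve3d <- ppvCurve(ranked, pair@contacts, stratumMask = mask3d,
                        minSeparation = minSeparation)
    res$ppvTopL3D <- if (nrow(curve3d) > 0L) {
      curve3d$ppv[min(L, nrow(curve3d))]
    } else {
      NA_real_
    }
  } else {
    res$ppvTopL3D <- NA_real_
  }
  res
}

#' Repeated k-fold cross-validation of filter training
#'
#' Randomly partitions the families into k balanced folds (sizes differ
#' by at most one), trains on k - 1 folds and evaluates the held-out fold,
#' and repeats the whole procedure with fresh random splits. Reported
#' metrics are averaged over families, folds and repeats with equal
#' weight. Fully reproducible from `seed`.
#'
#' @param pairs List of [TrainingPair] objects (one family each).
#' @param k Number of folds (default 5).
#' @param repeats Number of repeated random splittings (default 10).
#' @param seed Optional RNG seed.
#' @param mode,d Filter architecture passed to [trainFilters()].
#' @param minSeparation Sequence-separation exclusion band.
#' @param tertiaryWindow Exclusion window for tertiary stratification.
#' @return List with `perFamily` (one row per family x repeat with
#'   held-out top-L PPV, tertiary PPV and MCC), `summary` (their means),
#'   `assignments` (repeats x families fold labels), and `filters`
#'   (a final [FilterSet] trained on all families).
#' @export
crossValidate <- function(pairs, k = 5L, repeats = 10L, seed = NULL,
                          mode = c("single", "dual"), d = 3L,
                          minSeparation = 4L, tertiaryWindow = 5L) {
  mode <- match.arg(mode)
  n <- length(pairs)
  if (k > n) stopInput("k = %d folds but only %d families", k, n)
  if (k < 2L) stopInput("k must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  assignments <- matrix(0L, repeats, n,
                        dimnames = list(NULL, vapply(pairs, familyId, "")))
  rows <- list()
  for (r in seq_len(repeats)) {
    foldOf <- sample(rep_len(seq_len(k), n))
    assignments[r, ] <- foldOf
    for (f in seq_len(k)) {
      fs <- trainFilters(pairs[foldOf != f], mode = mode, d = d,
                         minSeparation = minSeparation)
      for (idx in which(foldOf == f)) {
        m <- heldOutMetrics(pairs[[idx]], fs, minSeparation,
                            tertiaryWindow)
        m$repeatId <- r
        m$fold <- f
        rows[[length(rows) + 1L]] <- m
      }
    }
  }
  perFamily <- do.call(rbind, rows)
  summary <- data.frame(
    ppvTopL = mean(perFamily$ppvTopL),
    ppvTopL3D = mean(perFamily$ppvTopL3D, na.rm = TRUE),
    mccAtL = mean(perFamily$mccAtL))
  list(perFamily = perFamily, summary = summary,
       assignments = assignments, k = k, repeats = repeats,
       filters = trainFilters(pairs, mode = mode, d = d,
                              minSeparation = minSeparation))
}

#' Save or load a filter set as plain text
#'
#' Format: a `mode` line, a `d` line, then for each filter a name line
#' followed by d whitespace-delimited rows.
#'
#' @param filters A [FilterSet].
#' @param path File path.
#' @return `writeFilters` returns `path` invisibly; `readFilters` a
#'   [FilterSet].
#' @export
writeFilters <- function(filters, path) {
  lines <- c(sprintf("mode %s", filters@mode),
             sprintf("d %d", filters@d))
  for (nm in names(filters@filters)) {
    lines <- c(lines, nm,
               apply(filters@filters[[nm]], 1L, paste,
                     collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeFilters
#' @export
readFilters <- function(path) {
  lines <- readLines(path, warn = FALSE)
  mode <- sub("^mode\\s+", "", lines[1L])
  d <- as.integer(sub("^d\\s+", "", lines[2L]))
  body <- lines[-(1:2)]
  want <- if (mode == "dual") c("wc", "nonwc") else "filter"
  filters <- list()
  pos <- 1L
  for (nm in want) {
    if (body[pos] != nm) stopInput("expected filter '%s' in '%s'", nm, path)
    rows <- body[pos + seq_len(d)]
    filters[[nm]] <- do.call(rbind, lapply(strsplit(rows, "\\s+"),
                                           as.numeric))
    pos <- pos + d + 1L
  }
  FilterSet(filters, mode = mode)
}

#' Read a training manifest table
#'
#' Tab-separated table with columns `family_id`, `msa_path`,
#' `structure_path`, `chain`, `ss_path` and optionally `target_id`.
#' Relative paths are resolved against the manifest's directory.
#'
#' @param path Manifest path.
#' @return `data.frame` of the manifest.
#' @export
readTrainingManifest <- function(path) {
  man <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("family_id", "msa_path", "structure_path", "chain", "ss_path")
  missing <- setdiff(need, names(man))
  if (length(missing) > 0L) {
    stopInput("manifest lacks columns: %s", paste(missing, collapse = ", "))
  }
  base <- dirname(normalizePath(path))
  for (col in c("msa_path", "structure_path", "ss_path")) {
    rel <- !grepl("^(/|[A-Za-z]:)", man[[col]])
    man[[col]][rel] <- file.path(base, man[[col]][rel])
  }
  man
}

#' Build training pairs from a manifest
#'
#' For each family: read and trim the alignment, compute the DI map,
#' derive the contact map from the structure and the secondary structure
#' from its annotation, and assemble a [TrainingPair].
#'
#' @param manifest `data.frame` from [readTrainingManifest()].
#' @param cutoff Contact cutoff in Angstrom.
#' @param ... Passed to [directInformation()].
#' @return List of [TrainingPair] objects.
#' @export
buildTrainingPairs <- function(manifest, cutoff = 10, ...) {
  lapply(seq_len(nrow(manifest)), function(r) {
    row <- manifest[r, ]
    targetId <- if ("target_id" %in% names(row)) row$target_id else NULL
    fmt <- if (grepl("\\.(sto|stk|stockholm)$", row$msa_path)) {
      "stockholm"
    } else {
      "fasta"
    }
    msa <- trimToTarget(readMsa(row$msa_path, targetId, format = fmt))
    di <- directInformation(msa, ...)
    contacts <- contactMapFromStructure(row$structure_path, row$chain,
                                        targetSequence(msa),
                                        cutoff = cutoff)
    ss <- if (grepl("\\.ct$", row$ss_path)) {
      readCtFile(row$ss_path)
    } else {
      readDotBracket(row$ss_path)
    }
    TrainingPair(di, contacts, ss = ss, familyId = row$family_id)
  })
}
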