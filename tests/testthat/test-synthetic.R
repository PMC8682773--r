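test_that("planted models respect the topology contracts", {
  model <- plantedStemModel(L = 40, nStems = 2, stemLength = 5,
                            nTertiary = 3, seed = 12)
  expect_true(validObject(model))
  planted <- rbind(model@stemPairs, model@tertiaryPairs)
  expect_true(all(planted[, 2] - planted[, 1] > 4))
  ## tertiary couplings are weaker than stem couplings
  expect_error(plantedStemModel(betaStem = 1, betaTertiary = 2), "exceed")
  ## dot-bracket matches the stem pairs
  ss <- readDotBracket(model@dotBracket)
  p <- secondaryPairs(ss)
  expect_identical(as.matrix(p[, c("i", "j")]),
                   model@stemPairs[order(model@stemPairs[, 1]), ,
                                   drop = FALSE],
                   ignore_attr = TRUE)
})

test_that("uncoupled sites sample from softmax(h) frequencies", {
  set.seed(1)
  h <- cbind(matrix(c(1, 0.5, 0, -0.5), 3, 4, byrow = TRUE), -2)
  model <- makeTinyModel(3, matrix(integer(0), 0, 2), list(), h)
  fam <- sampleMsa(model, M = 4000, seed = 2, burninSweeps = 200,
                   thinSweeps = 2)
  codes <- msaMatrix(fam$msa)[-1, ]          # target row is gap-free
  want <- exp(h[1, ]) / sum(exp(h[1, ]))
  for (i in 1:3) {
    emp <- tabulate(codes[, i], 5) / nrow(codes)
    expect_lt(max(abs(emp - want)), 0.03)
  }
})

test_that("Gibbs sampling matches exact enumeration on a tiny model", {
  ## two effective states per site (strongly suppressed fields elsewhere)
  h <- cbind(matrix(0, 4, 2), matrix(-30, 4, 3))
  J <- matrix(0, 5, 5)
  J[1, 2] <- J[2, 1] <- 1.2
  model <- makeTinyModel(4, c(1L, 3L), list(J), h)
  ex <- enumeratePotts(model)
  fam <- sampleMsa(model, M = 10000, seed = 5, burninSweeps = 400,
                   thinSweeps = 2)
  codes <- msaMatrix(fam$msa)[-1, ]
  ## empirical joint over the 2^4 surviving states
  key <- apply(codes, 1, paste, collapse = "")
  exKey <- apply(ex$states, 1, paste, collapse = "")
  emp <- table(factor(key, levels = exKey)) / nrow(codes)
  tv <- 0.5 * sum(abs(as.vector(emp) - ex$prob))
  expect_lt(tv, 0.02)

  ## exact two-site marginal of the coupled pair
  joint <- matrix(0, 5, 5)
  for (s in seq_along(ex$prob)) {
    joint[ex$states[s, 1], ex$states[s, 3]] <-
      joint[ex$states[s, 1], ex$states[s, 3]] + ex$prob[s]
  }
  empJoint <- matrix(0, 5, 5)
  for (m in seq_len(nrow(codes))) {
    empJoint[codes[m, 1], codes[m, 3]] <-
      empJoint[codes[m, 1], codes[m, 3]] + 1 / nrow(codes)
  }
  expect_lt(max(abs(joint - empJoint)), 0.02)
})

test_that("a strongly coupled stem occupies the top DI ranks", {
  model <- plantedStemModel(L = 24, nStems = 1, stemLength = 5,
                            nTertiary = 0, betaStem = 2.5, seed = 31)
  fam <- sampleMsa(model, M = 2000, seed = 32)
  di <- directInformation(fam$msa)
  top10 <- selectTop(diMatrix(di), 10)
  stemKey <- paste(model@stemPairs[, 1], model@stemPairs[, 2])
  hits <- sum(paste(top10$i, top10$j) %in% stemKey)
  expect_gte(hits, 5)
})

test_that("fixtures are deterministic given the seed", {
  model <- plantedStemModel(L = 20, nStems = 1, stemLength = 3,
                            nTertiary = 1, seed = 9)
  f1 <- sampleMsa(model, M = 50, seed = 7)
  f2 <- sampleMsa(model, M = 50, seed = 7)
  expect_identical(msaMatrix(f1$msa), msaMatrix(f2$msa))

  p1 <- tempfile(fileext = ".fasta")
  p2 <- tempfile(fileext = ".fasta")
  writeMsaFasta(f1$msa, p1)
  writeMsaFasta(f2$msa, p2)
  expect_identical(readLines(p1), readLines(p2))

  f3 <- sampleMsa(model, M = 50, seed = 8)
  expect_false(identical(msaMatrix(f1$msa), msaMatrix(f3$msa)))
})

test_that("schematic ground truth marks planted pairs and neighbourhoods", {
  model <- plantedStemModel(L = 30, nStems = 1, stemLength = 4,
                            nTertiary = 2, seed = 15)
  fam <- sampleMsa(model, M = 30, seed = 16)
  cm <- contactMatrix(fam$contacts)
  d <- distanceMatrix(fam$contacts)
  for (k in seq_len(nrow(model@stemPairs))) {
    i <- model@stemPairs[k, 1]; j <- model@stemPairs[k, 2]
    expect_equal(d[i, j], 3)
    expect_true(cm[i, j])
    expect_true(cm[i + 1, j])            # stem neighbourhood at 8 A
  }
  for (k in seq_len(nrow(model@tertiaryPairs))) {
    expect_true(cm[model@tertiaryPairs[k, 1], model@tertiaryPairs[k, 2]])
  }
  ## a long-range pair away from every planted pair is not a contact
  planted <- rbind(model@stemPairs, model@tertiaryPairs)
  isClear <- function(i, j) {
    j - i > 6 &&
      all(pmax(abs(planted[, 1] - i), abs(planted[, 2] - j)) > 1) &&
      all(pmax(abs(planted[, 2] - i), abs(planted[, 1] - j)) > 1)
  }
  clear <- NULL
  for (i in 1:29) {
    for (j in (i + 7):30) {
      if (j <= 30 && isClear(i, j)) clear <- rbind(clear, c(i, j))
    }
  }
  expect_true(all(!cm[clear]))
  expect_true(validObject(fam$contacts))
})

test_that("training suites are deterministic, valid, and span M_eff 70", {
  s1 <- makeTrainingSuite(nFamilies = 3, M = c(120, 40, 120), seed = 77)
  s2 <- makeTrainingSuite(nFamilies = 3, M = c(120, 40, 120), seed = 77)
  expect_identical(lapply(s1, diMatrix), lapply(s2, diMatrix))
  for (p in s1) {
    expect_true(validObject(p))
    expect_true(validObject(p@contacts))
    L <- nrow(diMatrix(p))
    expect_identical(dim(contactMatrix(p)), c(L, L))
    expect_identical(dim(p@wcMask), c(L, L))
  }
  meffs <- vapply(s1, function(p) effectiveSequences(p@di), 0)
  expect_gt(max(meffs), 70)     # deep families sit above the split
  expect_lte(min(meffs), 70)    # shallow ones below it
})

test_that("synthetic PDB files round-trip through the structure reader", {
  model <- plantedStemModel(L = 20, nStems = 1, stemLength = 3,
                            nTertiary = 1, seed = 41)
  fam <- sampleMsa(model, M = 20, seed = 42)
  seq <- targetSequence(fam$msa)
  planted <- rbind(model@stemPairs, model@tertiaryPairs)
  path <- tempfile(fileext = ".pdb")
  writeSyntheticPdb(seq, planted, path)
  cm <- contactMapFromStructure(path, "A", seq, cutoff = 10)
  for (k in seq_len(nrow(planted))) {
    expect_equal(distanceMatrix(cm)[planted[k, 1], planted[k, 2]], 3,
                 tolerance = 1e-5)
  }
  expect_true(contactMatrix(cm)[4, 5])     # chain neighbours at 6 A
  expect_false(contactMatrix(cm)[2, 10])   # unplanted long-range pair
})
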