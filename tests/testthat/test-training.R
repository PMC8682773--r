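## Small synthetic training pairs with binary labels.
toyTrainingPair <- function(L, seed, id = "toy") {
  set.seed(seed)
  di <- randomDiMap(L, seed)
  dist <- matrix(20, L, L)
  ij <- which(upper.tri(dist) & abs(row(dist) - col(dist)) > 4,
              arr.ind = TRUE)
  hit <- ij[sample(nrow(ij), max(3, L %/% 3)), , drop = FALSE]
  dist[hit] <- 3
  dist[hit[, 2:1]] <- 3
  diag(dist) <- 0
  seq <- sample(c("A", "C", "G", "U"), L, replace = TRUE)
  TrainingPair(DIMap(di, targetSeq = seq), ContactMap(dist),
               familyId = id)
}

test_that("the cost counts squared residuals over the separation band", {
  L <- 14
  zero <- FilterSet(matrix(0, 3, 3))
  noContacts <- TrainingPair(
    DIMap(randomDiMap(L, 1), targetSeq = rep("A", L)),
    ContactMap(matrix(20, L, L) - diag(20, L)), familyId = "empty")
  expect_equal(filterCost(zero, list(noContacts)), 0)

  pair <- toyTrainingPair(L, seed = 2)
  cm <- contactMatrix(pair)
  inBand <- sum(cm[upper.tri(cm) & col(cm) - row(cm) > 4])
  expect_equal(filterCost(zero, list(pair)), inBand)
})

test_that("cost and gradient match nested-loop and finite-difference oracles", {
  p1 <- toyTrainingPair(12, seed = 5, id = "a")
  p2 <- toyTrainingPair(15, seed = 6, id = "b")
  set.seed(7)
  w <- matrix(rnorm(9), 3, 3)
  fs <- FilterSet(w)
  got <- filterCost(fs, list(p1, p2))
  want <- oracleCost(w, list(diMatrix(p1), diMatrix(p2)),
                     list(contactMatrix(p1), contactMatrix(p2)))
  expect_equal(got, want, tolerance = 1e-10)

  g <- filterCostGradient(fs, list(p1, p2))
  fd <- numeric(9)
  eps <- 1e-6
  for (k in 1:9) {
    wp <- w; wp[k] <- wp[k] + eps
    wm <- w; wm[k] <- wm[k] - eps
    fd[k] <- (filterCost(FilterSet(wp), list(p1, p2)) -
                filterCost(FilterSet(wm), list(p1, p2))) / (2 * eps)
  }
  expect_lt(max(abs(g - fd)), 1e-5)
})

test_that("dual-mode cost equals the masked single-mode decomposition", {
  pair <- toyTrainingPair(12, seed = 9)
  set.seed(10)
  wWc <- matrix(rnorm(9), 3, 3)
  dual <- FilterSet(list(wc = wWc, nonwc = wWc))
  single <- FilterSet(wWc)
  expect_equal(filterCost(dual, list(pair)),
               filterCost(single, list(pair)), tolerance = 1e-10)
})

test_that("training recovers a planted filter from noise-free labels", {
  set.seed(21)
  wTrue <- matrix(rnorm(9), 3, 3)
  pairs <- lapply(1:3, function(k) {
    di <- randomDiMap(16, seed = 50 + k)
    labels <- convolveMap(di, FilterSet(wTrue), symmetrize = FALSE)
    list(di = di, labels = labels)
  })
  fit <- trainFilters(pairs, mode = "single", d = 3)
  expect_lt(max(abs(fit@filters$filter - wTrue)), 1e-6)
  expect_lt(attr(fit, "cost"), 1e-10)
})

test_that("the convex objective makes the optimum init-independent", {
  pairs <- lapply(1:2, function(k) toyTrainingPair(14, seed = 30 + k,
                                                   id = letters[k]))
  set.seed(31)
  f1 <- trainFilters(pairs, d = 3, init = rnorm(9))
  f2 <- trainFilters(pairs, d = 3, init = rnorm(9))
  expect_equal(attr(f1, "cost"), attr(f2, "cost"), tolerance = 1e-8)
  expect_equal(f1@filters$filter, f2@filters$filter, tolerance = 1e-5)

  zero <- FilterSet(matrix(0, 3, 3))
  expect_lte(attr(f1, "cost"), filterCost(zero, pairs))
})

test_that("duplicating every training pair leaves the minimizer unchanged", {
  pairs <- lapply(1:2, function(k) toyTrainingPair(13, seed = 40 + k,
                                                   id = letters[k]))
  f1 <- trainFilters(pairs, d = 3)
  f2 <- trainFilters(c(pairs, pairs), d = 3)
  expect_equal(f1@filters$filter, f2@filters$filter, tolerance = 1e-6)
  expect_equal(attr(f2, "cost"), 2 * attr(f1, "cost"), tolerance = 1e-6)
})

test_that("an underdetermined design triggers a rank warning", {
  pair <- toyTrainingPair(12, seed = 55)    # 28 band pairs < 49 params
  w <- capture_warnings(trainFilters(list(pair), d = 7))
  expect_true(any(grepl("rank-deficient", w)))
  expect_true(any(grepl("in-band pairs", w)))
})

test_that("filter sets round-trip through the text format", {
  set.seed(60)
  single <- FilterSet(matrix(rnorm(25), 5, 5))
  path <- tempfile(fileext = ".txt")
  writeFilters(single, path)
  back <- readFilters(path)
  expect_identical(back@mode, "single")
  expect_equal(back@filters$filter, single@filters$filter,
               tolerance = 1e-12)

  dual <- FilterSet(list(wc = matrix(rnorm(9), 3, 3),
                         nonwc = matrix(rnorm(9), 3, 3)))
  writeFilters(dual, path)
  back2 <- readFilters(path)
  expect_identical(back2@mode, "dual")
  expect_equal(back2@filters$nonwc, dual@filters$nonwc,
               tolerance = 1e-12)
})

test_that("cross-validation partitions, balances and reproduces", {
  pairs <- lapply(1:7, function(k) toyTrainingPair(14, seed = 70 + k,
                                                   id = sprintf("f%d", k)))
  cv <- crossValidate(pairs, k = 7, repeats = 2, seed = 99, d = 3)
  ## leave-one-out: every family held out exactly once per repeat
  for (r in 1:2) {
    expect_identical(sort(unname(cv$assignments[r, ])), 1:7)
  }
  expect_identical(nrow(cv$perFamily), 14L)
  expect_identical(sort(table(cv$perFamily$family)),
                   sort(table(rep(sprintf("f%d", 1:7), 2))))

  cv2 <- crossValidate(pairs, k = 7, repeats = 2, seed = 99, d = 3)
  expect_identical(cv$assignments, cv2$assignments)
  expect_equal(cv$perFamily$ppvTopL, cv2$perFamily$ppvTopL)

  expect_error(crossValidate(pairs, k = 9, repeats = 1), "families")
})

test_that("random fold splits stay balanced for awkward sizes", {
  pairs <- lapply(1:57, function(k) toyTrainingPair(12, seed = 200 + k,
                                                    id = sprintf("g%02d", k)))
  cv <- crossValidate(pairs, k = 5, repeats = 1, seed = 3, d = 3)
  sizes <- sort(as.vector(table(cv$assignments[1, ])), decreasing = TRUE)
  expect_identical(sizes, c(12L, 12L, 11L, 11L, 11L))
})
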