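test_that("sequence weights handle the degenerate similarity regimes", {
  same <- RnaMsa(matrix(rep(c(1L, 2L, 3L, 4L), each = 6), 6, 4))
  w <- computeWeights(same, 0.8)
  expect_equal(w@omega, rep(1 / 6, 6))
  expect_equal(effectiveSequences(w), 1)

  distinct <- RnaMsa(rbind(rep(1L, 8), rep(2L, 8), rep(3L, 8)))
  w2 <- computeWeights(distinct, 0.8)
  expect_equal(w2@omega, rep(1, 3))
  expect_equal(effectiveSequences(w2), 3)

  expect_error(computeWeights(same, 0), "threshold")
  expect_error(computeWeights(same, 1.2), "threshold")
})

test_that("weights match the all-pairs Hamming-identity brute force", {
  codes <- randomMsaCodes(4, 10, 1:5, seed = 31)
  codes[2, ] <- codes[1, ]
  codes[2, 1] <- (codes[1, 1] %% 5L) + 1L   # 90% identical to row 1
  msa <- RnaMsa(codes)
  for (thr in c(0.5, 0.8, 0.95)) {
    expect_equal(computeWeights(msa, thr)@omega,
                 oracleWeights(codes, thr))
  }
})

test_that("frequencies follow the pseudocounted reweighted form", {
  one <- RnaMsa(matrix(c(1L, 3L, 5L), 1, 3))
  w <- computeWeights(one, 0.8)
  fr <- computeFrequencies(one, w, lambda = 0)
  expect_equal(fr@f1[1, ], c(1, 0, 0, 0, 0))      # indicator at lambda = 0
  expect_equal(fr@f1[2, ], c(0, 0, 1, 0, 0))
  expect_equal(fr@f1[3, ], c(0, 0, 0, 0, 1))

  big <- computeFrequencies(one, w, lambda = 1e9)  # pseudocount dominates
  expect_equal(max(abs(big@f1 - 1 / 5)), 0, tolerance = 1e-8)
  expect_equal(max(abs(big@f2 - 1 / 25)), 0, tolerance = 1e-8)
})

test_that("frequencies equal the direct-summation oracle on a toy MSA", {
  codes <- rbind(c(1L, 2L, 3L), c(1L, 5L, 3L), c(4L, 2L, 2L))
  msa <- RnaMsa(codes)
  w <- computeWeights(msa, 0.6)
  fr <- computeFrequencies(msa, w, lambda = 1)
  or <- oracleFrequencies(codes, w@omega, lambda = 1)
  expect_equal(fr@f1, or$f1)
  q <- rnaStates()
  for (i in 1:3) {
    for (j in 1:3) {
      if (i == j) next
      block <- fr@f2[(i - 1) * q + 1:q, (j - 1) * q + 1:q]
      expect_equal(block, or$f2[i, j, , ])
    }
  }
})

test_that("pair-frequency marginals are consistent with f1", {
  codes <- randomMsaCodes(8, 6, 1:5, seed = 5)
  msa <- RnaMsa(codes)
  w <- computeWeights(msa, 0.8)
  fr <- computeFrequencies(msa, w, lambda = 2.5)
  q <- rnaStates()
  for (i in 1:5) {
    for (j in (i + 1):6) {
      block <- fr@f2[(i - 1) * q + 1:q, (j - 1) * q + 1:q]
      expect_equal(sum(block), 1, tolerance = 1e-12)
      expect_equal(rowSums(block), fr@f1[i, ], tolerance = 1e-12)
      expect_equal(colSums(block), fr@f1[j, ], tolerance = 1e-12)
    }
  }
  expect_equal(rowSums(fr@f1), rep(1, 6), tolerance = 1e-12)
})

test_that("couplings solve -C J = I and satisfy block symmetry", {
  codes <- randomMsaCodes(12, 5, 1:5, seed = 8)
  msa <- RnaMsa(codes)
  fr <- computeFrequencies(msa, computeWeights(msa, 0.8), lambda = 3)
  cm <- computeCouplings(fr)
  expect_equal(cm@corr, t(cm@corr), tolerance = 1e-10)
  p <- nrow(cm@corr)
  expect_equal(cm@corr %*% cm@couplings, -diag(p), tolerance = 1e-8)
  ## J_ij(a, b) = J_ji(b, a)
  qr <- cm@qReduced
  J12 <- cm@couplings[1:qr, qr + 1:qr]
  J21 <- cm@couplings[qr + 1:qr, 1:qr]
  expect_equal(J12, t(J21), tolerance = 1e-10)
})

test_that("independent sites yield near-zero couplings", {
  codes <- randomMsaCodes(6000, 2, 1:5, seed = 77)
  msa <- RnaMsa(codes)
  w <- computeWeights(msa, 0.8)
  fr <- computeFrequencies(msa, w, lambda = 0.5 * w@meff)
  cm <- computeCouplings(fr)
  qr <- cm@qReduced
  offdiag <- cm@couplings[1:qr, qr + 1:qr]
  expect_lt(max(abs(cm@corr[1:qr, qr + 1:qr])), 1e-10)
  expect_lt(max(abs(offdiag)), 1e-8)
})

test_that("zero couplings give an independent direct probability", {
  fi <- c(0.4, 0.3, 0.1, 0.1, 0.1)
  fj <- c(0.2, 0.2, 0.2, 0.2, 0.2)
  fit <- fitTwoSiteFields(matrix(0, 5, 5), fi, fj, tol = 1e-10)
  expect_equal(fit$pdir, tcrossprod(fi, fj), tolerance = 1e-9)
})

test_that("symmetric couplings with equal marginals give a symmetric fit", {
  set.seed(3)
  J <- matrix(rnorm(25), 5, 5)
  J <- (J + t(J)) / 2
  u <- rep(0.2, 5)
  fit <- fitTwoSiteFields(J, u, u, tol = 1e-10)
  expect_equal(fit$pdir, t(fit$pdir), tolerance = 1e-8)
})

test_that("field fitting matches direct constrained optimization", {
  set.seed(14)
  for (k in 1:4) {
    J <- matrix(rnorm(25, sd = 0.8), 5, 5)
    fi <- as.vector(stats::rgamma(5, 2)); fi <- fi / sum(fi)
    fj <- as.vector(stats::rgamma(5, 2)); fj <- fj / sum(fj)
    fit <- fitTwoSiteFields(J, fi, fj, tol = 1e-10, maxIter = 5000)
    expect_lt(fit$residual, 1e-10)
    expect_equal(fit$pdir, oracleFitPair(J, fi, fj), tolerance = 1e-7)
  }
})

test_that("DI maps are symmetric, nonnegative and near zero for iid data", {
  codes <- randomMsaCodes(2000, 8, 1:4, seed = 21)
  di <- directInformation(RnaMsa(codes, columnMap = 1:8))
  m <- diMatrix(di)
  expect_equal(m, t(m))
  expect_true(all(m >= 0))
  expect_lt(max(m[upper.tri(m)]), 0.01)   # no coevolution signal planted
})

test_that("a planted covarying pair dominates the DI ranking", {
  model <- plantedStemModel(L = 18, nStems = 1, stemLength = 1,
                            nTertiary = 0, betaStem = 3, seed = 2)
  fam <- sampleMsa(model, M = 800, seed = 3)
  di <- directInformation(fam$msa)
  top <- selectTop(diMatrix(di), 1, minSeparation = 4)
  expect_identical(c(top$i, top$j), as.vector(model@stemPairs[1, ]))
})

test_that("DI is invariant under row permutation and k-fold duplication", {
  model <- plantedStemModel(L = 16, nStems = 1, stemLength = 2,
                            nTertiary = 0, seed = 5)
  fam <- sampleMsa(model, M = 60, seed = 6)
  codes <- msaMatrix(fam$msa)
  di0 <- diMatrix(directInformation(RnaMsa(codes, columnMap = 1:16)))

  set.seed(10)
  perm <- sample(nrow(codes))
  diP <- diMatrix(directInformation(RnaMsa(codes[perm, ],
                                           columnMap = 1:16)))
  expect_equal(diP, di0, tolerance = 1e-10)

  dup <- codes[rep(seq_len(nrow(codes)), 3), ]
  diD <- diMatrix(directInformation(RnaMsa(dup, columnMap = 1:16)))
  expect_equal(diD, di0, tolerance = 1e-10)
})

test_that("DI TSV writer emits the upper triangle in order", {
  m <- randomDiMap(5, seed = 4)
  di <- DIMap(m, targetSeq = c("A", "C", "G", "U", "A"))
  path <- tempfile(fileext = ".tsv")
  writeDiTsv(di, path)
  tab <- read.delim(path)
  expect_identical(nrow(tab), 10L)
  expect_true(all(tab$i < tab$j))
  expect_equal(tab$score, m[cbind(tab$i, tab$j)])
})
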