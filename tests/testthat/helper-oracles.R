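## Independent brute-force oracles: written as plain nested loops and
## generic optimizers, deliberately sharing no code path with the package.

Q <- 5L

## --- mean-field DCA, loop-and-dense-solver route -----------------------

oracleWeights <- function(codes, threshold) {
  M <- nrow(codes)
  L <- ncol(codes)
  omega <- numeric(M)
  for (m in seq_len(M)) {
    nsim <- 0L
    for (mm in seq_len(M)) {
      if (mean(codes[m, ] == codes[mm, ]) >= threshold) nsim <- nsim + 1L
    }
    omega[m] <- 1 / nsim
  }
  omega
}

oracleFrequencies <- function(codes, omega, lambda) {
  M <- nrow(codes)
  L <- ncol(codes)
  meff <- sum(omega)
  f1 <- matrix(0, L, Q)
  for (i in seq_len(L)) {
    for (a in seq_len(Q)) {
      cnt <- 0
      for (m in seq_len(M)) if (codes[m, i] == a) cnt <- cnt + omega[m]
      f1[i, a] <- (lambda / Q + cnt) / (meff + lambda)
    }
  }
  f2 <- array(0, c(L, L, Q, Q))
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      for (a in seq_len(Q)) {
        for (b in seq_len(Q)) {
          cnt <- 0
          for (m in seq_len(M)) {
            if (codes[m, i] == a && codes[m, j] == b) cnt <- cnt + omega[m]
          }
          f2[i, j, a, b] <- (lambda / Q^2 + cnt) / (meff + lambda)
        }
      }
    }
  }
  list(f1 = f1, f2 = f2, meff = meff)
}

## Fields of the two-site model by direct convex optimization of the dual
## (log-partition minus linear term); gradient = marginal mismatch.
oracleFitPair <- function(J, fi, fj) {
  q <- length(fi)
  obj <- function(h) {
    E <- J + outer(h[1:q], h[q + 1:q], "+")
    mx <- max(E)
    log(sum(exp(E - mx))) + mx - sum(fi * h[1:q]) - sum(fj * h[q + 1:q])
  }
  grad <- function(h) {
    E <- J + outer(h[1:q], h[q + 1:q], "+")
    p <- exp(E - max(E))
    p <- p / sum(p)
    c(rowSums(p) - fi, colSums(p) - fj)
  }
  fit <- stats::optim(rep(0, 2 * q), obj, grad, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-16))
  h <- fit$par
  ## a few Newton-free polish sweeps to drive the marginals down hard
  for (k in 1:200) {
    E <- J + outer(h[1:q], h[q + 1:q], "+")
    p <- exp(E - max(E))
    p <- p / sum(p)
    h[1:q] <- h[1:q] + log(fi / rowSums(p))
    h[q + 1:q] <- h[q + 1:q] + log(fj / colSums(p))
  }
  E <- J + outer(h[1:q], h[q + 1:q], "+")
  p <- exp(E - max(E))
  p / sum(p)
}

## Full DI pipeline: frequencies by counting loops, C by explicit block
## loops, dense solve, per-pair dual-optimization field fit, Eq.-by-Eq.
oracleDi <- function(codes, threshold = 0.8, lambda = NULL) {
  L <- ncol(codes)
  omega <- oracleWeights(codes, threshold)
  if (is.null(lambda)) lambda <- 0.5 * sum(omega)
  fr <- oracleFrequencies(codes, omega, lambda)
  qr <- Q - 1L
  C <- matrix(0, L * qr, L * qr)
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      for (a in seq_len(qr)) {
        for (b in seq_len(qr)) {
          val <- if (i == j) {
            (a == b) * fr$f1[i, a] - fr$f1[i, a] * fr$f1[i, b]
          } else {
            fr$f2[i, j, a, b] - fr$f1[i, a] * fr$f1[j, b]
          }
          C[(i - 1) * qr + a, (j - 1) * qr + b] <- val
        }
      }
    }
  }
  Jred <- -solve(C)
  di <- matrix(0, L, L)
  for (i in seq_len(L - 1)) {
    for (j in (i + 1):L) {
      J <- matrix(0, Q, Q)
      J[1:qr, 1:qr] <- Jred[(i - 1) * qr + 1:qr, (j - 1) * qr + 1:qr]
      p <- oracleFitPair(J, fr$f1[i, ], fr$f1[j, ])
      v <- 0
      for (a in seq_len(Q)) {
        for (b in seq_len(Q)) {
          v <- v + p[a, b] * log(p[a, b] / (fr$f1[i, a] * fr$f1[j, b]))
        }
      }
      di[i, j] <- di[j, i] <- v
    }
  }
  di
}

## --- convolution / cost loop oracles -----------------------------------

oraclePad <- function(m, d) {
  p <- (d - 1) / 2
  L <- nrow(m)
  out <- matrix(0, L + 2 * p, L + 2 * p)
  out[p + 1:L, p + 1:L] <- m
  out
}

oracleCrossCorrelate <- function(m, w) {
  d <- nrow(w)
  L <- nrow(m)
  P <- oraclePad(m, d)
  out <- matrix(0, L, L)
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      acc <- 0
      for (u in seq_len(d)) {
        for (v in seq_len(d)) {
          acc <- acc + w[u, v] * P[i + u - 1, j + v - 1]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

## Single-mode training cost by direct summation over j > i + sep.
oracleCost <- function(w, dis, labels, minSep = 4) {
  total <- 0
  for (k in seq_along(dis)) {
    conv <- oracleCrossCorrelate(dis[[k]], w)
    L <- nrow(conv)
    for (i in seq_len(L)) {
      for (j in seq_len(L)) {
        if (j > i + minSep && !is.na(labels[[k]][i, j])) {
          total <- total + (conv[i, j] - labels[[k]][i, j])^2
        }
      }
    }
  }
  total
}

## --- misc fixture builders ---------------------------------------------

randomDiMap <- function(L, seed) {
  set.seed(seed)
  m <- matrix(stats::runif(L * L), L, L)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

randomMsaCodes <- function(M, L, states, seed) {
  set.seed(seed)
  matrix(sample(states, M * L, replace = TRUE), M, L)
}

## Tiny custom Potts model without the planted-stem layout.
makeTinyModel <- function(L, edges, couplings, h) {
  new("PlantedPottsModel", L = as.integer(L), h = h,
      edges = matrix(as.integer(edges), ncol = 2),
      couplings = couplings,
      stemPairs = matrix(integer(0), 0, 2),
      tertiaryPairs = matrix(integer(0), 0, 2),
      dotBracket = paste(rep(".", L), collapse = ""))
}

## Hand-rolled PDB writer for structure-reader tests.
pdbAtomLine <- function(serial, name, resid, chain, resno, x, y, z, elem,
                        occ = 1) {
  sprintf("ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, resid, chain, resno, x, y, z, occ, 0, elem)
}

writeTestPdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}
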