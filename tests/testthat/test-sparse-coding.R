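# Vocabulary construction, feature transforms and the l1-regularized
# least-squares solver.

test_that("normalizeColumns produces unit columns and restorable scales", {
  out <- normalizeColumns(cbind(c(3, 4)))
  expect_equal(out$matrix[, 1], c(0.6, 0.8))
  expect_equal(out$scales, 5)

  out <- normalizeColumns(diag(3))
  expect_equal(out$matrix, diag(3))
  expect_equal(out$scales, rep(1, 3))

  x <- withSeed(1, matrix(rnorm(60), 10, 6))
  out <- normalizeColumns(x)
  expect_true(all(abs(sqrt(colSums(out$matrix^2)) - 1) < 1e-12))
  expect_equal(out$matrix %*% diag(out$scales), x)

  x[, 3] <- 0
  expect_error(normalizeColumns(x), "index 3")
})

test_that("feature transforms match explicit matrix products", {
  expect_equal(applyTransform(identityTransform(3), c(1, 2, 3)), c(1, 2, 3))
  expect_equal(applyTransform(downsampleTransform(4, 2), c(1, 1, 3, 3)),
               c(1, 3))

  tr <- randomProjectionTransform(4, 16, seed = 7)
  x <- sin(seq_len(16))
  expect_equal(applyTransform(tr, x), as.numeric(tr@matrix %*% x))
  expect_equal(qr(tr@matrix)$rank, 4)

  # row-major 2x2 block means of a 4x4 patch
  patch <- matrix(1:16, 4, 4, byrow = TRUE)
  v <- as.vector(t(patch))
  got <- applyTransform(patchDownsampleTransform(4, 2), v)
  expected <- c(mean(patch[1:2, 1:2]), mean(patch[1:2, 3:4]),
                mean(patch[3:4, 1:2]), mean(patch[3:4, 3:4]))
  expect_equal(got, expected)

  expect_error(applyTransform(downsampleTransform(4, 2), c(1, 2, 3)),
               "length")
  expect_error(downsampleTransform(5, 2), "divide")
})

test_that("centering and composite transforms remove the feature mean", {
  tr <- patchFeatureTransform(6, 2)
  expect_identical(tr@kind, "composite")
  v <- withSeed(3, rnorm(36))
  f <- applyTransform(tr, v)
  expect_equal(mean(f), 0, tolerance = 1e-12)
  # composition order: downsample first, then centering
  ds <- applyTransform(patchDownsampleTransform(6, 2), v)
  expect_equal(f, ds - mean(ds))
})

test_that("solver reproduces the orthonormal closed form", {
  vocab <- Vocabulary(diag(2), c(1, -1))
  code <- solveL1LS(vocab, c(1, 0), solverSettings(lambda = 0.2))
  expect_equal(codeCoefficients(code), c(0.9, 0), tolerance = 1e-10)
  expect_true(code@converged)

  # lambda >= 2 max|A'y| forces the exact zero solution
  code0 <- solveL1LS(vocab, c(0.3, -0.2), solverSettings(lambda = 1))
  expect_identical(codeCoefficients(code0), c(0, 0))
  # just below the threshold the solution is nonzero
  codeEps <- solveL1LS(vocab, c(0.3, -0.2), solverSettings(lambda = 0.55))
  expect_gt(sum(abs(codeCoefficients(codeEps))), 0)

  # general orthonormal dictionary: soft threshold of A'y at lambda/2
  Q <- withSeed(9, qr.Q(qr(matrix(rnorm(25), 5))))
  vocabQ <- Vocabulary(Q, c(1, 1, 1, -1, -1))
  y <- withSeed(10, rnorm(5)); y <- y / sqrt(sum(y^2))
  lam <- 0.3
  codeQ <- solveL1LS(vocabQ, y, solverSettings(lambda = lam, gapTol = 1e-12,
                                               maxIter = 2000))
  aty <- as.numeric(crossprod(Q, y))
  soft <- sign(aty) * pmax(abs(aty) - lam / 2, 0)
  expect_equal(codeCoefficients(codeQ), soft, tolerance = 1e-9)
})

test_that("solver objective matches the split-QP oracle on random instances", {
  worst <- 0
  for (s in 1:50) {
    inst <- withSeed(1000 + s, {
      d <- sample(2:10, 1); n <- sample(3:20, 1)
      A <- matrix(rnorm(d * n), d, n)
      list(A = sweep(A, 2, sqrt(colSums(A^2)), "/"),
           y = {y <- rnorm(d); y / sqrt(sum(y^2))},
           lam = 10^runif(1, -3, -0.5),
           labels = c(1, rep(-1, n - 1)))
    })
    vocab <- Vocabulary(inst$A, inst$labels)
    fit <- solveL1LS(vocab, inst$y,
                     solverSettings(lambda = inst$lam, gapTol = 1e-10,
                                    maxIter = 10000))
    oracle <- lassoSplitOracle(inst$A, inst$y, inst$lam)
    worst <- max(worst, abs(fit@objective - oracle$objective))
  }
  expect_lt(worst, 1e-6)
})

test_that("solver output carries a valid optimality certificate", {
  for (s in 1:10) {
    inst <- withSeed(2000 + s, {
      A <- matrix(rnorm(8 * 12), 8, 12)
      list(A = sweep(A, 2, sqrt(colSums(A^2)), "/"),
           y = {y <- rnorm(8); y / sqrt(sum(y^2))})
    })
    lam <- 0.05
    vocab <- Vocabulary(inst$A, rep(c(1, -1), 6))
    fit <- solveL1LS(vocab, inst$y,
                     solverSettings(lambda = lam, gapTol = 1e-10,
                                    maxIter = 10000))
    cc <- codeCoefficients(fit)
    g <- 2 * as.numeric(crossprod(inst$A, inst$A %*% cc - inst$y))
    tol <- 1e-6
    # subgradient condition: |g_j| <= lambda on zeros, g_j = -lambda sign(c_j)
    expect_lte(max(abs(g[cc == 0])), lam + tol)
    if (any(cc != 0))
      expect_lt(max(abs(g[cc != 0] + lam * sign(cc[cc != 0]))), tol)
    # gap certificate within the configured tolerance
    expect_lte(fit@dualityGap, 1e-10 * (1 + abs(fit@objective)))
    # stored objective agrees with the pure recomputation
    expect_equal(fit@objective, l1Objective(vocab, inst$y, cc, lam),
                 tolerance = 1e-8)
  }
})

test_that("code l1 norm is non-increasing in lambda", {
  inst <- withSeed(77, {
    A <- matrix(rnorm(10 * 15), 10, 15)
    list(A = sweep(A, 2, sqrt(colSums(A^2)), "/"),
         y = {y <- rnorm(10); y / sqrt(sum(y^2))})
  })
  vocab <- Vocabulary(inst$A, rep(c(1, -1), length.out = 15))
  norms <- vapply(10^seq(-4, 0.5, length.out = 12), function(lam) {
    sum(abs(codeCoefficients(
      solveL1LS(vocab, inst$y, solverSettings(lambda = lam, gapTol = 1e-10,
                                              maxIter = 10000)))))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-8))
})

test_that("lambda -> 0 with invertible square A recovers A^{-1} y", {
  A <- withSeed(5, matrix(rnorm(16), 4, 4))
  An <- sweep(A, 2, sqrt(colSums(A^2)), "/")
  y <- withSeed(6, rnorm(4)); y <- y / sqrt(sum(y^2))
  vocab <- Vocabulary(An, c(1, 1, -1, -1))
  fit <- solveL1LS(vocab, y, solverSettings(lambda = 1e-8, gapTol = 1e-12,
                                            maxIter = 50000))
  expect_equal(codeCoefficients(fit), as.numeric(solve(An, y)),
               tolerance = 1e-4)
})

test_that("l1Objective is a pure function with the documented form", {
  vocab <- Vocabulary(diag(2), c(1, -1))
  y <- c(0.6, 0.8)
  expect_equal(l1Objective(vocab, y, c(0, 0), 0.3), sum(y^2))
  expect_equal(l1Objective(vocab, c(1, 0), c(1, 0), 0.5), 0.5)
  expect_error(l1Objective(vocab, c(1, 0, 0), c(1, 0), 0.5), "length")
  # solver output minimizes: any perturbation cannot do better
  fit <- solveL1LS(vocab, y, solverSettings(lambda = 0.3))
  base <- fit@objective
  for (s in 1:20) {
    pert <- codeCoefficients(fit) + withSeed(s, rnorm(2, sd = 0.1))
    expect_gte(l1Objective(vocab, y, pert, 0.3), base - 1e-12)
  }
})

test_that("solver flags non-convergence and rejects bad input", {
  inst <- withSeed(8, {
    A <- matrix(rnorm(20 * 40), 20, 40)
    list(A = sweep(A, 2, sqrt(colSums(A^2)), "/"),
         y = {y <- rnorm(20); y / sqrt(sum(y^2))})
  })
  vocab <- Vocabulary(inst$A, rep(c(1, -1), 20))
  fit <- solveL1LS(vocab, inst$y,
                   solverSettings(lambda = 1e-4, gapTol = 1e-14, maxIter = 2))
  expect_false(fit@converged)

  expect_error(solveL1LS(vocab, c(inst$y[-1], NaN), solverSettings()),
               "NaN")
  raw <- Vocabulary(inst$A, rep(c(1, -1), 20), normalize = FALSE)
  expect_error(solveL1LS(raw, inst$y, solverSettings()), "normalized")
})
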