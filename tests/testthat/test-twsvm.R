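# Twin SVM: augmented matrices, dual box QPs, primal recovery, prediction,
# KKT certificates, symmetries.

toyProblem <- function(c1 = 1, c2 = 1)
  twsvmProblem(rbind(c(-1, 0), c(-1, 1)), rbind(c(1, 0), c(1, 1)),
               c1 = c1, c2 = c2, kernel = linearKernel(), ridge = 1e-6)

test_that("augmented matrices append a ones column", {
  p <- twsvmProblem(rbind(c(1, 2)), rbind(c(0, 0), c(1, 1)),
                    kernel = linearKernel())
  aug <- buildAugmented(p)
  expect_equal(aug$H, cbind(rbind(c(1, 2)), 1))
  expect_equal(aug$G, cbind(rbind(c(0, 0), c(1, 1)), 1))
  expect_equal(ncol(aug$H), ncol(p@A) + 1)
})

test_that("degenerate zero quadratic term drives multipliers to the box", {
  H <- cbind(rbind(c(-1, 0), c(-1, 1)), 1)
  G0 <- matrix(0, 3, 3)
  a <- solveDTWSVM1(H, G0, c1 = 2.5)
  expect_equal(as.numeric(a$alpha), rep(2.5, 3))
  g <- solveDTWSVM2(matrix(0, 3, 3), cbind(rbind(c(1, 0)), 1), c2 = 1.5)
  expect_equal(as.numeric(g$gamma), rep(1.5, 3))
})

test_that("toy duals match the generic box-QP oracle", {
  p <- toyProblem()
  aug <- buildAugmented(p)
  a <- solveDTWSVM1(aug$H, aug$G, p@c1, p@ridge)
  Q1 <- dualQ(aug$H, aug$G, p@ridge)
  o1 <- boxQpOracle(Q1, rep(1, nrow(aug$G)), p@c1)
  expect_lt(max(abs(as.numeric(a$alpha) - o1$alpha)), 1e-5)

  g <- solveDTWSVM2(aug$H, aug$G, p@c2, p@ridge)
  Q2 <- dualQ(aug$G, aug$H, p@ridge)
  o2 <- boxQpOracle(Q2, rep(1, nrow(aug$H)), p@c2)
  expect_lt(max(abs(as.numeric(g$gamma) - o2$alpha)), 1e-5)

  # plane 1 hugs the class +1 points
  model <- trainTWSVM(p)
  w1 <- model@u[1:2]; b1 <- model@u[3]
  expect_lt(max(abs(p@A %*% w1 + b1)), 0.05)
})

test_that("dual objective is invariant under orthogonal rotation", {
  p <- randomTWSVMProblem(31)
  theta <- 0.7
  d <- ncol(p@A)
  R <- diag(d)
  R[1:2, 1:2] <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  pR <- twsvmProblem(p@A %*% R, p@B %*% R, p@c1, p@c2, linearKernel(),
                     p@ridge)
  a1 <- solveDTWSVM1(buildAugmented(p)$H, buildAugmented(p)$G, p@c1, p@ridge)
  a2 <- solveDTWSVM1(buildAugmented(pR)$H, buildAugmented(pR)$G, p@c1,
                     p@ridge)
  expect_equal(a1$objective, a2$objective, tolerance = 1e-7)
})

test_that("swapping classes maps one dual problem into the other", {
  p <- randomTWSVMProblem(17)
  ps <- twsvmProblem(p@B, p@A, c1 = p@c2, c2 = p@c1, linearKernel(), p@ridge)
  m <- trainTWSVM(p)
  ms <- trainTWSVM(ps)
  # same planes, orientation flipped by the swapped margin constraints
  expect_lt(max(abs(ms@u + m@v)), 1e-6)
  expect_lt(max(abs(ms@v + m@u)), 1e-6)
})

test_that("primal recovery satisfies its defining linear systems", {
  p <- toyProblem()
  aug <- buildAugmented(p)
  # alpha = 0 gives the zero plane
  pr0 <- recoverPrimal(aug$H, aug$G, rep(0, 2), rep(0, 2), p@ridge)
  expect_equal(pr0$u, rep(0, 3))

  alpha <- withSeed(12, runif(2)); gamma <- withSeed(13, runif(2))
  pr <- recoverPrimal(aug$H, aug$G, alpha, gamma, p@ridge)
  M <- crossprod(aug$H); eps1 <- p@ridge * mean(diag(M))
  expect_lt(max(abs((M + diag(eps1, 3)) %*% pr$u +
                      crossprod(aug$G, alpha))), 1e-8)
  N <- crossprod(aug$G); eps2 <- p@ridge * mean(diag(N))
  expect_lt(max(abs((N + diag(eps2, 3)) %*% pr$v -
                      crossprod(aug$H, gamma))), 1e-8)
})

test_that("mirror-symmetric data yields mirror-image planes", {
  p <- randomTWSVMProblem(23)
  pm <- twsvmProblem(-p@B, -p@A, c1 = p@c2, c2 = p@c1, linearKernel(),
                     p@ridge)
  m <- trainTWSVM(p)
  mm <- trainTWSVM(pm)
  d <- ncol(p@A)
  # plane 1 of the mirrored problem is plane 2 of the original, reflected
  # through the origin (same weights, negated offset)
  expect_lt(max(abs(mm@u - c(m@v[1:d], -m@v[d + 1]))), 1e-6)
  expect_lt(max(abs(mm@v - c(m@u[1:d], -m@u[d + 1]))), 1e-6)
})

test_that("separable Gaussian clusters are fit and predicted correctly", {
  fx <- generateClusterFixture(list(c(-2, 0), c(2, 0)), sd = 0.3, n = 50,
                               seed = 3)
  p <- twsvmProblem(fx$x[fx$labels == 1, ], fx$x[fx$labels == -1, ],
                    c1 = 10, c2 = 10, kernel = linearKernel())
  m <- trainTWSVM(p)
  expect_equal(mean(predict(m, fx$x)$label == fx$labels), 1)

  # fresh points classify by the nearer cluster mean
  fresh <- generateClusterFixture(list(c(-2, 0), c(2, 0)), sd = 0.3, n = 100,
                                  seed = 4)
  pr <- predict(m, fresh$x)
  nearer <- ifelse(sqrt(rowSums(sweep(fresh$x, 2, c(-2, 0))^2)) <=
                     sqrt(rowSums(sweep(fresh$x, 2, c(2, 0))^2)), 1, -1)
  expect_equal(pr$label, nearer)

  # raising the box parameters never hurts separable training accuracy
  for (cc in c(100, 1000)) {
    mc <- trainTWSVM(twsvmProblem(fx$x[fx$labels == 1, ],
                                  fx$x[fx$labels == -1, ],
                                  c1 = cc, c2 = cc, kernel = linearKernel()))
    expect_equal(mean(predict(mc, fx$x)$label == fx$labels), 1)
  }
})

test_that("prediction uses normalized plane distances and ties go to +1", {
  # symmetric planes: x = -1 (plane 1) and x = +1 (plane 2)
  model <- new("TWSVMModel", u = c(1, 0, 1), v = c(1, 0, -1),
               kernel = linearKernel(),
               reference = matrix(numeric(0), 0, 2),
               wnorm = c(1, 1), dual = list(), dim = 2L)
  # on plane 1, off plane 2
  expect_equal(predict(model, c(-1, 3))$label, 1)
  # equidistant point: tie -> +1, score 0
  tie <- predict(model, c(0, 5))
  expect_equal(tie$label, 1)
  expect_equal(tie$score, 0)
  expect_error(predict(model, c(1, 2, 3)), "features")
})

test_that("KKT residual certifies optima and flags non-optima", {
  p <- toyProblem()
  m <- trainTWSVM(p)
  expect_lte(kktResidual(m, p), 1e-5)

  # interior multipliers put class -1 points at unit margin
  alpha <- m@dual$alpha
  interior <- which(alpha > 1e-4 & alpha < p@c1 - 1e-4)
  if (length(interior)) {
    w1 <- m@u[1:2]; b1 <- m@u[3]
    margins <- -(p@B %*% w1 + b1)
    expect_lt(max(abs(margins[interior] - 1)), 1e-4)
  }

  # a perturbed plane is not optimal
  bad <- m
  bad@u <- m@u + 0.5
  expect_gt(kktResidual(bad, p), 1e-3)
})

test_that("implementation dual objective dominates oracle feasible points", {
  for (s in 1:20) {
    p <- randomTWSVMProblem(4000 + s)
    aug <- buildAugmented(p)
    a <- solveDTWSVM1(aug$H, aug$G, p@c1, p@ridge)
    Q <- dualQ(aug$H, aug$G, p@ridge)
    o <- boxQpOracle(Q, rep(1, nrow(aug$G)), p@c1)
    expect_gte(a$objective, o$objective - 1e-6)
    expect_lt(max(abs(as.numeric(a$alpha) - o$alpha)), 1e-5)
    m <- trainTWSVM(p)
    expect_lte(kktResidual(m, p), 1e-5)
  }
})

test_that("wide RBF kernels recover the linear decision on Gaussian data", {
  fx <- generateClusterFixture(list(c(-2, 0), c(2, 0)), sd = 0.3, n = 40,
                               seed = 8)
  A <- fx$x[fx$labels == 1, ]; B <- fx$x[fx$labels == -1, ]
  lin <- predict(trainTWSVM(twsvmProblem(A, B, 10, 10, linearKernel())),
                 fx$x)
  wide <- predict(trainTWSVM(twsvmProblem(A, B, 10, 10, rbfKernel(500))),
                  fx$x)
  expect_equal(wide$label, lin$label)
})

test_that("problem defaults carry the published RBF configuration", {
  p <- twsvmProblem(rbind(c(0, 1)), rbind(c(1, 0)))
  expect_identical(p@kernel@kind, "rbf")
  expect_equal(p@kernel@sigma, 15)
  expect_equal(p@c1, 1000)
  expect_equal(p@c2, 1000)
})
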