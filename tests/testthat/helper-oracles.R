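# Independent oracles used across the suite. These deliberately use a
# different formulation and solver (generic bound-constrained L-BFGS-B)
# than the package's coordinate methods.

# l1-regularized least squares via the nonnegative split c = cp - cm,
# a smooth bound-constrained QP.
lassoSplitOracle <- function(A, y, lambda) {
  n <- ncol(A)
  fn <- function(z) {
    cc <- z[1:n] - z[n + 1:n]
    r <- as.numeric(A %*% cc) - y
    sum(r^2) + lambda * sum(z)
  }
  gr <- function(z) {
    cc <- z[1:n] - z[n + 1:n]
    g <- 2 * as.numeric(crossprod(A, A %*% cc - y))
    c(g + lambda, -g + lambda)
  }
  o <- stats::optim(rep(0, 2 * n), fn, gr, method = "L-BFGS-B", lower = 0,
                    control = list(maxit = 20000, factr = 1))
  cc <- o$par[1:n] - o$par[n + 1:n]
  best <- o$value
  # polish: exact minimizer for the sign pattern L-BFGS-B discovered
  supp <- which(abs(cc) > 1e-7)
  if (length(supp)) {
    As <- A[, supp, drop = FALSE]
    sol <- tryCatch(
      solve(crossprod(As),
            as.numeric(crossprod(As, y)) - lambda / 2 * sign(cc[supp])),
      error = function(e) NULL)
    if (!is.null(sol) && all(sign(sol) == sign(cc[supp]))) {
      cp <- numeric(n); cp[supp] <- sol
      op <- sum((as.numeric(A %*% cp) - y)^2) + lambda * sum(abs(cp))
      if (op < best) { best <- op; cc <- cp }
    }
  }
  list(coefficients = cc, objective = best)
}

# max lin'a - a'Qa/2 subject to 0 <= a <= upper
boxQpOracle <- function(Q, lin, upper) {
  fn <- function(a) sum(lin * a) - 0.5 * sum(a * (Q %*% a))
  gr <- function(a) lin - as.numeric(Q %*% a)
  o <- stats::optim(rep(0, length(lin)), fn, gr, method = "L-BFGS-B",
                    lower = 0, upper = upper,
                    control = list(fnscale = -1, maxit = 5000, factr = 10,
                                   pgtol = 1e-12))
  list(alpha = o$par, objective = o$value)
}

# the dual Q matrix the package builds, recomputed independently
dualQ <- function(Hown, Gother, ridge) {
  M <- crossprod(Hown)
  Minv <- solve(M + diag(ridge * mean(diag(M)), ncol(M)))
  Q <- Gother %*% Minv %*% t(Gother)
  (Q + t(Q)) / 2
}

# small random two-class linear TWSVM problem with well-conditioned Grams
randomTWSVMProblem <- function(seed) {
  withSeed(seed, {
    d <- sample(2:5, 1)
    m1 <- sample((d + 2):10, 1)
    m2 <- sample((d + 2):10, 1)
    A <- matrix(rnorm(m1 * d), m1, d) + 1
    B <- matrix(rnorm(m2 * d), m2, d) - 1
    twsvmProblem(A, B, c1 = runif(1, 0.5, 5), c2 = runif(1, 0.5, 5),
                 kernel = linearKernel(), ridge = 1e-7)
  })
}

# separable Gaussian blur for the matched-filter sanity oracle; independent
# implementation (full kernel matrices, no banding)
testGaussBlur <- function(x, sigma) {
  n1 <- nrow(x); n2 <- ncol(x)
  k <- function(n) {
    K <- exp(-outer(seq_len(n), seq_len(n), "-")^2 / (2 * sigma^2))
    sweep(K, 1, rowSums(K), "/")
  }
  k(n1) %*% x %*% t(k(n2))
}
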