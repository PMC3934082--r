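# Twin support vector machines: two nonparallel planes, each fitted by a
# small box-constrained dual QP. Plane 1 hugs class +1 and keeps class -1 at
# unit margin; plane 2 is the mirror role. Classification is by the nearer
# plane (perpendicular distance, normalized by the plane weight norm).

#' Kernel constructors
#'
#' @param sigma RBF width; \eqn{K(x,z) = \exp(-\|x-z\|^2/(2\sigma^2))}.
#'   The default 15 follows common TWSVM practice for this task.
#' @return a \linkS4class{KernelSpec}.
#' @name kernels
NULL

#' @rdname kernels
#' @export
linearKernel <- function() new("KernelSpec", kind = "linear", sigma = NA_real_)

#' @rdname kernels
#' @export
rbfKernel <- function(sigma = 15) new("KernelSpec", kind = "rbf", sigma = sigma)

#' RBF Gram block between row-pattern matrices
#' @noRd
.rbfCross <- function(X, Z, sigma) {
  d2 <- outer(rowSums(X^2), rowSums(Z^2), "+") - 2 * tcrossprod(X, Z)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * sigma^2))
}

#' Define a twin SVM training problem
#'
#' @param A class +1 patterns, one row each.
#' @param B class -1 patterns, one row each.
#' @param c1,c2 positive box parameters (defaults 1000, the setting used for
#'   the mammogram task alongside the RBF width 15).
#' @param kernel a \linkS4class{KernelSpec}; default \code{rbfKernel(15)}.
#' @param ridge relative diagonal stabilizer: the Gram matrices H'H, G'G are
#'   only positive semidefinite, so \code{ridge * mean(diag)} is added before
#'   inversion.
#' @return a \linkS4class{TWSVMProblem}.
#' @export
twsvmProblem <- function(A, B, c1 = 1000, c2 = 1000, kernel = rbfKernel(15),
                         ridge = 1e-7) {
  new("TWSVMProblem", A = as.matrix(A), B = as.matrix(B), c1 = c1, c2 = c2,
      kernel = kernel, ridge = ridge)
}

#' Build the augmented pattern matrices H = [A 1], G = [B 1]
#'
#' In kernel mode the pattern blocks are the RBF cross-Gram against the
#' stacked reference matrix C = rbind(A, B).
#'
#' @param problem a \linkS4class{TWSVMProblem}.
#' @return list(H, G).
#' @export
buildAugmented <- function(problem) {
  A <- problem@A; B <- problem@B
  if (problem@kernel@kind == "rbf") {
    C <- rbind(A, B)
    A <- .rbfCross(problem@A, C, problem@kernel@sigma)
    B <- .rbfCross(problem@B, C, problem@kernel@sigma)
  }
  list(H = cbind(A, 1), G = cbind(B, 1))
}

#' Ridge-stabilized inverse application
#' @noRd
.ridgeSolve <- function(M, rhs, ridge) {
  p <- ncol(M)
  eps <- ridge * mean(diag(M))
  if (!is.finite(eps) || eps <= 0) eps <- ridge
  out <- tryCatch(solve(M + diag(eps, p), rhs), error = function(e) e)
  if (inherits(out, "error"))
    stop("augmented Gram matrix is singular even with ridge ", ridge,
         "; increase the ridge parameter")
  out
}

#' Solve the dual QPs of the twin SVM
#'
#' \code{solveDTWSVM1} maximizes \eqn{e^T\alpha - \alpha^T G (H^TH)^{-1} G^T
#' \alpha / 2} over \eqn{0 \le \alpha \le c_1} (multipliers of the class -1
#' margin constraints); \code{solveDTWSVM2} is the symmetric counterpart with
#' \eqn{0 \le \gamma \le c_2}. Solved by cyclic coordinate ascent with a
#' projected-gradient stationarity certificate.
#'
#' @param H,G augmented pattern matrices from \code{\link{buildAugmented}}.
#' @param c1,c2 box parameters.
#' @param ridge relative diagonal stabilizer for the Gram inverse.
#' @param tol stationarity tolerance (projected-gradient residual).
#' @param maxIter sweep cap.
#' @return list(alpha (or gamma), objective, residual, iterations, converged).
#' @name dtwsvm
NULL

.solveBoxDual <- function(Hown, Gother, cbox, ridge, tol, maxIter) {
  M <- crossprod(Hown)
  Q <- Gother %*% .ridgeSolve(M, t(Gother), ridge)
  Q <- (Q + t(Q)) / 2
  fit <- .boxqp_ca(Q, rep(1, nrow(Gother)), cbox, tol, as.integer(maxIter))
  if (!isTRUE(fit$converged) && fit$residual > sqrt(tol))
    warning("dual QP stationarity residual ", format(fit$residual),
            " above tolerance after ", fit$iterations, " sweeps")
  fit
}

#' @rdname dtwsvm
#' @export
solveDTWSVM1 <- function(H, G, c1, ridge = 1e-7, tol = 1e-10,
                         maxIter = 20000L) {
  stopifnot(c1 > 0)
  fit <- .solveBoxDual(H, G, c1, ridge, tol, maxIter)
  names(fit)[names(fit) == "alpha"] <- "alpha"
  fit
}

#' @rdname dtwsvm
#' @export
solveDTWSVM2 <- function(H, G, c2, ridge = 1e-7, tol = 1e-10,
                         maxIter = 20000L) {
  stopifnot(c2 > 0)
  fit <- .solveBoxDual(G, H, c2, ridge, tol, maxIter)
  names(fit)[names(fit) == "alpha"] <- "gamma"
  fit
}

#' Recover the primal augmented plane vectors from the duals
#'
#' \eqn{u = -(H^TH + \epsilon I)^{-1} G^T \alpha} (plane 1) and
#' \eqn{v = +(G^TG + \epsilon I)^{-1} H^T \gamma} (plane 2, oriented so class
#' +1 patterns sit on its positive side, the orientation the unit-margin
#' constraints imply).
#'
#' @param H,G augmented pattern matrices.
#' @param alpha,gamma dual solutions.
#' @param ridge relative diagonal stabilizer.
#' @return list(u, v), each c(w, b).
#' @export
recoverPrimal <- function(H, G, alpha, gamma, ridge = 1e-7) {
  u <- -as.numeric(.ridgeSolve(crossprod(H), crossprod(G, alpha), ridge))
  v <- as.numeric(.ridgeSolve(crossprod(G), crossprod(H, gamma), ridge))
  list(u = u, v = v)
}

#' Train a twin support vector machine
#'
#' Solves both dual QPs and recovers the two planes. In RBF mode the same
#' algebra runs on the kernel cross-Gram against the stacked training matrix
#' C = rbind(A, B), giving surfaces \eqn{K(x, C) w + b = 0}.
#'
#' @param problem a \linkS4class{TWSVMProblem}.
#' @param tol,maxIter dual-solver controls.
#' @return a \linkS4class{TWSVMModel}.
#' @export
trainTWSVM <- function(problem, tol = 1e-10, maxIter = 20000L) {
  stopifnot(is(problem, "TWSVMProblem"))
  aug <- buildAugmented(problem)
  d1 <- solveDTWSVM1(aug$H, aug$G, problem@c1, problem@ridge, tol, maxIter)
  d2 <- solveDTWSVM2(aug$H, aug$G, problem@c2, problem@ridge, tol, maxIter)
  pr <- recoverPrimal(aug$H, aug$G, d1$alpha, d2$gamma, problem@ridge)
  p <- length(pr$u)
  w1 <- pr$u[-p]; w2 <- pr$v[-p]
  if (problem@kernel@kind == "rbf") {
    C <- rbind(problem@A, problem@B)
    Kcc <- .rbfCross(C, C, problem@kernel@sigma)
    wnorm <- c(sqrt(max(0, sum(w1 * (Kcc %*% w1)))),
               sqrt(max(0, sum(w2 * (Kcc %*% w2)))))
    reference <- C
  } else {
    wnorm <- c(sqrt(sum(w1^2)), sqrt(sum(w2^2)))
    reference <- matrix(numeric(0), 0, ncol(problem@A))
  }
  new("TWSVMModel", u = pr$u, v = pr$v, kernel = problem@kernel,
      reference = reference, wnorm = wnorm,
      dual = list(alpha = as.numeric(d1$alpha), gamma = as.numeric(d2$gamma),
                  objective1 = d1$objective, objective2 = d2$objective,
                  residual1 = d1$residual, residual2 = d2$residual,
                  converged = isTRUE(d1$converged) && isTRUE(d2$converged)),
      dim = ncol(problem@A))
}

setMethod("show", "TWSVMModel", function(object) {
  cat(sprintf("TWSVMModel: %s kernel%s, %d-dim input, |w1| = %.4g, |w2| = %.4g\n",
              object@kernel@kind,
              if (object@kernel@kind == "rbf")
                sprintf(" (sigma = %g)", object@kernel@sigma) else "",
              object@dim, object@wnorm[1], object@wnorm[2]))
})

#' Signed plane evaluations for raw points
#' @noRd
.planeValues <- function(model, X) {
  X <- if (is.matrix(X)) X else matrix(X, nrow = 1)
  if (ncol(X) != model@dim)
    stop(sprintf("model expects %d features, input has %d",
                 model@dim, ncol(X)))
  Phi <- if (model@kernel@kind == "rbf")
    .rbfCross(X, model@reference, model@kernel@sigma) else X
  p <- length(model@u)
  cbind(Phi %*% model@u[-p] + model@u[p],
        Phi %*% model@v[-p] + model@v[p])
}

#' Classify points with a trained twin SVM
#'
#' Computes the perpendicular distance \eqn{d_i(x) = |K(x,C) w_i + b_i| /
#' \|w_i\|} to each plane and assigns class +1 iff \eqn{d_1 \le d_2} (ties go
#' to +1). The continuous margin score is \eqn{d_2 - d_1}: larger means more
#' class +1. Set \code{normalize = FALSE} for the strict-literal unnormalized
#' comparison.
#'
#' @param object a \linkS4class{TWSVMModel}.
#' @param newdata numeric vector or matrix of row points.
#' @param normalize divide by the plane weight norms (default TRUE).
#' @param ... unused.
#' @return data.frame with columns \code{label} and \code{score}.
#' @export
setMethod("predict", "TWSVMModel",
  function(object, newdata, normalize = TRUE, ...) {
    pv <- abs(.planeValues(object, newdata))
    if (normalize) {
      wn <- pmax(object@wnorm, .Machine$double.eps)
      pv <- sweep(pv, 2, wn, "/")
    }
    score <- pv[, 2] - pv[, 1]
    data.frame(label = ifelse(pv[, 1] <= pv[, 2], 1, -1), score = score)
  })

#' Maximum KKT violation of a trained model
#'
#' Checks, for both dual problems, stationarity of the ridge-free primal
#' system, box feasibility of the multipliers, primal feasibility of the
#' unit-margin constraints with slack q = max(0, e - margin), and
#' complementary slackness. Returns the largest violation; used to certify
#' solutions in tests.
#'
#' @param model a \linkS4class{TWSVMModel}.
#' @param problem the \linkS4class{TWSVMProblem} it was trained on.
#' @return nonnegative scalar.
#' @export
kktResidual <- function(model, problem) {
  aug <- buildAugmented(problem)
  H <- aug$H; G <- aug$G
  alpha <- model@dual$alpha; gamma <- model@dual$gamma
  v1 <- .kktOne(H, G, model@u, alpha, problem@c1)
  v2 <- .kktOne(G, H, model@v, gamma, problem@c2, flip = TRUE)
  max(v1, v2)
}

# One-sided KKT block: plane vector z hugs the rows of Hown; the rows of
# Gother must sit at margin >= 1 (negative side for plane 1, positive side
# for plane 2 -- `flip` selects the orientation).
.kktOne <- function(Hown, Gother, z, mult, cbox, flip = FALSE) {
  sgn <- if (flip) 1 else -1
  margin <- sgn * as.numeric(Gother %*% z)       # should be >= 1 - q
  q <- pmax(0, 1 - margin)
  stat <- max(abs(crossprod(Hown) %*% z - sgn * crossprod(Gother, mult)))
  box <- max(0, -mult, mult - cbox)
  feas <- max(0, 1 - margin - q, -q)
  cs1 <- abs(sum(mult * (margin + q - 1)))
  cs2 <- abs(sum((cbox - mult) * q))
  max(stat, box, feas, cs1, cs2)
}
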