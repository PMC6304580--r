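## The completion core: minimize over X
##
##   ||X||_* + alpha ||X||_F^2 + beta ||A o X - A||_F^2
##          + lambda [ tr(X' L_d X) + tr(X L_t X') ]
##
## where A is the binary indicator of observed interactions and o is the
## Hadamard product. Solved by an inexact augmented Lagrange multiplier
## scheme on the split X = J (nuclear norm) and X = Z (fidelity):
## J by singular value thresholding, Z by a diagonal linear system in
## closed form, X by a Sylvester equation solved in the eigenbases of the
## two Laplacians, then multiplier ascent with a growing penalty.

#' Construct solver hyperparameters
#'
#' @param alpha Tikhonov weight on the score matrix (default 0.1).
#' @param beta fidelity weight preserving observed interactions
#'   (default 1).
#' @param lambda dual Laplacian smoothness weight (default 1).
#' @param mu1Init,mu2Init initial penalties (default 1e-2).
#' @param rho penalty growth factor per iteration (default 1.1).
#' @param muMax penalty cap (default 1e6).
#' @param tol convergence tolerance on max(||X - J||_inf, ||X - Z||_inf)
#'   (default 1e-6).
#' @param maxIter iteration cap (default 500).
#' @param seed carried for API uniformity; the solver is deterministic.
#' @return A validated [HyperParams] object.
#' @details The weights are conventionally tuned by grid search over
#'   \code{c(0.001, 0.01, 0.1, 1, 10, 100, 1000)} for each of alpha, beta
#'   and lambda (see [hyperParamGrid()]).
#' @export
hyperParams <- function(alpha = 0.1, beta = 1, lambda = 1,
                        mu1Init = 1e-2, mu2Init = 1e-2,
                        rho = 1.1, muMax = 1e6,
                        tol = 1e-6, maxIter = 500L, seed = 1L) {
    new("HyperParams",
        alpha = alpha, beta = beta, lambda = lambda,
        mu1Init = mu1Init, mu2Init = mu2Init,
        rho = rho, muMax = muMax, tol = tol,
        maxIter = as.integer(maxIter), seed = as.integer(seed))
}

#' Default hyperparameter grid
#'
#' The seven-point logarithmic grid conventionally searched for each of
#' the three regularization weights.
#'
#' @return \code{c(0.001, 0.01, 0.1, 1, 10, 100, 1000)}.
#' @export
hyperParamGrid <- function() c(0.001, 0.01, 0.1, 1, 10, 100, 1000)

#' Singular value thresholding operator
#'
#' The proximal operator of the nuclear norm: for the SVD Y = U S V',
#' returns U max(S - tau, 0) V'. It is the unique minimizer of
#' tau ||J||_* + (1/2) ||J - Y||_F^2.
#'
#' @param Y numeric matrix.
#' @param tau threshold, >= 0.
#' @return The thresholded matrix.
#' @examples
#' svt(diag(c(3, 1)), 2)  # diag(1, 0)
#' @export
svt <- function(Y, tau) {
    if (tau < 0) stop("tau must be >= 0")
    if (any(!is.finite(Y))) stop("Y must be finite")
    if (tau == 0) return(Y)
    sv <- svd(Y)
    keep <- pmax(sv$d - tau, 0)
    pos <- keep > 0
    if (!any(pos)) return(matrix(0, nrow(Y), ncol(Y)))
    sv$u[, pos, drop = FALSE] %*%
        (keep[pos] * t(sv$v[, pos, drop = FALSE]))
}

#' Nuclear norm
#'
#' Sum of singular values, the convex surrogate for matrix rank.
#'
#' @param X numeric matrix.
#' @return A nonnegative scalar.
#' @export
nuclearNorm <- function(X) sum(svd(X, nu = 0, nv = 0)$d)

#' Completion objective value
#'
#' The four-term objective: nuclear norm, Tikhonov term, observed-entry
#' fidelity and the dual Laplacian smoothness penalty.
#'
#' @param X d x t score matrix.
#' @param A binary indicator matrix of observed interactions.
#' @param laplacians a [LaplacianPair].
#' @param hp a [HyperParams].
#' @return A scalar.
#' @export
objectiveValue <- function(X, A, laplacians, hp) {
    if (any(is.na(X))) stop("X contains NaN")
    nuclearNorm(X) +
        hp@alpha * sum(X^2) +
        hp@beta * sum((A * X - A)^2) +
        hp@lambda * (laplacianQuadratic(laplacians@drugLaplacian, X, "rows") +
                     laplacianQuadratic(laplacians@targetLaplacian, X, "cols"))
}

#' Augmented Lagrangian value
#'
#' The augmented Lagrangian of the split problem, with the nuclear norm
#' on J, the fidelity on Z, the smoothness and Tikhonov terms on X, and
#' linear plus quadratic penalty terms for the constraints X = J and
#' X = Z. Each block update minimizes this function exactly in its block,
#' so its value is non-increasing across the J, Z, X updates of one
#' iteration.
#'
#' @param X,J,Z primal blocks.
#' @param Y1,Y2 Lagrange multipliers.
#' @param mu1,mu2 penalties.
#' @inheritParams objectiveValue
#' @return A scalar.
#' @export
augLagrangian <- function(X, J, Z, Y1, Y2, mu1, mu2, A, laplacians, hp) {
    nuclearNorm(J) +
        hp@alpha * sum(X^2) +
        hp@beta * sum((A * Z - A)^2) +
        hp@lambda * (laplacianQuadratic(laplacians@drugLaplacian, X, "rows") +
                     laplacianQuadratic(laplacians@targetLaplacian, X, "cols")) +
        sum(Y1 * (X - J)) + mu1 / 2 * sum((X - J)^2) +
        sum(Y2 * (X - Z)) + mu2 / 2 * sum((X - Z)^2)
}

#' Block update for the nuclear-norm auxiliary J
#'
#' Minimizes ||J||_* + (mu1/2) ||X - J + Y1/mu1||_F^2, i.e.
#' J = svt(X + Y1/mu1, 1/mu1).
#'
#' @param X current score matrix.
#' @param Y1 multiplier for the X = J constraint.
#' @param mu1 penalty, > 0.
#' @return The updated J.
#' @export
updateJ <- function(X, Y1, mu1) {
    if (mu1 <= 0) stop("mu1 must be > 0")
    svt(X + Y1 / mu1, 1 / mu1)
}

#' Block update for the fidelity auxiliary Z
#'
#' Minimizes beta ||A o Z - A||_F^2 + (mu2/2) ||X - Z + Y2/mu2||_F^2.
#' The stationarity system is diagonal in the entries of Z (the linear
#' operator is 2 beta diag(vec(A)) + mu2 I), giving the closed form
#' Z_ij = (2 beta A_ij + mu2 X_ij + Y2_ij) / (2 beta A_ij + mu2)
#' for binary A.
#'
#' @param X current score matrix.
#' @param Y2 multiplier for the X = Z constraint.
#' @param mu2 penalty, > 0.
#' @param A binary indicator matrix.
#' @param beta fidelity weight.
#' @return The updated Z.
#' @export
updateZ <- function(X, Y2, mu2, A, beta) {
    if (mu2 <= 0) stop("mu2 must be > 0")
    (2 * beta * A + mu2 * X + Y2) / (2 * beta * A + mu2)
}

## cached symmetric eigendecompositions of the two Laplacians
.lapEigen <- function(laplacians) {
    ed <- eigen(laplacians@drugLaplacian, symmetric = TRUE)
    et <- eigen(laplacians@targetLaplacian, symmetric = TRUE)
    list(P = ed$vectors, dVals = ed$values,
         Q = et$vectors, tVals = et$values)
}

.updateXEigen <- function(J, Z, Y1, Y2, mu1, mu2, eig, alpha, lambda) {
    cc <- 2 * alpha + mu1 + mu2
    RHS <- mu1 * J + mu2 * Z - Y1 - Y2
    denom <- outer(cc + 2 * lambda * eig$dVals, 2 * lambda * eig$tVals, "+")
    eig$P %*% ((crossprod(eig$P, RHS) %*% eig$Q) / denom) %*% t(eig$Q)
}

#' Block update for the score matrix X
#'
#' Solves the stationarity condition
#' 2 alpha X + 2 lambda (L_d X + X L_t) + mu1 (X - J) + mu2 (X - Z)
#' + Y1 + Y2 = 0, a Sylvester equation
#' [(2 alpha + mu1 + mu2) I + 2 lambda L_d] X + X [2 lambda L_t] = RHS
#' with RHS = mu1 J + mu2 Z - Y1 - Y2. Both coefficient matrices are
#' symmetric and the left one is strictly positive definite for
#' mu1 + mu2 > 0 (the Laplacians are positive semidefinite), so the
#' solution exists and is unique. Solved by diagonalizing the two
#' Laplacians.
#'
#' @param J,Z auxiliary blocks.
#' @param Y1,Y2 multipliers.
#' @param mu1,mu2 penalties, > 0 in total.
#' @param laplacians a [LaplacianPair].
#' @param hp a [HyperParams] (alpha and lambda are used).
#' @return The updated X; an error is raised with residual diagnostics
#'   if the solution does not satisfy the stationarity condition to
#'   1e-8 relative accuracy.
#' @export
updateX <- function(J, Z, Y1, Y2, mu1, mu2, laplacians, hp) {
    eig <- .lapEigen(laplacians)
    X <- .updateXEigen(J, Z, Y1, Y2, mu1, mu2, eig, hp@alpha, hp@lambda)
    RHS <- mu1 * J + mu2 * Z - Y1 - Y2
    resid <- (2 * hp@alpha + mu1 + mu2) * X +
        2 * hp@lambda * (laplacians@drugLaplacian %*% X +
                         X %*% laplacians@targetLaplacian) - RHS
    rel <- max(abs(resid)) / (1 + max(abs(RHS)))
    if (rel > 1e-8)
        stop(sprintf("Sylvester solve failed: relative residual %.3g", rel))
    X
}

#' Multiplier and penalty update
#'
#' Ascent on the Lagrange multipliers, Y1 <- Y1 + mu1 (X - J) and
#' Y2 <- Y2 + mu2 (X - Z), followed by the penalty schedule
#' mu <- min(rho mu, muMax).
#'
#' @param X,J,Z primal blocks after the current iteration's updates.
#' @param Y1,Y2 current multipliers.
#' @param mu1,mu2 current penalties.
#' @param rho penalty growth factor.
#' @param muMax penalty cap.
#' @return A list with elements Y1, Y2, mu1, mu2.
#' @export
updateMultipliers <- function(X, J, Z, Y1, Y2, mu1, mu2,
                              rho = 1.1, muMax = 1e6) {
    list(Y1 = Y1 + mu1 * (X - J),
         Y2 = Y2 + mu2 * (X - Z),
         mu1 = min(rho * mu1, muMax),
         mu2 = min(rho * mu2, muMax))
}

.fitCore <- function(A, DS, TS, hp, drugIds = NULL, targetIds = NULL,
                     knnK = NULL, rbfSigma = NULL) {
    stopifnot(is.matrix(A), nrow(DS) == nrow(A), nrow(TS) == ncol(A))
    if (!.isBinary(A)) stop("A must be binary")
    lap <- laplacianPair(DS, TS, knnK = knnK, rbfSigma = rbfSigma)
    eig <- .lapEigen(lap)
    X <- J <- Z <- A
    Y1 <- Y2 <- matrix(0, nrow(A), ncol(A))
    mu1 <- hp@mu1Init; mu2 <- hp@mu2Init
    resids <- matrix(NA_real_, hp@maxIter, 2,
                     dimnames = list(NULL, c("XminusJ", "XminusZ")))
    objs <- rep(NA_real_, hp@maxIter)
    convergedAt <- NA_integer_
    for (it in seq_len(hp@maxIter)) {
        J <- updateJ(X, Y1, mu1)
        Z <- updateZ(X, Y2, mu2, A, hp@beta)
        X <- .updateXEigen(J, Z, Y1, Y2, mu1, mu2, eig, hp@alpha, hp@lambda)
        up <- updateMultipliers(X, J, Z, Y1, Y2, mu1, mu2, hp@rho, hp@muMax)
        Y1 <- up$Y1; Y2 <- up$Y2
        r <- c(max(abs(X - J)), max(abs(X - Z)))
        mu1 <- up$mu1; mu2 <- up$mu2
        resids[it, ] <- r
        objs[it] <- objectiveValue(X, A, lap, hp)
        if (max(r) <= hp@tol) {
            convergedAt <- it
            break
        }
    }
    it <- if (is.na(convergedAt)) hp@maxIter else convergedAt
    if (is.na(convergedAt))
        warning(sprintf(
            "solver did not converge in %d iterations (residual %.3g)",
            hp@maxIter, max(resids[it, ])))
    if (is.null(drugIds)) drugIds <- rownames(A)
    if (is.null(targetIds)) targetIds <- colnames(A)
    if (is.null(drugIds)) drugIds <- sprintf("drug%d", seq_len(nrow(A)))
    if (is.null(targetIds)) targetIds <- sprintf("target%d", seq_len(ncol(A)))
    dimnames(X) <- list(drugIds, targetIds)
    new("ALMFit",
        X = X, J = J, Z = Z, Y1 = Y1, Y2 = Y2,
        mu1 = mu1, mu2 = mu2,
        iterations = as.integer(it),
        converged = !is.na(convergedAt),
        primalResiduals = resids[seq_len(it), , drop = FALSE],
        objectiveTrace = objs[seq_len(it)],
        drugIds = as.character(drugIds),
        targetIds = as.character(targetIds))
}

#' Fit the dual Laplacian regularized matrix completion model
#'
#' Runs the augmented Lagrangian solver on a training indicator matrix A
#' with the drug and target similarity graphs, returning the completed
#' score matrix and the full solver state. Candidate interactions are
#' ranked by the completed scores in descending order.
#'
#' The solver is deterministic: identical inputs give bit-identical
#' results. Initialization is X = J = Z = A and zero multipliers.
#'
#' @param x a [DTIData] (its interaction matrix is used as A) or a
#'   binary d x t matrix.
#' @param drugSim,targetSim similarity matrices, required when \code{x}
#'   is a matrix.
#' @param hp a [HyperParams]; default [hyperParams()].
#' @param knnK if not NULL, sparsify both similarity graphs to the
#'   symmetric union of k nearest neighbors before building the
#'   Laplacians (default NULL: dense graphs).
#' @param rbfSigma if not NULL, Gaussian-kernel reweighting width applied
#'   to the similarities before (optional) sparsification.
#' @param ... unused.
#' @return An [ALMFit].
#' @examples
#' sim <- simulateDTI(d = 20, t = 12, rank = 2, seed = 1)
#' fit <- fitLapMC(dtiData(sim), hp = hyperParams(maxIter = 200))
#' converged(fit)
#' @name fitLapMC
NULL

#' @rdname fitLapMC
#' @export
setMethod("fitLapMC", "DTIData", function(x, hp = hyperParams(),
                                          knnK = NULL, rbfSigma = NULL,
                                          ...) {
    .fitCore(x@interactions, x@drugSim, x@targetSim, hp,
             drugIds = x@drugIds, targetIds = x@targetIds,
             knnK = knnK, rbfSigma = rbfSigma)
})

#' @rdname fitLapMC
#' @export
setMethod("fitLapMC", "matrix", function(x, drugSim, targetSim,
                                         hp = hyperParams(),
                                         knnK = NULL, rbfSigma = NULL,
                                         ...) {
    .fitCore(x, drugSim, targetSim, hp, knnK = knnK, rbfSigma = rbfSigma)
})

#' @rdname ALMFit-accessors
#' @export
setMethod("predictedScores", "ALMFit", function(x) x@X)

#' Accessors for ALMFit
#'
#' \code{predictedScores} returns the completed score matrix;
#' \code{converged} reports whether both primal residuals fell below the
#' tolerance.
#'
#' @param x an [ALMFit].
#' @name ALMFit-accessors
NULL

#' @rdname ALMFit-accessors
#' @export
setMethod("converged", "ALMFit", function(x) x@converged)

setMethod("show", "ALMFit", function(object) {
    r <- object@primalResiduals[nrow(object@primalResiduals), ]
    cat(sprintf("ALMFit: %d x %d scores, %d iterations (%s)\n",
                nrow(object@X), ncol(object@X), object@iterations,
                if (object@converged) "converged" else "NOT converged"))
    cat(sprintf("  final residuals: |X-J| = %.3g, |X-Z| = %.3g\n",
                r[1], r[2]))
    cat(sprintf("  final objective: %.6g\n",
                object@objectiveTrace[length(object@objectiveTrace)]))
})

#' Plain nuclear-norm matrix completion baseline
#'
#' Solves min ||X||_* subject to X agreeing with M on the observed
#' entries, by the classic singular value thresholding iteration
#' (shrinkage step on a dual variable accumulating the observed-entry
#' misfit). Used as a no-similarity baseline; at convergence the observed
#' entries are reproduced within \code{tol}.
#'
#' @param M matrix with the observed values.
#' @param observed logical matrix (or two-column index matrix) marking
#'   the observed entries; must be non-empty.
#' @param tau shrinkage threshold; default 5 * sqrt(d * t).
#' @param delta step size; default 1.2 / fraction observed.
#' @param tol max-abs constraint violation target on the observed
#'   entries (default 1e-3).
#' @param maxIter iteration cap (default 2000).
#' @return A list with the completed matrix \code{X}, \code{iterations}
#'   and \code{converged}.
#' @export
plainMC <- function(M, observed, tau = NULL, delta = NULL,
                    tol = 1e-3, maxIter = 2000L) {
    if (!is.logical(observed)) {
        idx <- observed
        observed <- matrix(FALSE, nrow(M), ncol(M))
        observed[idx] <- TRUE
    }
    m <- sum(observed)
    if (m == 0) stop("observed set is empty")
    p <- m / length(M)
    if (is.null(tau)) tau <- 5 * sqrt(nrow(M) * ncol(M))
    if (is.null(delta)) delta <- 1.2 / p
    Y <- matrix(0, nrow(M), ncol(M))
    X <- Y
    convergedAt <- NA_integer_
    for (it in seq_len(maxIter)) {
        X <- svt(Y, tau)
        gap <- (M - X) * observed
        if (max(abs(gap)) <= tol) {
            convergedAt <- it
            break
        }
        Y <- Y + delta * gap
    }
    if (is.na(convergedAt))
        warning("plain completion did not reach the constraint tolerance")
    list(X = X,
         iterations = if (is.na(convergedAt)) maxIter else convergedAt,
         converged = !is.na(convergedAt))
}
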