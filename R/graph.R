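## Graph Laplacian machinery for the dual smoothness regularizer.
## The canonical penalty is the trace form tr(X' L_d X) + tr(X L_t X');
## the pairwise double-sum over similarity weights equals twice the trace
## form, a factor conventionally absorbed into the smoothness weight.

#' Build an unnormalized graph Laplacian
#'
#' Computes L = D - W with degrees D(i,i) = sum_j W(i,j). Self-loop
#' weights (e.g. the unit diagonal of a similarity matrix) are kept in the
#' degree, literal to that definition; they cancel in the quadratic form
#' so the penalty is unaffected.
#'
#' @param W symmetric nonnegative weight matrix.
#' @return The Laplacian matrix, symmetric with zero row sums and
#'   positive semidefinite.
#' @examples
#' buildLaplacian(matrix(1, 2, 2))  # [[1, -1], [-1, 1]]
#' @export
buildLaplacian <- function(W) {
    if (!is.matrix(W) || nrow(W) != ncol(W))
        stop("W must be a square matrix")
    if (max(abs(W - t(W))) > 1e-8)
        stop("W must be symmetric")
    if (any(W < 0))
        stop("W must be nonnegative")
    L <- -W
    diag(L) <- rowSums(W) - diag(W)
    ## exact symmetry for downstream eigendecomposition
    (L + t(L)) / 2
}

#' Build the drug/target Laplacian pair
#'
#' Convenience wrapper building both Laplacians from a dataset's
#' similarity matrices, optionally after Gaussian-kernel reweighting and
#' k-nearest-neighbor sparsification. By default the dense similarity
#' matrices are used directly as edge weights.
#'
#' @param x a [DTIData] with both similarity matrices, or a d x d drug
#'   similarity matrix (then \code{targetSim} must be given).
#' @param targetSim t x t target similarity matrix when \code{x} is a
#'   matrix.
#' @param knnK if not NULL, sparsify each graph to the symmetric union of
#'   k nearest neighbors before building the Laplacian.
#' @param rbfSigma if not NULL, first reweight similarities through the
#'   Gaussian kernel exp(-(1 - s)^2 / (2 sigma^2)).
#' @return A [LaplacianPair].
#' @export
laplacianPair <- function(x, targetSim = NULL, knnK = NULL, rbfSigma = NULL) {
    if (is(x, "DTIData")) {
        ## slot access: the targetSim argument shadows the accessor here
        DS <- x@drugSim; TS <- x@targetSim
        if (!length(DS) || !length(TS))
            stop("dataset is missing a similarity matrix")
    } else {
        DS <- x; TS <- targetSim
        if (is.null(TS)) stop("targetSim is required")
    }
    src <- "dense_similarity"
    if (!is.null(rbfSigma)) {
        DS <- rbfKernel(DS, rbfSigma)
        TS <- rbfKernel(TS, rbfSigma)
    }
    if (!is.null(knnK)) {
        DS <- knnSparsify(DS, knnK)
        TS <- knnSparsify(TS, knnK)
        src <- "knn_sparsified"
    }
    new("LaplacianPair",
        drugLaplacian = buildLaplacian(DS),
        targetLaplacian = buildLaplacian(TS),
        drugDegrees = rowSums(DS),
        targetDegrees = rowSums(TS),
        source = src)
}

#' Gaussian kernel reweighting of a similarity matrix
#'
#' Maps similarities s to exp(-(1 - s)^2 / (2 sigma^2)), i.e. treats
#' 1 - s as a distance and applies a Gaussian (RBF) kernel of width
#' \code{sigma}. Preserves symmetry and the unit diagonal.
#'
#' @param W similarity matrix with entries in [0, 1].
#' @param sigma kernel width (> 0).
#' @return The reweighted matrix.
#' @export
rbfKernel <- function(W, sigma) {
    if (sigma <= 0) stop("sigma must be > 0")
    exp(-(1 - W)^2 / (2 * sigma^2))
}

#' k-nearest-neighbor sparsification of a similarity graph
#'
#' Keeps the off-diagonal weight W[i, j] iff j is among the k largest
#' off-diagonal entries of row i or i is among those of row j (the
#' symmetric union rule), and preserves the diagonal. The edge set is
#' monotone in k.
#'
#' @param W symmetric similarity matrix.
#' @param k number of neighbors, 1 <= k < nrow(W).
#' @return The sparsified symmetric matrix.
#' @export
knnSparsify <- function(W, k) {
    n <- nrow(W)
    if (k < 1 || k >= n)
        stop("k must satisfy 1 <= k < n")
    keep <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
        w <- W[i, ]
        w[i] <- -Inf
        nb <- order(w, decreasing = TRUE)[seq_len(k)]
        keep[i, nb] <- TRUE
    }
    keep <- keep | t(keep)
    out <- W
    out[!keep] <- 0
    diag(out) <- diag(W)
    out
}

#' Laplacian quadratic smoothness penalty
#'
#' Evaluates the smoothness of a score matrix with respect to a graph
#' Laplacian: \code{side = "rows"} gives tr(X' L X), penalizing
#' differences between rows of X across similar drugs; \code{side =
#' "cols"} gives tr(X L X'), penalizing differences between columns
#' across similar targets. Equals half the pairwise weighted
#' sum-of-squared-differences form.
#'
#' @param L graph Laplacian (d x d for rows, t x t for cols).
#' @param X d x t score matrix.
#' @param side \code{"rows"} or \code{"cols"}.
#' @return A scalar.
#' @export
laplacianQuadratic <- function(L, X, side = c("rows", "cols")) {
    side <- match.arg(side)
    if (side == "rows") {
        if (nrow(L) != nrow(X)) stop("shape mismatch: L is not d x d")
        sum((L %*% X) * X)
    } else {
        if (nrow(L) != ncol(X)) stop("shape mismatch: L is not t x t")
        sum((X %*% L) * X)
    }
}
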