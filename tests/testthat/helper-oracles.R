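## Independent oracles used across the suite. These deliberately use
## naive formulations (double sums, dense linear systems, exhaustive
## threshold enumeration, textbook DP) so they share no code path with
## the implementation they check.

## pairwise weighted sum-of-squared-differences form of the graph
## smoothness penalty; equals 2 * tr(X' L X) for rows
pairwiseSmoothness <- function(W, X, side = "rows") {
    n <- nrow(W)
    total <- 0
    for (i in seq_len(n)) {
        for (j in seq_len(n)) {
            diff <- if (side == "rows") X[i, ] - X[j, ] else X[, i] - X[, j]
            total <- total + sum(diff^2) * W[i, j]
        }
    }
    total
}

## brute-force per-row top-k union sparsification
bruteKnn <- function(W, k) {
    n <- nrow(W)
    keep <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
        others <- setdiff(seq_len(n), i)
        top <- others[order(W[i, others], decreasing = TRUE)][seq_len(k)]
        keep[i, top] <- TRUE
    }
    keep <- keep | t(keep)
    out <- W * keep
    diag(out) <- diag(W)
    out
}

## random symmetric nonnegative weight matrix with unit diagonal
randomWeights <- function(n) {
    W <- matrix(runif(n * n), n, n)
    W <- (W + t(W)) / 2
    diag(W) <- 1
    W
}

## textbook affine-gap Smith-Waterman DP (a gap of length L costs
## open + L * ext), three-state recurrence, local floor at zero
swOracle <- function(a, b, subst, open = 10, ext = 1) {
    a <- strsplit(a, "")[[1]]
    b <- strsplit(b, "")[[1]]
    n <- length(a); m <- length(b)
    NEG <- -1e9
    M <- matrix(0, n + 1, m + 1)
    Ix <- matrix(NEG, n + 1, m + 1)
    Iy <- matrix(NEG, n + 1, m + 1)
    best <- 0
    for (i in seq_len(n)) {
        for (j in seq_len(m)) {
            s <- subst[a[i], b[j]]
            M[i + 1, j + 1] <- max(0,
                M[i, j] + s, Ix[i, j] + s, Iy[i, j] + s)
            Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                                    Ix[i, j + 1] - ext)
            Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                                    Iy[i + 1, j] - ext)
            best <- max(best, M[i + 1, j + 1])
        }
    }
    best
}

## exhaustive threshold enumeration of the precision-recall points
prOracle <- function(scores, labels) {
    th <- sort(unique(scores), decreasing = TRUE)
    P <- sum(labels)
    recall <- precision <- numeric(length(th))
    for (k in seq_along(th)) {
        pred <- scores >= th[k]
        recall[k] <- sum(labels[pred]) / P
        precision[k] <- sum(labels[pred]) / sum(pred)
    }
    data.frame(threshold = c(Inf, th),
               recall = c(0, recall),
               precision = c(precision[1], precision))
}

## dense (d*t) x (d*t) linear system for the fidelity block:
## [2 beta diag(vec(A)) + mu2 I] vec(Z) = vec(2 beta A o A + mu2 X + Y2)
denseZOracle <- function(X, Y2, mu2, A, beta) {
    dt <- length(A)
    R <- diag(mu2, dt) + 2 * beta * diag(as.vector(A))
    C <- 2 * beta * (A * A) + mu2 * X + Y2
    matrix(solve(R, as.vector(C)), nrow(A), ncol(A))
}

## small random problem instance for solver block tests
randomState <- function(d, t, seed) {
    set.seed(seed)
    list(
        X = matrix(rnorm(d * t), d, t),
        J = matrix(rnorm(d * t), d, t),
        Z = matrix(rnorm(d * t), d, t),
        Y1 = matrix(rnorm(d * t), d, t),
        Y2 = matrix(rnorm(d * t), d, t),
        A = matrix(rbinom(d * t, 1, 0.3), d, t),
        Wd = randomWeights(d),
        Wt = randomWeights(t))
}

writeTempTSV <- function(lines) {
    path <- tempfile(fileext = ".tsv")
    writeLines(lines, path)
    path
}
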