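## Cross-validation under three blinding settings and precision-recall
## evaluation. "pairs" blinds random matrix entries (interaction
## re-ranking), "drugs" blinds whole rows (new-drug scenario), "targets"
## blinds whole columns (new-target scenario). One pooled AUPR is
## computed per repetition; mean and standard deviation are reported over
## repetitions.

.normalizeSetting <- function(setting) {
    s <- tolower(setting)
    map <- c(cv1 = "pairs", cv2 = "drugs", cv3 = "targets",
             pairs = "pairs", drugs = "drugs", targets = "targets")
    if (!s %in% names(map))
        stop("unknown CV setting: ", setting)
    unname(map[s])
}

## run expr under a temporary RNG state seeded with `seed`
.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv())) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    expr
}

#' Build a seeded cross-validation plan
#'
#' Partitions the evaluation units uniformly at random (without
#' replacement) into \code{nFolds} folds, independently for each of
#' \code{nReps} repetitions. Fold sizes differ by at most one.
#' Regenerating with the same seed reproduces the identical plan.
#'
#' @param x a [DTIData], or an integer vector \code{c(d, t)}.
#' @param setting \code{"pairs"}/\code{"cv1"}, \code{"drugs"}/
#'   \code{"cv2"} or \code{"targets"}/\code{"cv3"}.
#' @param nFolds folds per repetition (default 10).
#' @param nReps number of repetitions (default 5).
#' @param seed RNG seed.
#' @param cv1Units for the pairs setting, partition \code{"all_pairs"}
#'   (default) or only the \code{"positives"}; in the latter case the
#'   interaction matrix is required.
#' @param M interaction matrix, needed only for
#'   \code{cv1Units = "positives"} when \code{x} is a dimension vector.
#' @return A [CVPlan].
#' @export
cvPlan <- function(x, setting = "pairs", nFolds = 10L, nReps = 5L,
                   seed = 1L, cv1Units = c("all_pairs", "positives"),
                   M = NULL) {
    setting <- .normalizeSetting(setting)
    cv1Units <- match.arg(cv1Units)
    if (is(x, "DTIData")) {
        dims <- dim(x)
        if (is.null(M)) M <- interactions(x)
    } else {
        dims <- as.integer(x)
    }
    d <- dims[1]; t <- dims[2]
    n <- switch(setting,
        pairs = if (cv1Units == "positives") {
            if (is.null(M)) stop("cv1Units = 'positives' requires M")
            sum(M == 1)
        } else d * t,
        drugs = d,
        targets = t)
    if (n < nFolds)
        stop(sprintf("too few units (%d) for %d folds", n, nFolds))
    unitPool <- if (setting == "pairs" && cv1Units == "positives")
        which(M == 1) else seq_len(n)
    folds <- .withSeed(seed, {
        lapply(seq_len(nReps), function(rep) {
            assign <- sample(rep_len(seq_len(nFolds), n))
            lapply(seq_len(nFolds), function(f) unitPool[assign == f])
        })
    })
    new("CVPlan",
        setting = setting,
        nFolds = as.integer(nFolds), nReps = as.integer(nReps),
        seed = as.integer(seed), dims = c(d, t), folds = folds,
        cv1Units = cv1Units)
}

#' Mask test units out of the training matrix
#'
#' Returns the training indicator A: the interaction matrix with the
#' test units zeroed. For the pairs setting the test entries are zeroed;
#' for drugs/targets, entire test rows/columns are zeroed (blinded).
#' Masking never creates 1s.
#'
#' @param x a [DTIData] or a binary interaction matrix.
#' @param testUnits integer indices of the test units (entry indices in
#'   column-major order, row indices, or column indices, per setting).
#' @param setting the CV setting (see [cvPlan()]).
#' @return The masked binary training matrix.
#' @export
maskTraining <- function(x, testUnits, setting = "pairs") {
    setting <- .normalizeSetting(setting)
    A <- if (is(x, "DTIData")) interactions(x) else x
    switch(setting,
        pairs = { A[testUnits] <- 0 },
        drugs = { A[testUnits, ] <- 0 },
        targets = { A[, testUnits] <- 0 })
    A
}

#' Precision-recall curve
#'
#' Computes the precision-recall points at every distinct score
#' threshold, in descending score order, with tied scores grouped at a
#' single threshold. The curve is anchored at recall 0 (with the
#' precision of the highest threshold) and ends at recall 1.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1 or logical), at least one of each
#'   class.
#' @return A data frame with columns \code{threshold}, \code{recall},
#'   \code{precision}.
#' @export
prCurve <- function(scores, labels) {
    labels <- as.numeric(labels)
    if (length(scores) != length(labels))
        stop("scores and labels differ in length")
    if (!.isBinary(labels))
        stop("labels must be binary")
    P <- sum(labels)
    if (P == 0 || P == length(labels))
        stop("labels must contain at least one positive and one negative")
    o <- order(scores, decreasing = TRUE)
    s <- scores[o]; y <- labels[o]
    ## last index of each tied group of scores
    grp <- cumsum(rle(s)$lengths)
    tp <- cumsum(y)[grp]
    np <- grp  # predictions made at each threshold
    recall <- tp / P
    precision <- tp / np
    data.frame(
        threshold = c(Inf, s[grp]),
        recall = c(0, recall),
        precision = c(precision[1], precision))
}

#' Area under the precision-recall curve
#'
#' Trapezoidal area over recall. A perfect ranking scores 1; the score
#' is invariant to strictly monotone transformations of the prediction
#' scores. \code{interpolation = "step"} instead uses the right-step
#' (non-interpolated) area sum(diff(recall) * precision).
#'
#' @param pr a curve from [prCurve()], or a numeric vector of scores
#'   (then \code{labels} must be given).
#' @param labels optional binary labels when \code{pr} is a score vector.
#' @param interpolation \code{"trapezoid"} (default) or \code{"step"}.
#' @return The area, in [0, 1].
#' @export
aupr <- function(pr, labels = NULL,
                 interpolation = c("trapezoid", "step")) {
    interpolation <- match.arg(interpolation)
    if (!is.null(labels)) pr <- prCurve(pr, labels)
    r <- pr$recall; p <- pr$precision
    if (interpolation == "trapezoid")
        sum(diff(r) * (p[-1] + p[-length(p)]) / 2)
    else
        sum(diff(r) * p[-1])
}

.testEntries <- function(testUnits, setting, dims) {
    d <- dims[1]; t <- dims[2]
    switch(setting,
        pairs = testUnits,
        drugs = as.vector(outer(testUnits, (seq_len(t) - 1) * d, "+")),
        targets = as.vector(outer(seq_len(d), (testUnits - 1) * d, "+")))
}

#' Run cross-validated evaluation
#'
#' For each repetition of the plan: every fold is left out in turn, the
#' model is fitted on the masked training matrix, the held-out entries
#' are scored, and all folds' (score, label) pairs are pooled into one
#' precision-recall curve and AUPR. Folds whose test entries contain no
#' positive are skipped with a warning (recorded in the details).
#'
#' For blinded drugs/targets the scores of a held-out row/column come
#' from the completed matrix itself; the graph smoothness term is what
#' propagates information into blinded rows and columns.
#'
#' @param x a [DTIData] with similarity matrices.
#' @param hp a [HyperParams] for the default scorer.
#' @param plan a [CVPlan] (built with [cvPlan()] if omitted).
#' @param scorer optional function(A, x) returning a d x t score matrix;
#'   defaults to fitting the completion model on A. Injecting a scorer
#'   replaces the model, e.g. with an oracle, for calibration checks.
#' @param knnK,rbfSigma graph preprocessing options passed to
#'   [fitLapMC()] by the default scorer.
#' @param ... passed to [cvPlan()] when \code{plan} is missing.
#' @return A [CVResult].
#' @export
runCV <- function(x, hp = hyperParams(), plan = NULL, scorer = NULL,
                  knnK = NULL, rbfSigma = NULL, ...) {
    if (is.null(plan))
        plan <- cvPlan(x, ...)
    M <- interactions(x)
    dims <- dim(M)
    if (is.null(scorer))
        scorer <- function(A, x)
            predictedScores(fitLapMC(A, drugSim(x), targetSim(x), hp = hp,
                                     knnK = knnK, rbfSigma = rbfSigma))
    perRep <- rep(NA_real_, plan@nReps)
    curves <- vector("list", plan@nReps)
    details <- list()
    for (rep in seq_len(plan@nReps)) {
        scores <- numeric(0); labels <- numeric(0)
        for (f in seq_len(plan@nFolds)) {
            testUnits <- plan@folds[[rep]][[f]]
            entries <- .testEntries(testUnits, plan@setting, dims)
            nPos <- sum(M[entries])
            rec <- list(rep = rep, fold = f,
                        nTest = length(entries), nPos = nPos,
                        skipped = FALSE)
            if (nPos == 0) {
                warning(sprintf(
                    "repetition %d fold %d has no positive test entries; skipped",
                    rep, f))
                rec$skipped <- TRUE
                details[[length(details) + 1L]] <- rec
                next
            }
            A <- maskTraining(M, testUnits, plan@setting)
            Xhat <- scorer(A, x)
            scores <- c(scores, Xhat[entries])
            labels <- c(labels, M[entries])
            details[[length(details) + 1L]] <- rec
        }
        curves[[rep]] <- prCurve(scores, labels)
        perRep[rep] <- aupr(curves[[rep]])
    }
    new("CVResult",
        setting = plan@setting,
        perRepetitionAUPR = perRep,
        meanAUPR = mean(perRep),
        sdAUPR = if (length(perRep) > 1) stats::sd(perRep) else 0,
        prCurves = curves,
        details = details)
}

setMethod("show", "CVResult", function(object) {
    cat(sprintf("CVResult (%s): AUPR %.3f +/- %.3f over %d repetitions\n",
                object@setting, object@meanAUPR, object@sdAUPR,
                length(object@perRepetitionAUPR)))
    cat("  per repetition:",
        paste(sprintf("%.3f", object@perRepetitionAUPR), collapse = " "),
        "\n")
})

#' Top-k predicted targets for a drug
#'
#' Ranks the targets of one drug by descending completed score,
#' optionally excluding interactions that were observed in training.
#' Ties are broken by lexicographic target identifier so rankings are
#' deterministic.
#'
#' @param x an [ALMFit] or a score matrix with dimnames.
#' @param drugId the drug identifier.
#' @param k number of targets to return.
#' @param excludeObserved optional binary training matrix; targets with
#'   an observed interaction for this drug are dropped before ranking.
#' @return A data frame with columns \code{rank}, \code{targetId},
#'   \code{score}.
#' @export
predictTopK <- function(x, drugId, k = 10L, excludeObserved = NULL) {
    X <- if (is(x, "ALMFit")) predictedScores(x) else x
    if (!drugId %in% rownames(X))
        stop("unknown drug: ", drugId)
    sc <- X[drugId, ]
    ids <- colnames(X)
    if (!is.null(excludeObserved)) {
        keep <- excludeObserved[drugId, ] == 0
        sc <- sc[keep]; ids <- ids[keep]
    }
    o <- order(-sc, ids)
    o <- o[seq_len(min(k, length(o)))]
    data.frame(rank = seq_along(o), targetId = ids[o], score = sc[o],
               row.names = NULL)
}
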