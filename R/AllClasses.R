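#' @import methods
NULL

.SYM_TOL <- 1e-8

.isBinary <- function(M) all(M == 0 | M == 1)

.checkSimilarity <- function(S, n, what) {
    msgs <- character(0)
    if (!is.matrix(S) || !is.numeric(S))
        return(sprintf("%s must be a numeric matrix", what))
    if (nrow(S) != n || ncol(S) != n)
        msgs <- c(msgs, sprintf("%s must be %d x %d", what, n, n))
    else {
        if (any(!is.finite(S)))
            msgs <- c(msgs, sprintf("%s contains non-finite values", what))
        else {
            if (max(abs(S - t(S))) > .SYM_TOL)
                msgs <- c(msgs, sprintf("%s is not symmetric", what))
            if (min(S) < -.SYM_TOL || max(S) > 1 + .SYM_TOL)
                msgs <- c(msgs, sprintf("%s entries must lie in [0, 1]", what))
            if (n > 0 && max(abs(diag(S) - 1)) > .SYM_TOL)
                msgs <- c(msgs, sprintf("%s diagonal must equal 1", what))
        }
    }
    msgs
}

#' DTIData: a drug-target interaction dataset
#'
#' Holds a binary drug-target interaction matrix together with a drug-drug
#' chemical-structure similarity matrix and a target-target sequence
#' similarity matrix, all aligned to ordered drug and target identifier
#' lists. The similarity matrices may be absent (0 x 0) for a partially
#' constructed dataset, e.g. straight after reading an interaction table.
#'
#' Validity enforces: interaction entries are exactly 0 or 1; similarity
#' matrices (when present) are symmetric within 1e-8, have entries in
#' [0, 1] and unit diagonal; dimensions agree with the identifier lists.
#'
#' @slot drugIds character vector of unique drug identifiers (row order).
#' @slot targetIds character vector of unique target identifiers
#'   (column order).
#' @slot interactions d x t binary matrix; 1 marks an experimentally
#'   validated interaction.
#' @slot drugSim d x d drug-drug similarity matrix (or 0 x 0 if unset).
#' @slot targetSim t x t target-target similarity matrix (or 0 x 0 if
#'   unset).
#'
#' @seealso [DTIData()] for the user constructor, [readInteractions()],
#'   [readSimilarity()], [datasetStats()].
#' @export
setClass("DTIData",
    slots = c(
        drugIds = "character",
        targetIds = "character",
        interactions = "matrix",
        drugSim = "matrix",
        targetSim = "matrix"
    ),
    prototype = prototype(
        drugIds = character(0),
        targetIds = character(0),
        interactions = matrix(0, 0, 0),
        drugSim = matrix(0, 0, 0),
        targetSim = matrix(0, 0, 0)
    )
)

setValidity("DTIData", function(object) {
    msgs <- character(0)
    M <- object@interactions
    d <- length(object@drugIds)
    t <- length(object@targetIds)
    if (anyDuplicated(object@drugIds))
        msgs <- c(msgs, "drug identifiers must be unique")
    if (anyDuplicated(object@targetIds))
        msgs <- c(msgs, "target identifiers must be unique")
    if (nrow(M) != d || ncol(M) != t)
        msgs <- c(msgs, "interaction matrix dimensions do not match the identifier lists")
    if (length(M) && !.isBinary(M))
        msgs <- c(msgs, "interaction matrix entries must be exactly 0 or 1")
    if (length(object@drugSim))
        msgs <- c(msgs, .checkSimilarity(object@drugSim, d, "drugSim"))
    if (length(object@targetSim))
        msgs <- c(msgs, .checkSimilarity(object@targetSim, t, "targetSim"))
    if (length(msgs)) msgs else TRUE
})

#' LaplacianPair: drug and target graph Laplacians
#'
#' The pair of unnormalized graph Laplacians L = D - W built from the drug
#' and target similarity matrices, used as the dual smoothness regularizer
#' of the completion objective. Degrees are D(i,i) = sum_j W(i,j),
#' including the unit self-similarity, which contributes nothing to the
#' quadratic form.
#'
#' @slot drugLaplacian d x d symmetric Laplacian over the drug graph.
#' @slot targetLaplacian t x t symmetric Laplacian over the target graph.
#' @slot drugDegrees,targetDegrees the diagonal of the degree matrices.
#' @slot source provenance tag, one of \code{"dense_similarity"} or
#'   \code{"knn_sparsified"}.
#' @seealso [laplacianPair()], [buildLaplacian()]
#' @export
setClass("LaplacianPair",
    slots = c(
        drugLaplacian = "matrix",
        targetLaplacian = "matrix",
        drugDegrees = "numeric",
        targetDegrees = "numeric",
        source = "character"
    )
)

.checkLaplacian <- function(L, what) {
    msgs <- character(0)
    if (nrow(L) != ncol(L))
        return(sprintf("%s must be square", what))
    if (length(L)) {
        if (max(abs(L - t(L))) > .SYM_TOL)
            msgs <- c(msgs, sprintf("%s is not symmetric", what))
        if (max(abs(rowSums(L))) > 1e-10 * max(1, max(abs(L))))
            msgs <- c(msgs, sprintf("%s rows do not sum to zero", what))
    }
    msgs
}

setValidity("LaplacianPair", function(object) {
    msgs <- c(
        .checkLaplacian(object@drugLaplacian, "drugLaplacian"),
        .checkLaplacian(object@targetLaplacian, "targetLaplacian")
    )
    if (length(object@drugDegrees) != nrow(object@drugLaplacian))
        msgs <- c(msgs, "drugDegrees length mismatch")
    if (length(object@targetDegrees) != nrow(object@targetLaplacian))
        msgs <- c(msgs, "targetDegrees length mismatch")
    if (!object@source %in% c("dense_similarity", "knn_sparsified"))
        msgs <- c(msgs, "source must be 'dense_similarity' or 'knn_sparsified'")
    if (length(msgs)) msgs else TRUE
})

#' HyperParams: regularization weights and solver controls
#'
#' The three regularization weights of the completion objective and the
#' controls of the augmented Lagrange multiplier solver.
#'
#' @slot alpha Tikhonov (ridge) weight on the score matrix, >= 0.
#' @slot beta fidelity weight preserving observed interactions, >= 0.
#' @slot lambda dual Laplacian smoothness weight, >= 0.
#' @slot mu1Init,mu2Init initial penalty parameters (> 0) for the two
#'   auxiliary-variable constraints.
#' @slot rho penalty growth factor per iteration (>= 1).
#' @slot muMax penalty cap.
#' @slot tol convergence tolerance on the primal residuals (max norm).
#' @slot maxIter iteration cap.
#' @slot seed carried for API uniformity; the solver is deterministic.
#' @seealso [hyperParams()], [fitLapMC()]
#' @export
setClass("HyperParams",
    slots = c(
        alpha = "numeric", beta = "numeric", lambda = "numeric",
        mu1Init = "numeric", mu2Init = "numeric",
        rho = "numeric", muMax = "numeric",
        tol = "numeric", maxIter = "integer", seed = "integer"
    )
)

setValidity("HyperParams", function(object) {
    msgs <- character(0)
    w <- c(alpha = object@alpha, beta = object@beta, lambda = object@lambda)
    if (any(!is.finite(w)) || any(w < 0))
        msgs <- c(msgs, "alpha, beta and lambda must be finite and >= 0")
    if (object@mu1Init <= 0 || object@mu2Init <= 0)
        msgs <- c(msgs, "initial penalties must be > 0")
    if (object@rho < 1)
        msgs <- c(msgs, "rho must be >= 1")
    if (object@tol <= 0)
        msgs <- c(msgs, "tol must be > 0")
    if (object@maxIter < 1L)
        msgs <- c(msgs, "maxIter must be >= 1")
    if (length(msgs)) msgs else TRUE
})

#' ALMFit: state and result of the augmented Lagrangian solver
#'
#' Carries the completed score matrix X alongside the auxiliary variables,
#' Lagrange multipliers, penalties and convergence traces of the solver.
#' The score matrix is the prediction: candidate interactions are ranked
#' by its entries in descending order.
#'
#' @slot X completed d x t score matrix (the prediction).
#' @slot J nuclear-norm auxiliary variable.
#' @slot Z fidelity auxiliary variable.
#' @slot Y1,Y2 Lagrange multiplier matrices.
#' @slot mu1,mu2 final penalty values.
#' @slot iterations number of iterations performed.
#' @slot converged TRUE if both primal residuals fell below the tolerance.
#' @slot primalResiduals iterations x 2 matrix of max-norm residuals
#'   (X - J and X - Z) per iteration.
#' @slot objectiveTrace objective value per iteration.
#' @slot drugIds,targetIds identifier lists aligned to the rows/columns
#'   of X.
#' @seealso [fitLapMC()], [predictedScores()], [predictTopK()]
#' @export
setClass("ALMFit",
    slots = c(
        X = "matrix", J = "matrix", Z = "matrix",
        Y1 = "matrix", Y2 = "matrix",
        mu1 = "numeric", mu2 = "numeric",
        iterations = "integer", converged = "logical",
        primalResiduals = "matrix", objectiveTrace = "numeric",
        drugIds = "character", targetIds = "character"
    )
)

#' CVPlan: a seeded cross-validation plan
#'
#' A reproducible partition of the evaluation units into folds, for a
#' number of independent repetitions. Units depend on the setting:
#' blinded pairs partition matrix entries, blinded drugs partition rows
#' and blinded targets partition columns.
#'
#' @slot setting one of \code{"pairs"} (CV on drug-target pairs),
#'   \code{"drugs"} (whole rows held out) or \code{"targets"} (whole
#'   columns held out).
#' @slot nFolds,nReps folds per repetition, number of repetitions.
#' @slot seed RNG seed the plan was generated from.
#' @slot dims c(d, t) of the dataset the plan indexes.
#' @slot folds list (one per repetition) of lists (one per fold) of
#'   integer unit indices; pair units are column-major entry indices.
#' @slot cv1Units for the pairs setting, whether all d*t pairs or only
#'   the positive entries were partitioned.
#' @seealso [cvPlan()], [runCV()]
#' @export
setClass("CVPlan",
    slots = c(
        setting = "character",
        nFolds = "integer", nReps = "integer", seed = "integer",
        dims = "integer", folds = "list", cv1Units = "character"
    )
)

setValidity("CVPlan", function(object) {
    msgs <- character(0)
    if (!object@setting %in% c("pairs", "drugs", "targets"))
        msgs <- c(msgs, "setting must be 'pairs', 'drugs' or 'targets'")
    if (length(object@folds) != object@nReps)
        msgs <- c(msgs, "folds must hold one partition per repetition")
    for (rep in object@folds) {
        units <- sort(unlist(rep))
        n <- length(units)
        if (anyDuplicated(units))
            msgs <- c(msgs, "folds within a repetition must be disjoint")
        if (n && !identical(units, seq_len(max(units))) && !all(diff(units) >= 1))
            msgs <- c(msgs, "fold units must be unique indices")
        sizes <- lengths(rep)
        if (length(sizes) && diff(range(sizes)) > 1)
            msgs <- c(msgs, "fold sizes must differ by at most 1")
    }
    if (length(msgs)) unique(msgs) else TRUE
})

#' CVResult: cross-validation scores and curves
#'
#' @slot setting the cross-validation setting evaluated.
#' @slot perRepetitionAUPR one pooled AUPR per repetition.
#' @slot meanAUPR,sdAUPR mean and standard deviation over repetitions.
#' @slot prCurves list of per-repetition precision-recall curves
#'   (data frames with threshold, recall, precision).
#' @slot details per-fold bookkeeping (positives per fold, skipped folds).
#' @seealso [runCV()]
#' @export
setClass("CVResult",
    slots = c(
        setting = "character",
        perRepetitionAUPR = "numeric",
        meanAUPR = "numeric", sdAUPR = "numeric",
        prCurves = "list", details = "list"
    )
)

setValidity("CVResult", function(object) {
    msgs <- character(0)
    a <- object@perRepetitionAUPR
    if (length(a) && (any(a < 0) || any(a > 1)))
        msgs <- c(msgs, "AUPR values must lie in [0, 1]")
    if (length(a) && abs(object@meanAUPR - mean(a)) > 1e-12)
        msgs <- c(msgs, "meanAUPR inconsistent with per-repetition values")
    if (length(msgs)) msgs else TRUE
})

#' SyntheticDTI: a synthetic dataset with known ground truth
#'
#' A generated [DTIData] whose interaction pattern is the thresholding of
#' a noisy low-rank score matrix, plus the latent factors and true scores
#' that produced it.
#'
#' @slot data the generated [DTIData] (interactions and similarities).
#' @slot trueScores the underlying real-valued d x t score matrix U V'.
#' @slot U,V latent factor matrices (d x r and t x r).
#' @slot params the generator parameters, as a named list.
#' @seealso [simulateDTI()], [recoveryExperiment()]
#' @export
setClass("SyntheticDTI",
    slots = c(
        data = "DTIData",
        trueScores = "matrix",
        U = "matrix", V = "matrix",
        params = "list"
    )
)
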