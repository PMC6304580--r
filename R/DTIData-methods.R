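#' Construct a drug-target interaction dataset
#'
#' Builds a [DTIData] from a binary interaction matrix and (optionally)
#' the two similarity matrices. Identifier lists default to the dimnames
#' of the interaction matrix.
#'
#' @param interactions d x t binary matrix (entries exactly 0/1).
#' @param drugSim,targetSim optional similarity matrices (d x d, t x t);
#'   symmetric within 1e-8, entries in [0, 1], unit diagonal.
#' @param drugIds,targetIds identifier character vectors; default to the
#'   row/column names of \code{interactions}.
#' @return A validated [DTIData] object.
#' @examples
#' M <- matrix(c(1, 0, 0, 1), 2, 2,
#'             dimnames = list(c("d1", "d2"), c("t1", "t2")))
#' DTIData(M)
#' @export
DTIData <- function(interactions, drugSim = NULL, targetSim = NULL,
                    drugIds = rownames(interactions),
                    targetIds = colnames(interactions)) {
    if (is.null(drugIds))
        drugIds <- sprintf("drug%d", seq_len(nrow(interactions)))
    if (is.null(targetIds))
        targetIds <- sprintf("target%d", seq_len(ncol(interactions)))
    interactions <- as.matrix(interactions)
    storage.mode(interactions) <- "double"
    dimnames(interactions) <- list(drugIds, targetIds)
    if (is.null(drugSim)) drugSim <- matrix(0, 0, 0)
    else dimnames(drugSim) <- list(drugIds, drugIds)
    if (is.null(targetSim)) targetSim <- matrix(0, 0, 0)
    else dimnames(targetSim) <- list(targetIds, targetIds)
    new("DTIData",
        drugIds = as.character(drugIds),
        targetIds = as.character(targetIds),
        interactions = interactions,
        drugSim = drugSim, targetSim = targetSim)
}

#' Accessors for DTIData
#'
#' @param x a [DTIData] object.
#' @param value a replacement similarity matrix.
#' @return \code{drugIds}/\code{targetIds} return character vectors;
#'   \code{interactions}, \code{drugSim}, \code{targetSim} return
#'   matrices; \code{observedPairs} returns a two-column integer matrix
#'   of (drug, target) indices with an observed interaction.
#' @name DTIData-accessors
NULL

#' @rdname DTIData-accessors
#' @export
setMethod("drugIds", "DTIData", function(x) x@drugIds)

#' @rdname DTIData-accessors
#' @export
setMethod("targetIds", "DTIData", function(x) x@targetIds)

#' @rdname DTIData-accessors
#' @export
setMethod("interactions", "DTIData", function(x) x@interactions)

#' @rdname DTIData-accessors
#' @export
setMethod("drugSim", "DTIData", function(x) x@drugSim)

#' @rdname DTIData-accessors
#' @export
setMethod("targetSim", "DTIData", function(x) x@targetSim)

#' @rdname DTIData-accessors
#' @export
setReplaceMethod("drugSim", "DTIData", function(x, value) {
    dimnames(value) <- list(x@drugIds, x@drugIds)
    x@drugSim <- value
    validObject(x)
    x
})

#' @rdname DTIData-accessors
#' @export
setReplaceMethod("targetSim", "DTIData", function(x, value) {
    dimnames(value) <- list(x@targetIds, x@targetIds)
    x@targetSim <- value
    validObject(x)
    x
})

#' @rdname DTIData-accessors
#' @export
setMethod("observedPairs", "DTIData", function(x) {
    which(x@interactions == 1, arr.ind = TRUE, useNames = FALSE)
})

#' @describeIn DTIData-accessors number of drugs and targets.
#' @export
setMethod("dim", "DTIData", function(x) dim(x@interactions))

setMethod("show", "DTIData", function(object) {
    M <- object@interactions
    cat(sprintf("DTIData: %d drugs x %d targets, %d observed interactions\n",
                nrow(M), ncol(M), sum(M)))
    if (length(M))
        cat(sprintf("  sparsity: %.2f%%\n", 100 * (1 - sum(M) / length(M))))
    cat(sprintf("  drug similarity: %s\n",
                if (length(object@drugSim)) "present" else "absent"))
    cat(sprintf("  target similarity: %s\n",
                if (length(object@targetSim)) "present" else "absent"))
})

## round half away from zero, the convention used for reported statistics
.round2 <- function(x, digits = 2) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Summary statistics of an interaction dataset
#'
#' Computes the descriptive statistics customarily reported for
#' drug-target interaction benchmarks: counts of drugs, targets and
#' interactions; average number of interacting drugs per target and
#' targets per drug; sparsity of the interaction matrix; and the
#' percentage of drugs (targets) with exactly one interaction. Ratios are
#' rounded half-away-from-zero to two decimals, the precision these
#' statistics are conventionally printed at.
#'
#' @param x a [DTIData] object.
#' @param ... unused.
#' @return A one-row data frame with columns \code{nDrugs},
#'   \code{nTargets}, \code{nInteractions}, \code{drugsPerTarget},
#'   \code{targetsPerDrug}, \code{sparsity},
#'   \code{pctDrugsOneInteraction}, \code{pctTargetsOneInteraction}.
#' @examples
#' set.seed(1)
#' M <- matrix(0, 54, 26)
#' M[sample(length(M), 90)] <- 1
#' datasetStats(DTIData(M))  # sparsity 93.59
#' @export
setMethod("datasetStats", "DTIData", function(x, ...) {
    M <- x@interactions
    d <- nrow(M); t <- ncol(M)
    if (d == 0 || t == 0)
        stop("dataset has no drugs or no targets")
    nE <- sum(M)
    data.frame(
        nDrugs = d,
        nTargets = t,
        nInteractions = nE,
        drugsPerTarget = .round2(nE / t),
        targetsPerDrug = .round2(nE / d),
        sparsity = .round2(100 * (1 - nE / (d * t))),
        pctDrugsOneInteraction = .round2(100 * mean(rowSums(M) == 1)),
        pctTargetsOneInteraction = .round2(100 * mean(colSums(M) == 1))
    )
})
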