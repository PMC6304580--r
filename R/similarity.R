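## Similarity construction from raw representations: Jaccard overlap of
## drug substructure/fingerprint sets, and normalized Smith-Waterman local
## alignment scores for target protein sequences. The exact local
## alignment DP is delegated to Biostrings; intended for small/medium
## inputs (no heuristic prefiltering).

#' Jaccard similarity of two substructure sets
#'
#' |a intersect b| / |a union b|, the set-overlap score used for chemical
#' substructure/fingerprint comparison. Two empty sets are defined as
#' identical (similarity 1); an empty set against a non-empty one scores
#' 0.
#'
#' @param a,b vectors of substructure/fingerprint tokens; duplicates are
#'   ignored (set semantics).
#' @return A score in [0, 1].
#' @examples
#' jaccardSimilarity(c(1, 2, 3), c(2, 3, 4))  # 0.5
#' @export
jaccardSimilarity <- function(a, b) {
    a <- unique(a); b <- unique(b)
    if (!length(a) && !length(b)) return(1)
    length(intersect(a, b)) / length(union(a, b))
}

.DEFAULT_GAP_OPEN <- 10
.DEFAULT_GAP_EXTEND <- 1

.asAAString <- function(x) {
    if (is(x, "AAString")) return(x)
    x <- toupper(as.character(x))
    if (!nzchar(x)) stop("empty sequence")
    Biostrings::AAString(x)
}

.substMatrix <- function(substitutionMatrix) {
    if (is.matrix(substitutionMatrix)) return(substitutionMatrix)
    ## named matrices shipped with Biostrings (BLOSUM62, PAM250, ...)
    get(utils::data(list = substitutionMatrix,
                    package = "Biostrings",
                    envir = environment())[1L], envir = environment())
}

#' Smith-Waterman local alignment score
#'
#' Optimal local alignment score of two amino-acid sequences under affine
#' gap penalties (a gap of length L costs gapOpening + L * gapExtension),
#' computed by exact dynamic programming. The score is symmetric in its
#' arguments and never negative; the self-score of a non-empty sequence
#' is positive.
#'
#' @param g,gPrime sequences (character strings or \code{AAString}).
#' @param substitutionMatrix a scoring matrix or the name of one shipped
#'   with Biostrings; default \code{"BLOSUM62"}.
#' @param gapOpening,gapExtension affine gap parameters; defaults 10 / 1.
#' @return The nonnegative optimal local alignment score.
#' @export
smithWaterman <- function(g, gPrime, substitutionMatrix = "BLOSUM62",
                          gapOpening = .DEFAULT_GAP_OPEN,
                          gapExtension = .DEFAULT_GAP_EXTEND) {
    s <- Biostrings::pairwiseAlignment(
        .asAAString(g), .asAAString(gPrime), type = "local",
        substitutionMatrix = .substMatrix(substitutionMatrix),
        gapOpening = gapOpening, gapExtension = gapExtension,
        scoreOnly = TRUE)
    max(0, s)
}

#' Normalized Smith-Waterman similarity
#'
#' SW(g, g') / sqrt(SW(g, g) * SW(g', g')): the local alignment score
#' normalized by the geometric mean of the self-alignment scores, so that
#' the self-similarity is exactly 1. Values exceeding 1 (possible only
#' under exotic scoring schemes) are clipped to 1 with a warning.
#'
#' @inheritParams smithWaterman
#' @return A score in [0, 1].
#' @export
normalizedSW <- function(g, gPrime, substitutionMatrix = "BLOSUM62",
                         gapOpening = .DEFAULT_GAP_OPEN,
                         gapExtension = .DEFAULT_GAP_EXTEND) {
    sm <- .substMatrix(substitutionMatrix)
    sgg <- smithWaterman(g, g, sm, gapOpening, gapExtension)
    shh <- smithWaterman(gPrime, gPrime, sm, gapOpening, gapExtension)
    if (sgg <= 0 || shh <= 0)
        stop("zero self-alignment score; cannot normalize")
    s <- smithWaterman(g, gPrime, sm, gapOpening, gapExtension) /
        sqrt(sgg * shh)
    if (s > 1) {
        warning(sprintf("normalized score %.6g exceeds 1; clipping", s))
        s <- 1
    }
    s
}

#' Pairwise similarity matrix from raw records
#'
#' Applies a pairwise scorer to every pair of records and assembles the
#' symmetric similarity matrix with unit diagonal expected by the
#' completion model. For \code{method = "jaccard"}, \code{records} is a
#' named list of token vectors (substructure sets); for \code{method =
#' "sw"}, a named character vector or \code{AAStringSet} of protein
#' sequences, scored by [normalizedSW()].
#'
#' @param records named list/vector of records with unique names.
#' @param method \code{"jaccard"} or \code{"sw"}.
#' @param ... passed on to the scorer (e.g. \code{substitutionMatrix}).
#' @return A symmetric matrix in [0, 1] with unit diagonal, dimnames set
#'   to the record names; it satisfies the [DTIData] similarity contract
#'   unmodified.
#' @export
similarityMatrix <- function(records, method = c("jaccard", "sw"), ...) {
    method <- match.arg(method)
    ids <- names(records)
    if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
        stop("records must have unique non-empty names")
    n <- length(records)
    S <- diag(1, n)
    dimnames(S) <- list(ids, ids)
    if (n < 2) return(S)
    scorer <- switch(method,
        jaccard = function(a, b) jaccardSimilarity(a, b),
        sw = function(a, b) normalizedSW(a, b, ...))
    recs <- if (is(records, "XStringSet")) as.character(records) else records
    for (i in seq_len(n - 1)) {
        for (j in seq(i + 1, n)) {
            S[i, j] <- S[j, i] <- scorer(recs[[i]], recs[[j]])
        }
    }
    S
}

#' Read substructure/fingerprint sets from JSON
#'
#' Expects a JSON object mapping drug identifiers to arrays of
#' substructure tokens.
#'
#' @param path path to the JSON file.
#' @return A named list of character vectors.
#' @export
readSubstructureSets <- function(path) {
    x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    if (!is.list(x) || is.null(names(x)))
        stop("expected a JSON object mapping drug IDs to token arrays")
    lapply(x, as.character)
}

#' Read protein sequences from FASTA
#'
#' Thin wrapper over \code{Biostrings::readAAStringSet} that uppercases
#' sequences and uses the first whitespace-delimited word of each header
#' as the identifier.
#'
#' @param path path to a FASTA file.
#' @return An \code{AAStringSet} with unique names.
#' @export
readSequences <- function(path) {
    x <- Biostrings::readAAStringSet(path)
    names(x) <- vapply(strsplit(names(x), "\\s+"), `[[`, "", 1L)
    if (anyDuplicated(names(x)))
        stop("duplicate sequence identifiers in ", path)
    Biostrings::AAStringSet(toupper(x))
}
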