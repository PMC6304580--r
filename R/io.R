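## Readers and writers for the labeled-table dialects used by public
## drug-target interaction benchmarks: a rectangular 0/1 matrix with target
## IDs as header and drug IDs as first column, and a two-column pair list.

#' Read a drug-target interaction table
#'
#' Reads a binary interaction matrix in one of two dialects.
#' \code{"matrix"} is a labeled rectangular table: a header row of target
#' identifiers (first cell blank or a label such as \code{"drug"}), then
#' one row per drug whose first field is the drug identifier and whose
#' remaining fields are 0/1. \code{"pairs"} is a two-column
#' \code{drug_id, target_id} list (comma or tab separated), each line one
#' observed interaction; duplicated pairs collapse to a single 1.
#'
#' Identifier order is defined by first appearance in the file.
#'
#' @param path path to the file.
#' @param dialect \code{"matrix"} or \code{"pairs"}.
#' @param sep field separator; defaults to tab for \code{"matrix"} and
#'   auto-detected (comma or tab) for \code{"pairs"}.
#' @return A [DTIData] with interactions and identifiers only (no
#'   similarity matrices).
#' @seealso [writeInteractions()], [readSimilarity()]
#' @export
readInteractions <- function(path, dialect = c("matrix", "pairs"), sep = NULL) {
    dialect <- match.arg(dialect)
    if (!file.exists(path))
        stop("file not found: ", path)
    if (file.size(path) == 0)
        stop("empty interaction file: ", path)
    if (dialect == "matrix") {
        if (is.null(sep)) sep <- "\t"
        tab <- utils::read.table(path, header = TRUE, sep = sep,
                                 row.names = NULL, check.names = FALSE,
                                 colClasses = "character",
                                 stringsAsFactors = FALSE)
        if (ncol(tab) < 2)
            stop("interaction matrix must have at least one target column")
        drugs <- tab[[1]]
        targets <- colnames(tab)[-1]
        M <- as.matrix(tab[, -1, drop = FALSE])
        suppressWarnings(storage.mode(M) <- "double")
        badmat <- is.na(M) | !(M == 0 | M == 1)
        badmat[is.na(badmat)] <- TRUE
        bad <- which(badmat, arr.ind = TRUE)
        if (nrow(bad)) {
            stop(sprintf(
                "non-binary cell at drug '%s', target '%s' in %s",
                drugs[bad[1, 1]], targets[bad[1, 2]], path))
        }
        if (anyDuplicated(drugs)) {
            dup <- unique(drugs[duplicated(drugs)])
            for (id in dup) {
                rows <- M[drugs == id, , drop = FALSE]
                if (nrow(unique(rows)) > 1)
                    stop("duplicate drug '", id, "' with conflicting rows")
            }
            keep <- !duplicated(drugs)
            M <- M[keep, , drop = FALSE]
            drugs <- drugs[keep]
        }
        if (anyDuplicated(targets))
            stop("duplicate target identifiers in header")
        dimnames(M) <- list(drugs, targets)
        DTIData(M)
    } else {
        lines <- readLines(path, warn = FALSE)
        lines <- lines[nzchar(trimws(lines))]
        if (!length(lines))
            stop("empty pair list: ", path)
        if (is.null(sep))
            sep <- if (grepl("\t", lines[[1]])) "\t" else ","
        parts <- strsplit(lines, sep, fixed = TRUE)
        if (any(lengths(parts) < 2))
            stop("pair list lines must have two fields: drug", sep, "target")
        dcol <- trimws(vapply(parts, `[[`, "", 1L))
        tcol <- trimws(vapply(parts, `[[`, "", 2L))
        ## tolerate a header line
        if (tolower(dcol[1]) %in% c("drug", "drug_id", "drugid") ||
            tolower(tcol[1]) %in% c("target", "target_id", "targetid")) {
            dcol <- dcol[-1]; tcol <- tcol[-1]
        }
        if (!length(dcol))
            stop("pair list contains no data rows: ", path)
        drugs <- unique(dcol)
        targets <- unique(tcol)
        M <- matrix(0, length(drugs), length(targets),
                    dimnames = list(drugs, targets))
        M[cbind(match(dcol, drugs), match(tcol, targets))] <- 1
        DTIData(M)
    }
}

#' Write an interaction matrix as a labeled table
#'
#' Writes the \code{"matrix"} dialect understood by [readInteractions()]:
#' tab-separated, header of target identifiers, one row per drug.
#'
#' @param x a [DTIData] or a matrix with dimnames.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeInteractions <- function(x, path) {
    M <- if (is(x, "DTIData")) interactions(x) else x
    .writeLabeledMatrix(M, path, first = "drug", fmt = "%.0f")
    invisible(path)
}

.writeLabeledMatrix <- function(M, path, first = "", fmt = "%.17g") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(c(first, colnames(M)), collapse = "\t"), con)
    body <- apply(M, 1L, function(r) paste(sprintf(fmt, r), collapse = "\t"))
    writeLines(paste(rownames(M), body, sep = "\t"), con)
}

#' Read a labeled similarity matrix
#'
#' Reads a labeled square similarity table and normalizes it to the
#' package's similarity contract: the matrix is reindexed to
#' \code{expectedIds} order, symmetrized as (S + S')/2 (similarity files
#' may carry rounding asymmetry), entries clipped to [0, 1] and the
#' diagonal forced to 1. Loading an already-conformant matrix returns it
#' unchanged.
#'
#' @param path path to a tab-separated labeled square matrix.
#' @param expectedIds identifiers to select and order by; the file's IDs
#'   must be a superset.
#' @return A numeric matrix indexed by \code{expectedIds}.
#' @export
readSimilarity <- function(path, expectedIds = NULL) {
    if (!file.exists(path))
        stop("file not found: ", path)
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             row.names = 1, check.names = FALSE,
                             stringsAsFactors = FALSE)
    S <- as.matrix(tab)
    storage.mode(S) <- "double"
    if (nrow(S) != ncol(S))
        stop("similarity matrix is not square: ", path)
    if (any(is.na(S)))
        stop("NaN/NA cell in similarity matrix: ", path)
    if (is.null(expectedIds)) expectedIds <- rownames(S)
    missing <- setdiff(expectedIds, rownames(S))
    missing <- union(missing, setdiff(expectedIds, colnames(S)))
    if (length(missing))
        stop("similarity matrix is missing identifiers: ",
             paste(missing, collapse = ", "))
    S <- S[expectedIds, expectedIds, drop = FALSE]
    S <- (S + t(S)) / 2
    S[S < 0] <- 0
    S[S > 1] <- 1
    diag(S) <- 1
    S
}

#' Write a labeled similarity matrix
#'
#' @param S square numeric matrix with dimnames.
#' @param path output path (tab-separated).
#' @return \code{path}, invisibly.
#' @export
writeSimilarity <- function(S, path) {
    .writeLabeledMatrix(S, path, first = "id")
    invisible(path)
}
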