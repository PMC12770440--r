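#' @include AllGenerics.R
NULL

#' Pareto dominance predicate (canonical minimize orientation)
#'
#' \code{x} dominates \code{y} when \code{x} is equal or better in every
#' objective and strictly better in at least one, with smaller meaning
#' better. The predicate is deliberately exact: no floating-point
#' tolerance, since endpoint deltas are small integers/halves and a
#' tolerance would create artifacts.
#'
#' @param x,y numeric vectors of equal length, finite.
#' @return logical scalar.
#' @examples
#' dominates(c(-5, -2, -2), c(-1, -1, -1))  # TRUE
#' dominates(c(-5, 0), c(0, -5))            # FALSE (conflicting)
#' @export
dominates <- function(x, y) {
    if (length(x) != length(y))
        stop("objective vectors must have equal length")
    if (!all(is.finite(x)) || !all(is.finite(y)))
        stop("objective vectors must be finite")
    all(x <= y) && any(x < y)
}

.objValues <- function(x) {
    if (is(x, "ObjectiveMatrix")) x@values
    else if (is.matrix(x) && is.numeric(x)) x
    else stop("need an ObjectiveMatrix or a numeric matrix")
}

.fastNondominatedSort <- function(vals) {
    n <- nrow(vals)
    if (n == 0L) stop("empty objective matrix")
    if (any(!is.finite(vals))) stop("objective matrix must be finite")
    m <- ncol(vals)
    # D[i, j] TRUE iff row i dominates row j (count-based fast sort)
    allLE <- outer(vals[, 1L], vals[, 1L], `<=`)
    anyLT <- outer(vals[, 1L], vals[, 1L], `<`)
    if (m > 1L) for (k in 2:m) {
        allLE <- allLE & outer(vals[, k], vals[, k], `<=`)
        anyLT <- anyLT | outer(vals[, k], vals[, k], `<`)
    }
    D <- allLE & anyLT
    ndom <- colSums(D)
    front <- integer(n)
    f <- 0L
    while (any(front == 0L)) {
        f <- f + 1L
        idx <- which(front == 0L & ndom == 0L)
        front[idx] <- f
        ndom <- ndom - colSums(D[idx, , drop = FALSE])
        ndom[front > 0L] <- .Machine$integer.max
    }
    ids <- rownames(vals)
    if (is.null(ids)) ids <- as.character(seq_len(n))
    names(front) <- ids
    new("FrontAssignment", front = front, nFronts = f)
}

#' @rdname nondominatedSort
#' @export
setMethod("nondominatedSort", "ObjectiveMatrix",
          function(x, ...) .fastNondominatedSort(x@values))

#' @rdname nondominatedSort
#' @export
setMethod("nondominatedSort", "matrix",
          function(x, ...) .fastNondominatedSort(x))

#' Brute-force Pareto front (verification oracle)
#'
#' Quadratic scan with no shortcuts: returns exactly the rows not dominated
#' by any other row. Kept separate from [nondominatedSort()] so the two
#' routes can be cross-checked.
#'
#' @param x an \linkS4class{ObjectiveMatrix} or numeric matrix (canonical
#'   minimize orientation).
#' @return character vector of row ids on front 1.
#' @export
paretoFrontOracle <- function(x) {
    vals <- .objValues(x)
    n <- nrow(vals)
    if (n == 0L) stop("empty objective matrix")
    ids <- rownames(vals)
    if (is.null(ids)) ids <- as.character(seq_len(n))
    keep <- logical(n)
    for (i in seq_len(n)) {
        dominated <- FALSE
        for (j in seq_len(n)) {
            if (j != i && dominates(vals[j, ], vals[i, ])) {
                dominated <- TRUE
                break
            }
        }
        keep[i] <- !dominated
    }
    ids[keep]
}

#' @rdname frontNumbers
#' @export
setMethod("frontNumbers", "FrontAssignment", function(x) x@front)

#' @rdname nFronts
#' @export
setMethod("nFronts", "FrontAssignment", function(x) x@nFronts)

#' Front sizes summary
#' @param x a \linkS4class{FrontAssignment}.
#' @return integer vector of length \code{nFronts(x)}; element k is |Fk|.
#' @export
frontSizes <- function(x) {
    stopifnot(is(x, "FrontAssignment"))
    as.integer(table(factor(x@front, levels = seq_len(x@nFronts))))
}

#' Write a front assignment as CSV plus JSON summary
#' @param x a \linkS4class{FrontAssignment}.
#' @param path CSV output path (columns patient_id, front_number).
#' @param summaryPath optional JSON path recording w and front sizes.
#' @return \code{path}, invisibly.
#' @export
writeFronts <- function(x, path, summaryPath = NULL) {
    stopifnot(is(x, "FrontAssignment"))
    df <- data.frame(patient_id = names(x@front),
                     front_number = unname(x@front))
    df <- df[order(df$front_number, df$patient_id), , drop = FALSE]
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    if (!is.null(summaryPath))
        jsonlite::write_json(list(w = x@nFronts, front_sizes = frontSizes(x)),
                             summaryPath, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
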