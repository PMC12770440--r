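# independent verification oracles, deliberately brute-force

# iterative peeling using only the quadratic-scan front oracle
peelOracleFronts <- function(vals) {
    ids <- rownames(vals)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(vals)))
    rownames(vals) <- ids
    front <- integer(nrow(vals))
    names(front) <- ids
    remaining <- ids
    k <- 0L
    while (length(remaining)) {
        k <- k + 1L
        f <- paretoFrontOracle(vals[remaining, , drop = FALSE])
        front[f] <- k
        remaining <- setdiff(remaining, f)
    }
    front
}

# pairwise dominance matrix built only from the exported predicate
dominanceMatrix <- function(vals) {
    n <- nrow(vals)
    D <- matrix(FALSE, n, n)
    for (i in seq_len(n))
        for (j in seq_len(n))
            if (i != j) D[i, j] <- dominates(vals[i, ], vals[j, ])
    D
}

# strictly increasing per-column transforms for invariance checks
monotoneTransforms <- list(
    function(x) exp(x),
    function(x) x^3 + 2 * x,
    function(x) 5 * x - 7,
    function(x) atan(x),
    function(x) rank(x, ties.method = "min")  # monotone, tie-preserving
)

# direct rank + z-score oracle for one column (sample sd)
rankZOracle <- function(x) {
    obs <- !is.na(x)
    r <- rank(x[obs], ties.method = "average")
    out <- x
    out[obs] <- (r - mean(r)) / sd(r)
    out
}
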