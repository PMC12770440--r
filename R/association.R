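#' @include stratify.R
NULL

#' Rank-normalize parameter log-ratios
#'
#' Per parameter (column): rank the log-ratios over all non-missing
#' patients (average ranks for ties), then z-score the ranks to mean 0 and
#' sample (n-1) standard deviation 1. Ranks are computed over the whole
#' cohort — cluster statistics are later read off cluster members against
#' this population-wide scale. Columns with fewer than two distinct values
#' are degenerate: emitted as all zeros and flagged, with a warning.
#'
#' @param ratios a \linkS4class{FeatureRatioMatrix} or numeric matrix
#'   (patients x parameters, NA = missing).
#' @return a \linkS4class{RankZMatrix}.
#' @examples
#' z <- rankNormalize(matrix(c(0.1, 0.5, 0.9), ncol = 1,
#'                           dimnames = list(NULL, "p")))
#' matrixValues(z)   # -1, 0, 1
#' @export
rankNormalize <- function(ratios) {
    vals <- if (is(ratios, "FeatureRatioMatrix")) ratios@values
            else if (is.matrix(ratios) && is.numeric(ratios)) ratios
            else stop("need a FeatureRatioMatrix or numeric matrix")
    if (ncol(vals) == 0L) stop("no parameter columns")
    z <- vals
    degenerate <- logical(ncol(vals))
    names(degenerate) <- colnames(vals)
    for (j in seq_len(ncol(vals))) {
        x <- vals[, j]
        obs <- !is.na(x)
        if (length(unique(x[obs])) < 2L) {
            degenerate[j] <- TRUE
            z[obs, j] <- 0
            next
        }
        r <- rank(x[obs], ties.method = "average")
        z[obs, j] <- (r - mean(r)) / stats::sd(r)
    }
    if (any(degenerate))
        warning("degenerate (constant) column(s) emitted as zeros: ",
                paste(names(degenerate)[degenerate], collapse = ", "))
    new("RankZMatrix", values = z, degenerate = degenerate)
}

#' Within-cluster mean and standard deviation of normalized ranks
#'
#' For each parameter and each extreme cluster, the arithmetic mean and
#' sample standard deviation of the cluster members' rank-z values. Since
#' columns are normalized over the whole cohort, the mean measures how far
#' the cluster deviates from the rest of the population and the standard
#' deviation how concentrated the cluster is. Missing values are dropped
#' pairwise per parameter; the effective n is reported. Parameter-cluster
#' pairs with fewer than 2 observations (sd undefined) or degenerate
#' columns are flagged and excluded from the ranking stage.
#'
#' @param z a \linkS4class{RankZMatrix}.
#' @param clusters a \linkS4class{ClusterLabels}.
#' @return data.frame with columns \code{parameter}, \code{cluster},
#'   \code{mean}, \code{sd}, \code{abs_mean}, \code{effective_n},
#'   \code{flagged}.
#' @export
clusterFeatureStats <- function(z, clusters) {
    stopifnot(is(z, "RankZMatrix"), is(clusters, "ClusterLabels"))
    vals <- z@values
    members <- list(A1 = clusters@best, A2 = clusters@worst)
    if (!all(unlist(members) %in% rownames(vals)))
        stop("cluster members absent from the rank-z matrix")
    out <- do.call(rbind, lapply(names(members), function(cl) {
        sub <- vals[members[[cl]], , drop = FALSE]
        mu <- colMeans(sub, na.rm = TRUE)
        sdv <- apply(sub, 2L, stats::sd, na.rm = TRUE)
        nEff <- colSums(!is.na(sub))
        data.frame(parameter = colnames(vals), cluster = cl,
                   mean = unname(mu), sd = unname(sdv),
                   abs_mean = unname(abs(mu)),
                   effective_n = as.integer(unname(nEff)),
                   flagged = unname(nEff < 2L | z@degenerate),
                   stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}

#' Second-stage nondominated ranking of parameters
#'
#' Ranks parameters within one extreme cluster by nondominated sorting in
#' the two-objective space (maximize |mean|, minimize sd), i.e. canonical
#' minimization of \code{(-abs(mean), sd)}. Front 1 contains the
#' parameters with high deviation and low within-cluster variation — those
#' most strongly associated with the cluster's response. Flagged
#' parameter-cluster pairs are excluded.
#'
#' @param stats data.frame from [clusterFeatureStats()].
#' @param cluster \code{"A1"} (best response) or \code{"A2"} (worst).
#' @return data.frame with columns \code{parameter}, \code{cluster},
#'   \code{mean}, \code{sd}, \code{abs_mean}, \code{front_number},
#'   \code{effective_n}, ordered by front then descending |mean|. Empty
#'   with attribute \code{status} when every parameter is flagged.
#' @export
rankParameters <- function(stats, cluster = c("A1", "A2")) {
    cluster <- match.arg(cluster)
    need <- c("parameter", "cluster", "mean", "sd", "abs_mean",
              "effective_n", "flagged")
    if (!all(need %in% colnames(stats)))
        stop("stats must come from clusterFeatureStats()")
    sub <- stats[stats$cluster == cluster & !stats$flagged, , drop = FALSE]
    if (nrow(sub) == 0L) {
        out <- data.frame(parameter = character(), cluster = character(),
                          mean = numeric(), sd = numeric(),
                          abs_mean = numeric(), front_number = integer(),
                          effective_n = integer(), stringsAsFactors = FALSE)
        attr(out, "status") <- "all parameters flagged; nothing to rank"
        return(out)
    }
    m <- cbind(-sub$abs_mean, sub$sd)
    rownames(m) <- sub$parameter
    fa <- nondominatedSort(m)
    out <- data.frame(parameter = sub$parameter, cluster = cluster,
                      mean = sub$mean, sd = sub$sd, abs_mean = sub$abs_mean,
                      front_number = unname(fa@front[sub$parameter]),
                      effective_n = sub$effective_n,
                      stringsAsFactors = FALSE)
    out[order(out$front_number, -out$abs_mean, out$parameter), , drop = FALSE]
}

#' Write parameter rankings as CSV
#' @param rankings a single data.frame from [rankParameters()] or a list of
#'   them (e.g. A1 and A2), row-bound on output.
#' @param path CSV output path.
#' @return \code{path}, invisibly.
#' @export
writeParameterRanking <- function(rankings, path) {
    if (is.data.frame(rankings)) rankings <- list(rankings)
    df <- do.call(rbind, rankings)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
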