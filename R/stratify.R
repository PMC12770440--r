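#' @include pareto.R
NULL

.roundHalfUp <- function(x) floor(x + 0.5)

#' Select extreme best/worst response clusters (A1/A2)
#'
#' Takes the fraction \code{q} (default 20%) of patients with the lowest
#' front numbers as the best-response cluster A1, and the fraction with the
#' highest front numbers as the worst-response cluster A2. The target size
#' is \code{round(q*N)} (half up). When a front straddles the cutoff its
#' members are ordered by the sum of their per-objective ranks (ascending
#' for A1, descending for A2; residual exact ties by patient id) and
#' truncated; straddle events are recorded.
#'
#' @param fronts a \linkS4class{FrontAssignment}.
#' @param objectives the \linkS4class{ObjectiveMatrix} the fronts were
#'   computed from (used for the within-front tie-break).
#' @param q selection fraction in (0, 0.5].
#' @return a \linkS4class{ClusterLabels}.
#' @export
selectExtremeClusters <- function(fronts, objectives, q = 0.2) {
    stopifnot(is(fronts, "FrontAssignment"))
    if (!is.numeric(q) || length(q) != 1L || q <= 0 || q > 0.5)
        stop("q must be a single fraction in (0, 0.5]")
    f <- fronts@front
    n <- length(f)
    s <- .roundHalfUp(q * n)
    if (2L * s > n)
        stop(sprintf("cluster size %d too large: 2*%d > N=%d", s, s, n))
    if (s < 1L) stop("q*N rounds to zero patients")
    vals <- .objValues(objectives)
    if (!all(names(f) %in% rownames(vals)))
        stop("fronts contain patients absent from the objective matrix")
    vals <- vals[names(f), , drop = FALSE]
    rs <- rowSums(apply(vals, 2L, rank))       # smaller = better
    ids <- names(f)

    ordBest <- ids[order(f, rs, ids)]
    ordWorst <- ids[order(-f, -rs, ids)]
    best <- ordBest[seq_len(s)]
    worst <- ordWorst[seq_len(s)]

    ties <- data.frame(cluster = character(), front = integer(),
                       taken = integer(), front_size = integer(),
                       stringsAsFactors = FALSE)
    straddle <- function(ordIds, cluster) {
        cutF <- f[[ordIds[s]]]
        if (s < n && f[[ordIds[s + 1L]]] == cutF) {
            taken <- sum(f[ordIds[seq_len(s)]] == cutF)
            ties <<- rbind(ties, data.frame(
                cluster = cluster, front = cutF, taken = taken,
                front_size = sum(f == cutF), stringsAsFactors = FALSE))
        }
    }
    straddle(ordBest, "A1")
    straddle(ordWorst, "A2")

    new("ClusterLabels", best = best, worst = worst, q = q, ties = ties)
}

#' @rdname bestCluster
#' @export
setMethod("bestCluster", "ClusterLabels", function(x) x@best)

#' @rdname worstCluster
#' @export
setMethod("worstCluster", "ClusterLabels", function(x) x@worst)

#' Write cluster labels as CSV with a JSON provenance block
#' @param x a \linkS4class{ClusterLabels}.
#' @param allIds all patient ids under analysis (patients in neither
#'   cluster are labeled \code{"none"}).
#' @param path CSV output path (columns patient_id, cluster).
#' @param provenancePath optional JSON path recording q and tie events.
#' @return \code{path}, invisibly.
#' @export
writeClusters <- function(x, allIds, path, provenancePath = NULL) {
    stopifnot(is(x, "ClusterLabels"))
    cl <- rep("none", length(allIds))
    names(cl) <- allIds
    cl[x@best] <- "A1"
    cl[x@worst] <- "A2"
    df <- data.frame(patient_id = allIds, cluster = unname(cl))
    utils::write.csv(df[order(df$patient_id), ], path,
                     row.names = FALSE, quote = FALSE)
    if (!is.null(provenancePath))
        jsonlite::write_json(list(q = x@q, target_size = length(x@best),
                                  tie_events = x@ties),
                             provenancePath, auto_unbox = TRUE, digits = NA,
                             dataframe = "rows")
    invisible(path)
}

#' Single-endpoint responder classification
#'
#' Two rules on the motor endpoint (MDS-UPDRS III, lower is better):
#' \describe{
#'   \item{\code{strict_decrease}}{responder (R) iff V2 < baseline;
#'     nonresponder (NR) iff V2 >= baseline.}
#'   \item{\code{median_split_pct_change}}{percent change
#'     \code{100*(V2 - baseline)/baseline}; R iff the patient's percent
#'     change is strictly below the cohort median (arms pooled); patients
#'     exactly at the median are NR. Patients with baseline 0 are excluded
#'     with a warning.}
#' }
#' Patients missing either visit are excluded (listed with reasons).
#'
#' @param cohort a \linkS4class{ClinicalCohort}.
#' @param rule classification rule.
#' @param endpoint endpoint variable name (default \code{"MDS-UPDRS III"}).
#' @return a \linkS4class{ResponderLabels}.
#' @export
classifyResponders <- function(cohort,
                               rule = c("strict_decrease",
                                        "median_split_pct_change"),
                               endpoint = "MDS-UPDRS III") {
    rule <- match.arg(rule)
    stopifnot(is(cohort, "ClinicalCohort"))
    if (!endpoint %in% rownames(cohort))
        stop("endpoint '", endpoint, "' absent from cohort")
    b <- assay(cohort, "baseline")[endpoint, ]
    v2 <- assay(cohort, "V2")[endpoint, ]
    ids <- patientIds(cohort)
    ok <- !is.na(b) & !is.na(v2)
    excluded <- data.frame(patient_id = ids[!ok],
                           reason = rep("missing visit", sum(!ok)),
                           stringsAsFactors = FALSE)
    b <- b[ok]; v2 <- v2[ok]; ids <- ids[ok]
    if (rule == "strict_decrease") {
        lab <- ifelse(v2 < b, "R", "NR")
    } else {
        zero <- b == 0
        if (any(zero)) {
            warning(sum(zero), " patient(s) with baseline 0 excluded from ",
                    "median split")
            excluded <- rbind(excluded, data.frame(
                patient_id = ids[zero], reason = "baseline 0",
                stringsAsFactors = FALSE))
            b <- b[!zero]; v2 <- v2[!zero]; ids <- ids[!zero]
        }
        pct <- 100 * (v2 - b) / b
        lab <- ifelse(pct < stats::median(pct), "R", "NR")
    }
    names(lab) <- ids
    new("ResponderLabels", labels = lab, rule = rule, excluded = excluded)
}

#' @rdname responderCalls
#' @export
setMethod("responderCalls", "ResponderLabels", function(x) x@labels)

#' Write responder labels as CSV
#' @param x a \linkS4class{ResponderLabels}.
#' @param path CSV output path (columns patient_id, responder, rule).
#' @return \code{path}, invisibly.
#' @export
writeResponders <- function(x, path) {
    stopifnot(is(x, "ResponderLabels"))
    df <- data.frame(patient_id = names(x@labels),
                     responder = unname(x@labels), rule = x@rule)
    utils::write.csv(df[order(df$patient_id), ], path,
                     row.names = FALSE, quote = FALSE)
    invisible(path)
}
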