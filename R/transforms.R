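#' @include cohort.R
NULL

#' Define an objective (clinical endpoint) set
#'
#' Each objective has a name matching a cohort variable and a direction:
#' \code{"lower_is_better"} (e.g. a motor-impairment score) or
#' \code{"higher_is_better"} (e.g. a cognitive or olfactory score). The
#' change from baseline to V2 is oriented at ingestion so that smaller is
#' always better, making the Pareto machinery orientation-free.
#'
#' @param name character vector of objective names.
#' @param direction character vector, per objective, one of
#'   \code{"lower_is_better"}, \code{"higher_is_better"}.
#' @return data.frame with columns \code{name}, \code{direction}.
#' @examples
#' objectiveSpecs(c("PANDA", "MDS-UPDRS III"),
#'                c("higher_is_better", "lower_is_better"))
#' @export
objectiveSpecs <- function(name, direction) {
    direction <- match.arg(direction,
                           c("lower_is_better", "higher_is_better"),
                           several.ok = TRUE)
    if (length(direction) == 1L) direction <- rep(direction, length(name))
    stopifnot(length(name) == length(direction), !anyDuplicated(name))
    data.frame(name = as.character(name), direction = direction,
               stringsAsFactors = FALSE)
}

#' The default three-endpoint objective set
#'
#' PANDA (cognition, higher is better), MDS-UPDRS III (motor examination,
#' lower is better) and olfactory score (higher is better).
#'
#' @return data.frame of objective specs (see [objectiveSpecs()]).
#' @export
defaultObjectives <- function() {
    objectiveSpecs(
        name = c("PANDA", "MDS-UPDRS III", "olfactory score"),
        direction = c("higher_is_better", "lower_is_better",
                      "higher_is_better"))
}

#' Canonically oriented endpoint changes (V2 - baseline)
#'
#' Computes, per patient and objective, the change from baseline to V2 and
#' multiplies by -1 where the objective is higher-is-better, so a clinical
#' improvement is always a negative entry and smaller is always better.
#' Patients missing either visit for any objective are excluded (complete
#' cases) and listed with reasons.
#'
#' @param cohort a \linkS4class{ClinicalCohort} with baseline and V2 assays.
#' @param objectives objective set (see [objectiveSpecs()]); every name must
#'   exist in the cohort.
#' @return an \linkS4class{ObjectiveMatrix}.
#' @examples
#' cohort <- makeCohort(data.frame(
#'     patient_id = "P1", arm = "2FL",
#'     visit = rep(c("baseline", "V2"), each = 3),
#'     variable = rep(c("MDS-UPDRS III", "PANDA", "olfactory score"), 2),
#'     value = c(30, 20, 8, 25, 22, 10)))
#' matrixValues(objectiveDeltas(cohort))   # all improvements: negative row
#' @export
objectiveDeltas <- function(cohort, objectives = defaultObjectives()) {
    stopifnot(is(cohort, "ClinicalCohort"), nrow(objectives) >= 1L)
    absent <- setdiff(objectives$name, rownames(cohort))
    if (length(absent))
        stop("objective(s) absent from cohort: ", paste(absent, collapse = ", "))
    for (vv in c("baseline", "V2"))
        if (!vv %in% assayNames(cohort))
            stop("cohort lacks the '", vv, "' visit")
    b <- assay(cohort, "baseline")[objectives$name, , drop = FALSE]
    v2 <- assay(cohort, "V2")[objectives$name, , drop = FALSE]
    sgn <- ifelse(objectives$direction == "higher_is_better", -1, 1)
    delta <- (v2 - b) * sgn                     # objectives x patients
    ok <- colSums(is.na(delta)) == 0L
    excluded <- data.frame(patient_id = character(), reason = character(),
                           stringsAsFactors = FALSE)
    if (any(!ok)) {
        excluded <- do.call(rbind, lapply(colnames(delta)[!ok], function(p) {
            miss <- objectives$name[is.na(delta[, p])]
            vis <- vapply(miss, function(o)
                paste(c("baseline", "V2")[is.na(c(b[o, p], v2[o, p]))],
                      collapse = "+"), "")
            data.frame(patient_id = p,
                       reason = paste(sprintf("missing %s (%s)", miss, vis),
                                      collapse = "; "),
                       stringsAsFactors = FALSE)
        }))
    }
    new("ObjectiveMatrix",
        values = t(delta[, ok, drop = FALSE]),
        excluded = excluded,
        specs = objectives)
}

#' Parameter log fold changes ln(V2/baseline)
#'
#' Computes \code{ln(V2/baseline)} for every physiological parameter.
#' Immune-subset frequencies can be zero, so nonpositive inputs are handled
#' by a pseudocount policy: \code{"half_min"} (default) replaces each
#' nonpositive value with half the smallest positive value observed for
#' that parameter across the whole cohort (both visits); \code{"exclude"}
#' sets the affected cell to \code{NA}. Every application is logged.
#'
#' @param cohort a \linkS4class{ClinicalCohort}.
#' @param policy \code{"half_min"} or \code{"exclude"}.
#' @return a \linkS4class{FeatureRatioMatrix} (patients x parameters).
#' @export
featureLogRatios <- function(cohort, policy = c("half_min", "exclude")) {
    policy <- match.arg(policy)
    stopifnot(is(cohort, "ClinicalCohort"))
    pars <- parameterNames(cohort)
    if (!length(pars)) stop("cohort has no parameter variables")
    b <- assay(cohort, "baseline")[pars, , drop = FALSE]
    v2 <- assay(cohort, "V2")[pars, , drop = FALSE]
    logRows <- list()
    for (p in pars) {
        pair <- rbind(b[p, ], v2[p, ])
        colnames(pair) <- colnames(b)
        nonpos <- which(!is.na(pair) & pair <= 0, arr.ind = TRUE)
        npatNonpos <- length(unique(nonpos[, 2L]))
        if (npatNonpos > 0.5 * ncol(pair))
            warning("parameter '", p, "' nonpositive for >50% of patients (",
                    npatNonpos, "/", ncol(pair), ")")
        if (nrow(nonpos) == 0L) next
        if (policy == "half_min") {
            posmin <- suppressWarnings(min(pair[!is.na(pair) & pair > 0]))
            repl <- if (is.finite(posmin)) posmin / 2 else NA_real_
            if (!is.finite(repl))
                warning("parameter '", p,
                        "' has no positive value; cells set to NA")
        } else repl <- NA_real_
        logRows[[p]] <- data.frame(
            parameter = p,
            patient_id = colnames(pair)[nonpos[, 2L]],
            visit = c("baseline", "V2")[nonpos[, 1L]],
            original = pair[nonpos],
            replacement = repl, stringsAsFactors = FALSE)
        pair[nonpos] <- repl
        b[p, ] <- pair[1L, ]; v2[p, ] <- pair[2L, ]
    }
    ratios <- t(log(v2 / b))                   # patients x parameters
    new("FeatureRatioMatrix",
        values = ratios,
        policy = policy,
        policyLog = if (length(logRows)) do.call(rbind, c(logRows, list(
            make.row.names = FALSE)))
        else data.frame(parameter = character(), patient_id = character(),
                        visit = character(), original = numeric(),
                        replacement = numeric(), stringsAsFactors = FALSE))
}
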