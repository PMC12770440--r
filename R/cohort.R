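#' @include AllGenerics.R
NULL

.LONG_COLS <- c("patient_id", "arm", "visit", "variable", "value")

#' Construct a ClinicalCohort from a long-format table
#'
#' @param x data.frame with columns \code{patient_id}, \code{arm},
#'   \code{visit}, \code{variable}, \code{value} (one row per measurement;
#'   missing measurements are simply absent or have \code{NA} value).
#' @param objectives objective set (see [defaultObjectives()]); variables
#'   named there are typed \code{"objective"}, all others
#'   \code{"parameter"}.
#' @return a \linkS4class{ClinicalCohort}.
#' @export
makeCohort <- function(x, objectives = defaultObjectives()) {
    missing_cols <- setdiff(.LONG_COLS, colnames(x))
    if (length(missing_cols))
        stop("long table lacks column(s): ", paste(missing_cols, collapse = ", "))
    x$patient_id <- as.character(x$patient_id)
    x$visit <- as.character(x$visit)
    x$variable <- as.character(x$variable)
    bad_visit <- setdiff(unique(x$visit), .VISITS)
    if (length(bad_visit))
        stop("unknown visit label(s): ", paste(bad_visit, collapse = ", "))
    key <- paste(x$patient_id, x$visit, x$variable, sep = "\r")
    if (anyDuplicated(key)) {
        d <- x[duplicated(key), , drop = FALSE][1L, ]
        stop(sprintf("duplicate (patient, visit, variable) triple: (%s, %s, %s)",
                     d$patient_id, d$visit, d$variable))
    }
    if (!is.numeric(x$value)) {
        v <- suppressWarnings(as.numeric(x$value))
        bad <- which(is.na(v) & !is.na(x$value) & !x$value %in% c("", "NA"))
        if (length(bad))
            stop("non-numeric value at table row ", bad[1L], ": '", x$value[bad[1L]], "'")
        x$value <- v
    }
    if (any(is.infinite(x$value)))
        stop("non-finite measurement values are not allowed")

    arm_map <- unique(x[, c("patient_id", "arm")])
    if (anyDuplicated(arm_map$patient_id)) {
        p <- arm_map$patient_id[duplicated(arm_map$patient_id)][1L]
        stop("conflicting arm labels for patient ", p)
    }
    pts <- sort(unique(x$patient_id))
    vars <- unique(x$variable)
    obj_vars <- intersect(objectives$name, vars)
    par_vars <- setdiff(vars, obj_vars)
    vars <- c(obj_vars, sort(par_vars))
    visits <- intersect(.VISITS, unique(x$visit))

    assays <- lapply(visits, function(vv) {
        m <- matrix(NA_real_, nrow = length(vars), ncol = length(pts),
                    dimnames = list(vars, pts))
        sub <- x[x$visit == vv, , drop = FALSE]
        m[cbind(match(sub$variable, vars), match(sub$patient_id, pts))] <- sub$value
        m
    })
    names(assays) <- visits

    arms <- arm_map$arm[match(pts, arm_map$patient_id)]
    cohort <- new("ClinicalCohort", SummarizedExperiment(
        assays = assays,
        rowData = DataFrame(type = ifelse(vars %in% obj_vars,
                                          "objective", "parameter"),
                            row.names = vars),
        colData = DataFrame(arm = as.character(arms), row.names = pts)))

    miss <- sapply(visits, function(vv) rowSums(is.na(assays[[vv]])))
    metadata(cohort)$validation <- list(
        n_patients = length(pts),
        n_variables = length(vars),
        visits = visits,
        arms = table(arms),
        missing_by_variable = as.data.frame(miss))
    cohort
}

#' Read a cohort table from delimited text
#'
#' Accepts the canonical long layout (header
#' \code{patient_id,arm,visit,variable,value}) or a wide layout
#' (\code{patient_id,arm} plus one \code{<variable>_<visit>} column per
#' measurement). The field separator is auto-detected among comma and tab
#' unless given.
#'
#' @param path path to a CSV/TSV file.
#' @param format \code{"auto"} (default), \code{"long"} or \code{"wide"}.
#' @param sep field separator; \code{NULL} auto-detects.
#' @param objectives objective set used to type variables.
#' @param verbose log per-variable missingness counts via [message()].
#' @return a \linkS4class{ClinicalCohort}; the validation report (counts,
#'   missingness) is in \code{metadata(x)$validation}.
#' @examples
#' path <- system.file("extdata", "synthetic_cohort_72.csv",
#'                     package = "MOAstrat")
#' cohort <- readCohort(path)
#' nPatients(cohort)
#' @export
readCohort <- function(path, format = c("auto", "long", "wide"), sep = NULL,
                       objectives = defaultObjectives(), verbose = FALSE) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("file not found: ", path)
    header <- readLines(path, n = 1L)
    if (is.null(sep))
        sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >
                   lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
    x <- tryCatch(
        utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE),
        error = function(e) stop("malformed table '", path, "': ",
                                 conditionMessage(e), call. = FALSE))
    if (format == "auto")
        format <- if (all(.LONG_COLS %in% colnames(x))) "long" else "wide"
    if (format == "wide")
        x <- .wideToLong(x)
    else if (!all(.LONG_COLS %in% colnames(x)))
        stop("long table lacks column(s): ",
             paste(setdiff(.LONG_COLS, colnames(x)), collapse = ", "))
    cohort <- makeCohort(x, objectives = objectives)
    if (verbose) {
        rep <- metadata(cohort)$validation
        message(sprintf("cohort: %d patients, %d variables, visits: %s",
                        rep$n_patients, rep$n_variables,
                        paste(rep$visits, collapse = ", ")))
        mm <- rep$missing_by_variable
        for (v in rownames(mm)[rowSums(mm) > 0])
            message(sprintf("  missing %s: %s", v,
                            paste(sprintf("%s=%d", colnames(mm), unlist(mm[v, ])),
                                  collapse = ", ")))
    }
    cohort
}

.wideToLong <- function(x) {
    if (!all(c("patient_id", "arm") %in% colnames(x)))
        stop("wide table must have columns patient_id, arm")
    meas <- setdiff(colnames(x), c("patient_id", "arm"))
    visit <- sub(".*_", "", meas)
    bad <- meas[!visit %in% .VISITS]
    if (length(bad))
        stop("wide column(s) without a recognizable visit suffix: ",
             paste(bad, collapse = ", "))
    variable <- sub("_[^_]*$", "", meas)
    out <- do.call(rbind, lapply(seq_along(meas), function(i)
        data.frame(patient_id = x$patient_id, arm = x$arm,
                   visit = visit[i], variable = variable[i],
                   value = x[[meas[i]]], stringsAsFactors = FALSE)))
    out[!is.na(out$value), , drop = FALSE]
}

#' Write a cohort as canonical long-form CSV
#'
#' Missing cells are omitted; [readCohort()] on the output reproduces the
#' cohort (up to row order and float formatting).
#'
#' @param x a \linkS4class{ClinicalCohort}.
#' @param path output file path.
#' @param reportPath optional path for a JSON validation report (counts,
#'   missingness).
#' @return \code{path}, invisibly.
#' @export
writeCohort <- function(x, path, reportPath = NULL) {
    long <- cohortToLong(x)
    long$value <- sprintf("%.15g", long$value)
    utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
    if (!is.null(reportPath)) {
        rep <- metadata(x)$validation
        rep$arms <- as.list(rep$arms)
        rep$missing_by_variable <- cbind(variable = rownames(rep$missing_by_variable),
                                         rep$missing_by_variable)
        jsonlite::write_json(rep, reportPath, auto_unbox = TRUE, digits = NA,
                             dataframe = "rows")
    }
    invisible(path)
}

#' Flatten a cohort to the canonical long layout
#' @param x a \linkS4class{ClinicalCohort}.
#' @return data.frame with columns patient_id, arm, visit, variable, value,
#'   sorted by patient, visit, variable; missing cells omitted.
#' @export
cohortToLong <- function(x) {
    arms <- armLabels(x)
    out <- do.call(rbind, lapply(assayNames(x), function(vv) {
        a <- assay(x, vv)
        idx <- which(!is.na(a), arr.ind = TRUE)
        data.frame(patient_id = colnames(a)[idx[, 2L]],
                   arm = unname(arms[colnames(a)[idx[, 2L]]]),
                   visit = vv,
                   variable = rownames(a)[idx[, 1L]],
                   value = a[idx], stringsAsFactors = FALSE)
    }))
    out[order(out$patient_id, match(out$visit, .VISITS), out$variable), ,
        drop = FALSE]
}

#' @rdname nPatients
#' @export
setMethod("nPatients", "ClinicalCohort", function(x) ncol(x))

#' @rdname nPatients
#' @export
setMethod("nPatients", "ObjectiveMatrix",
          function(x) nrow(x@values) + nrow(x@excluded))

#' @rdname patientIds
#' @export
setMethod("patientIds", "ClinicalCohort", function(x) colnames(x))

#' @rdname patientIds
#' @export
setMethod("patientIds", "ObjectiveMatrix", function(x) rownames(x@values))

#' @rdname armLabels
#' @export
setMethod("armLabels", "ClinicalCohort", function(x) {
    a <- colData(x)$arm
    names(a) <- colnames(x)
    a
})

#' @rdname objectiveNames
#' @export
setMethod("objectiveNames", "ClinicalCohort",
          function(x) rownames(x)[rowData(x)$type == "objective"])

#' @rdname parameterNames
#' @export
setMethod("parameterNames", "ClinicalCohort",
          function(x) rownames(x)[rowData(x)$type == "parameter"])

#' @rdname matrixValues
#' @export
setMethod("matrixValues", "ObjectiveMatrix", function(x) x@values)

#' @rdname matrixValues
#' @export
setMethod("matrixValues", "FeatureRatioMatrix", function(x) x@values)

#' @rdname matrixValues
#' @export
setMethod("matrixValues", "RankZMatrix", function(x) x@values)

#' Patients excluded from an ObjectiveMatrix, with reasons
#' @param x an \linkS4class{ObjectiveMatrix}.
#' @return data.frame with columns patient_id, reason.
#' @export
excludedPatients <- function(x) {
    stopifnot(is(x, "ObjectiveMatrix"))
    x@excluded
}
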