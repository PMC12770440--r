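#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assays assay
#'   assayNames rowData colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

.VISITS <- c("baseline", "V1", "V2")

#' ClinicalCohort: per-patient, per-visit clinical measurements
#'
#' A \linkS4class{SummarizedExperiment} holding one assay per study visit
#' (\code{"baseline"}, optionally \code{"V1"}, and \code{"V2"}); rows are
#' measured variables (clinical endpoint scores and physiological
#' parameters), columns are patients. \code{rowData} carries a \code{type}
#' column (\code{"objective"} or \code{"parameter"}), \code{colData} an
#' \code{arm} column with the intervention-arm label. Missing measurements
#' are \code{NA}, never a sentinel value.
#'
#' Construct with [readCohort()], [makeCohort()] or [simulateCohort()].
#'
#' @seealso [readCohort()], [objectiveDeltas()], [featureLogRatios()]
#' @export
setClass("ClinicalCohort", contains = "SummarizedExperiment")

setValidity("ClinicalCohort", function(object) {
    msg <- NULL
    an <- assayNames(object)
    if (length(an) == 0L || !all(an %in% .VISITS))
        msg <- c(msg, sprintf("assay (visit) names must be among %s",
                              paste(.VISITS, collapse = ", ")))
    if (!"arm" %in% colnames(colData(object)))
        msg <- c(msg, "colData must contain an 'arm' column")
    if (!"type" %in% colnames(rowData(object)))
        msg <- c(msg, "rowData must contain a 'type' column")
    else if (!all(rowData(object)$type %in% c("objective", "parameter")))
        msg <- c(msg, "rowData$type must be 'objective' or 'parameter'")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "patient ids (colnames) must be unique and non-NULL")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "variable names (rownames) must be unique and non-NULL")
    for (v in an) {
        a <- assay(object, v)
        if (any(is.infinite(a)))
            msg <- c(msg, sprintf("assay '%s' contains non-finite values", v))
    }
    if (is.null(msg)) TRUE else msg
})

#' ObjectiveMatrix: canonically oriented endpoint changes
#'
#' Complete-case matrix of per-patient endpoint changes (V2 - baseline),
#' sign-flipped for higher-is-better endpoints so that smaller is always
#' better. Rows are patients, columns objectives. Patients excluded for
#' missing visits are listed with reasons in \code{excluded}.
#'
#' @slot values numeric matrix, patients x objectives, no missing values.
#' @slot excluded data.frame with columns \code{patient_id}, \code{reason}.
#' @slot specs data.frame of the objective set used (columns \code{name},
#'   \code{direction}).
#' @export
setClass("ObjectiveMatrix",
    representation(values = "matrix", excluded = "data.frame",
                   specs = "data.frame"))

setValidity("ObjectiveMatrix", function(object) {
    v <- object@values
    if (!is.numeric(v)) return("values must be numeric")
    if (nrow(v) > 0 && any(!is.finite(v)))
        return("values must be finite (complete cases only)")
    if (!all(c("patient_id", "reason") %in% colnames(object@excluded)))
        return("excluded must have columns patient_id, reason")
    if (!all(c("name", "direction") %in% colnames(object@specs)))
        return("specs must have columns name, direction")
    if (!identical(colnames(v), object@specs$name))
        return("column order must match specs$name")
    TRUE
})

#' FeatureRatioMatrix: log fold changes of physiological parameters
#'
#' Per-patient \code{ln(V2/baseline)} for every physiological parameter.
#' Nonpositive inputs are handled by the recorded pseudocount policy;
#' every policy application is logged per cell in \code{policyLog}.
#'
#' @slot values numeric matrix, patients x parameters (NA = missing).
#' @slot policy character, the nonpositive-value policy applied.
#' @slot policyLog data.frame logging each replaced/excluded cell.
#' @export
setClass("FeatureRatioMatrix",
    representation(values = "matrix", policy = "character",
                   policyLog = "data.frame"))

#' FrontAssignment: nondominated-sorting front numbers
#'
#' Result of nondominated sorting: each patient's front number, from 1
#' (best, dominated by no one) to \code{nFronts} (worst). Fronts partition
#' the patients.
#'
#' @slot front named integer vector, patient id -> front number.
#' @slot nFronts integer, the number of fronts w.
#' @export
setClass("FrontAssignment",
    representation(front = "integer", nFronts = "integer"))

setValidity("FrontAssignment", function(object) {
    f <- object@front
    if (length(f) == 0L) return("empty front assignment")
    if (is.null(names(f)) || anyDuplicated(names(f)))
        return("front numbers must be uniquely named by patient id")
    w <- object@nFronts
    if (length(w) != 1L || w < 1L) return("nFronts must be a single integer >= 1")
    if (!setequal(unique(f), seq_len(w)))
        return("front numbers must form the contiguous range 1..nFronts")
    TRUE
})

#' ClusterLabels: extreme best/worst response clusters
#'
#' The best (A1) and worst (A2) response clusters: the fraction \code{q} of
#' patients with the lowest and highest front numbers. Boundary fronts that
#' straddle the cutoff are resolved by the within-front rank-sum tie-break
#' and the events are recorded.
#'
#' @slot best character vector of patient ids in A1.
#' @slot worst character vector of patient ids in A2.
#' @slot q numeric selection fraction.
#' @slot ties data.frame recording boundary-straddle events.
#' @export
setClass("ClusterLabels",
    representation(best = "character", worst = "character",
                   q = "numeric", ties = "data.frame"))

setValidity("ClusterLabels", function(object) {
    if (length(intersect(object@best, object@worst)) > 0L)
        return("A1 and A2 must be disjoint")
    if (length(object@best) != length(object@worst))
        return("A1 and A2 must have the same target size")
    if (object@q <= 0 || object@q > 0.5)
        return("q must be in (0, 0.5]")
    TRUE
})

#' ResponderLabels: single-endpoint responder classification
#'
#' Patient-level responder (R) / nonresponder (NR) labels from one of the
#' two motor-endpoint rules: strict decrease (R iff MDS-UPDRS III V2 <
#' baseline) or median split on percent change.
#'
#' @slot labels named character vector ("R"/"NR") by patient id.
#' @slot rule character, the classification rule applied.
#' @slot excluded data.frame of unlabeled patients with reasons.
#' @export
setClass("ResponderLabels",
    representation(labels = "character", rule = "character",
                   excluded = "data.frame"))

#' RankZMatrix: rank-normalized parameter log-ratios
#'
#' Per-parameter cohort-wide ranks of \code{ln(V2/baseline)}, z-scored per
#' column to mean 0 and sample standard deviation 1. Constant (degenerate)
#' columns are emitted as all zeros and flagged.
#'
#' @slot values numeric matrix, patients x parameters.
#' @slot degenerate named logical vector flagging constant columns.
#' @export
setClass("RankZMatrix",
    representation(values = "matrix", degenerate = "logical"))

#' PowerDesign: one-way ANOVA power/sample-size design
#'
#' @slot effectSize Cohen's f.
#' @slot alpha type-I error rate.
#' @slot kGroups number of groups.
#' @slot targetPower requested power.
#' @slot totalN total sample size satisfying the target.
#' @slot achievedPower power achieved at \code{totalN}.
#' @slot balanced whether \code{totalN} was forced to a multiple of k.
#' @export
setClass("PowerDesign",
    representation(effectSize = "numeric", alpha = "numeric",
                   kGroups = "integer", targetPower = "numeric",
                   totalN = "integer", achievedPower = "numeric",
                   balanced = "logical"))

setValidity("PowerDesign", function(object) {
    if (object@achievedPower < object@targetPower)
        return("achieved power must be >= target power")
    TRUE
})

#' MoaResult: full multiobjective-analysis result bundle
#'
#' Returned by [runMoa()]: every intermediate and final object of the
#' pipeline, plus a machine-readable manifest of all policies in force.
#'
#' @slot cohort the \linkS4class{ClinicalCohort} analyzed.
#' @slot deltas \linkS4class{ObjectiveMatrix} of oriented endpoint changes.
#' @slot ratios \linkS4class{FeatureRatioMatrix} of parameter log-ratios.
#' @slot fronts \linkS4class{FrontAssignment}.
#' @slot clusters \linkS4class{ClusterLabels}.
#' @slot responders list of \linkS4class{ResponderLabels} (both rules).
#' @slot rankZ \linkS4class{RankZMatrix}.
#' @slot stats data.frame of within-cluster parameter statistics.
#' @slot rankings list of per-cluster parameter-ranking data.frames.
#' @slot manifest list recording every policy affecting the output.
#' @export
setClass("MoaResult",
    representation(cohort = "ClinicalCohort", deltas = "ObjectiveMatrix",
                   ratios = "FeatureRatioMatrix", fronts = "FrontAssignment",
                   clusters = "ClusterLabels", responders = "list",
                   rankZ = "RankZMatrix", stats = "data.frame",
                   rankings = "list", manifest = "list"))
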