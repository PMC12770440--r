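#' @include AllClasses.R
NULL

#' Number of patients in a cohort or matrix
#' @param x a \linkS4class{ClinicalCohort} or \linkS4class{ObjectiveMatrix}.
#' @return integer patient count.
#' @export
setGeneric("nPatients", function(x) standardGeneric("nPatients"))

#' Patient identifiers
#' @param x a cohort or derived object.
#' @return character vector of patient ids.
#' @export
setGeneric("patientIds", function(x) standardGeneric("patientIds"))

#' Intervention-arm labels per patient
#' @param x a \linkS4class{ClinicalCohort}.
#' @return named character vector, patient id -> arm.
#' @export
setGeneric("armLabels", function(x) standardGeneric("armLabels"))

#' Names of clinical-endpoint (objective) variables
#' @param x a \linkS4class{ClinicalCohort}.
#' @return character vector.
#' @export
setGeneric("objectiveNames", function(x) standardGeneric("objectiveNames"))

#' Names of physiological-parameter variables
#' @param x a \linkS4class{ClinicalCohort}.
#' @return character vector.
#' @export
setGeneric("parameterNames", function(x) standardGeneric("parameterNames"))

#' Underlying numeric values of a derived matrix object
#' @param x an \linkS4class{ObjectiveMatrix}, \linkS4class{FeatureRatioMatrix}
#'   or \linkS4class{RankZMatrix}.
#' @return numeric matrix, patients in rows.
#' @export
setGeneric("matrixValues", function(x) standardGeneric("matrixValues"))

#' Front numbers from nondominated sorting
#' @param x a \linkS4class{FrontAssignment}.
#' @return named integer vector, patient id -> front number (1 = best).
#' @export
setGeneric("frontNumbers", function(x) standardGeneric("frontNumbers"))

#' Number of fronts
#' @param x a \linkS4class{FrontAssignment}.
#' @return integer, the worst front number w.
#' @export
setGeneric("nFronts", function(x) standardGeneric("nFronts"))

#' Members of the best-response cluster (A1)
#' @param x a \linkS4class{ClusterLabels}.
#' @return character vector of patient ids.
#' @export
setGeneric("bestCluster", function(x) standardGeneric("bestCluster"))

#' Members of the worst-response cluster (A2)
#' @param x a \linkS4class{ClusterLabels}.
#' @return character vector of patient ids.
#' @export
setGeneric("worstCluster", function(x) standardGeneric("worstCluster"))

#' Responder/nonresponder labels
#' @param x a \linkS4class{ResponderLabels}.
#' @return named character vector ("R"/"NR") by patient id.
#' @export
setGeneric("responderCalls", function(x) standardGeneric("responderCalls"))

#' Nondominated sorting into Pareto fronts
#'
#' Sorts rows (patients, or parameters in the second-stage ranking) into
#' fronts F1..Fw under the canonical minimize-is-better orientation: front 1
#' is the set of rows dominated by no other row; front k is the
#' nondominated set after removing fronts 1..k-1.
#'
#' @param x an \linkS4class{ObjectiveMatrix} or a plain numeric matrix in
#'   canonical (smaller-is-better) orientation.
#' @param ... unused.
#' @return a \linkS4class{FrontAssignment}.
#' @export
setGeneric("nondominatedSort", function(x, ...) standardGeneric("nondominatedSort"))
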