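#' MOAstrat: multiobjective stratification of clinical response
#'
#' Tools for analyzing intervention studies with several conflicting
#' clinical endpoints: Pareto nondominated sorting of patients on oriented
#' endpoint changes, extreme best/worst response clusters, rank-normalized
#' feature association with a second-stage nondominated parameter ranking,
#' single-endpoint responder rules, a priori one-way ANOVA power via the
#' noncentral F distribution, and a synthetic cohort simulator with
#' planted ground truth.
#'
#' Start with [runMoa()] for the full pipeline, or the stage functions
#' [objectiveDeltas()], [nondominatedSort()], [selectExtremeClusters()],
#' [featureLogRatios()], [rankNormalize()], [clusterFeatureStats()],
#' [rankParameters()]. Study design: [anovaPower()],
#' [requiredSampleSize()]. Validation: [simulateCohort()],
#' [recoveryBenchmark()].
#'
#' @keywords internal
"_PACKAGE"
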