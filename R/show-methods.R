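#' @include pipeline.R
NULL

setMethod("show", "ClinicalCohort", function(object) {
    cat("ClinicalCohort:", ncol(object), "patients,",
        nrow(object), "variables\n")
    cat("  visits:", paste(assayNames(object), collapse = ", "), "\n")
    cat("  objectives:", paste(objectiveNames(object), collapse = ", "), "\n")
    np <- length(parameterNames(object))
    cat("  parameters:", np, "\n")
    tab <- table(colData(object)$arm)
    cat("  arms:", paste(sprintf("%s (n=%d)", names(tab), tab),
                         collapse = ", "), "\n")
})

setMethod("show", "ObjectiveMatrix", function(object) {
    cat("ObjectiveMatrix:", nrow(object@values), "patients x",
        ncol(object@values), "objectives (canonical minimize)\n")
    cat("  objectives:", paste(sprintf("%s [%s]", object@specs$name,
                                       object@specs$direction),
                               collapse = ", "), "\n")
    if (nrow(object@excluded))
        cat("  excluded:", nrow(object@excluded), "patient(s)\n")
})

setMethod("show", "FeatureRatioMatrix", function(object) {
    cat("FeatureRatioMatrix: ln(V2/baseline),", nrow(object@values),
        "patients x", ncol(object@values), "parameters\n")
    cat("  nonpositive-value policy:", object@policy,
        sprintf("(%d application(s))\n", nrow(object@policyLog)))
})

setMethod("show", "FrontAssignment", function(object) {
    cat("FrontAssignment:", length(object@front), "patients in",
        object@nFronts, "fronts\n")
    cat("  front sizes:", paste(frontSizes(object), collapse = ", "), "\n")
})

setMethod("show", "ClusterLabels", function(object) {
    cat(sprintf("ClusterLabels (q = %g): |A1| = |A2| = %d\n",
                object@q, length(object@best)))
    if (nrow(object@ties))
        cat("  boundary-straddle events:", nrow(object@ties), "\n")
})

setMethod("show", "ResponderLabels", function(object) {
    tab <- table(factor(object@labels, levels = c("R", "NR")))
    cat(sprintf("ResponderLabels (%s): R = %d, NR = %d",
                object@rule, tab[["R"]], tab[["NR"]]))
    if (nrow(object@excluded))
        cat(",", nrow(object@excluded), "excluded")
    cat("\n")
})

setMethod("show", "RankZMatrix", function(object) {
    cat("RankZMatrix:", nrow(object@values), "patients x",
        ncol(object@values), "parameters (column mean 0, sd 1)\n")
    if (any(object@degenerate))
        cat("  degenerate columns:", sum(object@degenerate), "\n")
})

setMethod("show", "PowerDesign", function(object) {
    cat(sprintf(paste0("One-way ANOVA design: f = %g, alpha = %g, ",
                       "k = %d groups\n  total N = %d%s, achieved power ",
                       "= %.7f (target %.2f)\n"),
                object@effectSize, object@alpha, object@kGroups,
                object@totalN,
                if (object@balanced)
                    sprintf(" (%d per group)", object@totalN %/% object@kGroups)
                else "",
                object@achievedPower, object@targetPower))
})

setMethod("show", "MoaResult", function(object) {
    cat("MoaResult\n")
    cat(sprintf("  %d patients (%d analyzed, %d excluded), %d fronts\n",
                nPatients(object@cohort), nrow(object@deltas@values),
                nrow(object@deltas@excluded), object@fronts@nFronts))
    cat(sprintf("  clusters: |A1| = |A2| = %d (q = %g)\n",
                length(object@clusters@best), object@clusters@q))
    f1 <- vapply(object@rankings, function(rk)
        sum(rk$front_number == 1L), 1L)
    cat(sprintf("  front-1 parameters: A1 = %d, A2 = %d\n",
                f1[["A1"]], f1[["A2"]]))
})
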