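# in-code fixtures shared across test files

# minimal long table: one patient, the three endpoints at both visits
tinyLong <- function(patient = "P1", arm = "2FL",
                     baseline = c("MDS-UPDRS III" = 30, "PANDA" = 20,
                                  "olfactory score" = 8),
                     v2 = c("MDS-UPDRS III" = 25, "PANDA" = 22,
                            "olfactory score" = 10)) {
    data.frame(patient_id = patient, arm = arm,
               visit = rep(c("baseline", "V2"), each = length(baseline)),
               variable = rep(names(baseline), 2L),
               value = c(unname(baseline), unname(v2)),
               stringsAsFactors = FALSE)
}

# n-patient cohort with explicit per-objective deltas (canonical clinical
# orientation handled by objectiveDeltas); optional parameter matrix
deltaCohort <- function(deltas, parameters = NULL, arm = "2FL") {
    # deltas: matrix patients x 3 in raw units for the default endpoints
    n <- nrow(deltas)
    ids <- sprintf("P%02d", seq_len(n))
    base <- c("MDS-UPDRS III" = 40, "PANDA" = 15, "olfactory score" = 8)
    rows <- list()
    for (k in seq_along(base)) {
        v <- names(base)[k]
        rows[[v]] <- data.frame(
            patient_id = rep(ids, 2L), arm = arm,
            visit = rep(c("baseline", "V2"), each = n), variable = v,
            value = c(rep(base[[v]], n), base[[v]] + deltas[, k]),
            stringsAsFactors = FALSE)
    }
    if (!is.null(parameters)) {
        for (p in colnames(parameters)) {
            rows[[p]] <- data.frame(
                patient_id = rep(ids, 2L), arm = arm,
                visit = rep(c("baseline", "V2"), each = n), variable = p,
                value = c(rep(4, n), 4 * exp(parameters[, p])),
                stringsAsFactors = FALSE)
        }
    }
    makeCohort(do.call(rbind, rows))
}

# random canonical objective matrices, optionally with ties (rounded values)
randomInstance <- function(n, m, tied = FALSE) {
    vals <- matrix(stats::rnorm(n * m), nrow = n, ncol = m)
    if (tied) vals <- round(vals * 2) / 2
    rownames(vals) <- sprintf("P%03d", seq_len(n))
    vals
}

fixturePath <- function() {
    system.file("extdata", "synthetic_cohort_72.csv", package = "MOAstrat")
}
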