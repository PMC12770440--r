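test_that("objective deltas are canonically oriented (improvement < 0)", {
    # motor 30->25 (improved), cognition 20->22 (improved), smell 8->10
    cohort <- makeCohort(tinyLong())
    m <- objectiveDeltas(cohort)
    row <- matrixValues(m)["P1", ]
    expect_equal(unname(row[c("MDS-UPDRS III", "PANDA", "olfactory score")]),
                 c(-5, -2, -2))
    # no change at all -> zero row
    cohort0 <- makeCohort(tinyLong(v2 = c("MDS-UPDRS III" = 30, "PANDA" = 20,
                                          "olfactory score" = 8)))
    expect_equal(unname(matrixValues(objectiveDeltas(cohort0))["P1", ]),
                 c(0, 0, 0))
})

test_that("flipping an objective's direction negates exactly its column", {
    set.seed(42)
    cohort <- deltaCohort(matrix(rnorm(30), ncol = 3))
    specs <- defaultObjectives()
    m1 <- matrixValues(objectiveDeltas(cohort, specs))
    specs$direction[specs$name == "PANDA"] <- "lower_is_better"
    m2 <- matrixValues(objectiveDeltas(cohort, specs))
    expect_identical(m2[, "PANDA"], -m1[, "PANDA"])
    other <- setdiff(colnames(m1), "PANDA")
    expect_identical(m2[, other], m1[, other])
})

test_that("patients missing any objective visit are excluded with reasons", {
    long <- rbind(tinyLong("P1"), tinyLong("P2"))
    long <- long[!(long$patient_id == "P2" & long$visit == "V2" &
                   long$variable == "olfactory score"), ]
    m <- objectiveDeltas(makeCohort(long))
    expect_identical(rownames(matrixValues(m)), "P1")
    expect_identical(excludedPatients(m)$patient_id, "P2")
    expect_match(excludedPatients(m)$reason, "olfactory score.*V2")
    expect_identical(nPatients(m), 2L)
})

test_that("absent objectives raise a configuration error", {
    cohort <- makeCohort(tinyLong())
    expect_error(objectiveDeltas(cohort, objectiveSpecs("LEDD",
                                                        "lower_is_better")),
                 "absent")
})

test_that("log-ratios follow the closed form and the half-min pseudocount", {
    long <- rbind(tinyLong(),
                  data.frame(patient_id = "P1", arm = "2FL",
                             visit = c("baseline", "V2", "baseline", "V2",
                                       "baseline", "V2"),
                             variable = rep(c("parA", "parB", "parC"),
                                            each = 2L),
                             value = c(4, 8, 5, 5, 0, 2)))
    # parC baseline 0; half-min is per parameter over both visits:
    # min positive = 2 -> pseudocount 1 (the 1-patient cohort also trips
    # the mostly-nonpositive warning, which is not under test here)
    r <- suppressWarnings(featureLogRatios(makeCohort(long)))
    v <- matrixValues(r)["P1", ]
    expect_equal(unname(v["parA"]), log(2), tolerance = 1e-12)
    expect_identical(unname(v["parB"]), 0)
    expect_equal(unname(v["parC"]), log(2 / 1), tolerance = 1e-12)
    expect_identical(r@policyLog$parameter, "parC")
    expect_identical(r@policyLog$replacement, 1)
})

test_that("half-min uses the cohort-wide column minimum", {
    # worked case: baseline 0, V2 2.0, min positive in column 0.5 ->
    # pseudocount 0.25, ratio ln(2/0.25)
    long <- rbind(do.call(rbind, lapply(1:2, function(i)
        tinyLong(sprintf("P%d", i)))),
        data.frame(patient_id = c("P1", "P1", "P2", "P2"), arm = "2FL",
                   visit = c("baseline", "V2", "baseline", "V2"),
                   variable = "p", value = c(0, 2, 0.5, 0.6)))
    r <- featureLogRatios(makeCohort(long))
    expect_equal(matrixValues(r)["P1", "p"], log(2 / 0.25),
                 tolerance = 1e-12)
})

test_that("the exclude policy blanks nonpositive cells instead", {
    long <- rbind(tinyLong(),
                  data.frame(patient_id = "P1", arm = "2FL",
                             visit = c("baseline", "V2"),
                             variable = "p", value = c(0, 2)))
    r <- suppressWarnings(featureLogRatios(makeCohort(long),
                                           policy = "exclude"))
    expect_true(is.na(matrixValues(r)["P1", "p"]))
})

test_that("mostly-nonpositive parameters trigger a warning naming them", {
    long <- do.call(rbind, lapply(1:4, function(i) tinyLong(sprintf("P%d", i))))
    long <- rbind(long, data.frame(
        patient_id = rep(sprintf("P%d", 1:4), each = 2L), arm = "2FL",
        visit = rep(c("baseline", "V2"), 4L), variable = "badpar",
        value = c(0, 1, 0, 2, 0, 3, 5, 6)))
    expect_warning(featureLogRatios(makeCohort(long)), "badpar")
})

test_that("swapping visit roles negates all-positive log-ratios", {
    sim <- simulateCohort(syntheticConfig(nPatients = 15, nPlanted = 2,
                                          nNoise = 3, seed = 8))
    fwd <- matrixValues(featureLogRatios(sim$cohort))
    long <- cohortToLong(sim$cohort)
    long$visit <- c(baseline = "V2", V2 = "baseline")[long$visit]
    bwd <- matrixValues(featureLogRatios(makeCohort(long)))
    expect_equal(bwd, -fwd, tolerance = 1e-12)
})
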