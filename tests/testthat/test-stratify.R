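# ten patients on a clean 5-front chain: two patients per front
chainFronts <- function() {
    # canonical deltas: pairs (k, k) so fronts are 1,1,2,2,...,5,5
    vals <- matrix(rep(1:5, each = 2), ncol = 1)
    vals <- cbind(vals, vals)
    rownames(vals) <- sprintf("P%02d", 1:10)
    list(vals = vals, fa = nondominatedSort(vals))
}

test_that("q = 0.2 picks the two extreme fronts of a 10-patient chain", {
    cf <- chainFronts()
    cl <- selectExtremeClusters(cf$fa, cf$vals, q = 0.2)
    expect_identical(sort(bestCluster(cl)), c("P01", "P02"))
    expect_identical(sort(worstCluster(cl)), c("P09", "P10"))
    expect_identical(nrow(cl@ties), 0L)
})

test_that("straddling fronts are resolved by the rank-sum tie-break", {
    # 10 patients, fronts 1,1,2,2,2,3,3,4,4,5; q=0.3 -> s=3, front 2 straddles
    vals <- matrix(c(1, 1,   1, 1,
                     2, 3,   3, 2,   2.5, 2.5,
                     4, 5,   5, 4,
                     6, 6,   6, 6.5,
                     7, 7), ncol = 2, byrow = TRUE)
    rownames(vals) <- sprintf("P%02d", 1:10)
    fa <- nondominatedSort(vals)
    cl <- selectExtremeClusters(fa, vals, q = 0.3)
    expect_length(bestCluster(cl), 3L)
    # the front-2 member with the smallest per-objective rank sum enters A1:
    # ranks within front 2 favor (2.5, 2.5) over (2,3)/(3,2) total order by
    # rank sums: P05 has sum 3+3=... compute directly
    rs <- rowSums(apply(vals, 2, rank))
    f2 <- names(which(frontNumbers(fa) == 2L))
    expect_identical(setdiff(bestCluster(cl), c("P01", "P02")),
                     f2[which.min(rs[f2])])
    expect_identical(cl@ties$cluster, "A1")
    expect_identical(cl@ties$front, 2L)
})

test_that("cluster size follows round-half-up and the 2s > N guard", {
    cf <- chainFronts()
    expect_error(selectExtremeClusters(cf$fa, cf$vals, q = 0.6), "0.5")
    # 72 * 0.2 = 14.4 -> 14
    sim <- simulateCohort(syntheticConfig(nPatients = 72, seed = 3))
    deltas <- objectiveDeltas(sim$cohort, sim$objectives)
    cl <- selectExtremeClusters(nondominatedSort(deltas), deltas, q = 0.2)
    expect_length(bestCluster(cl), 14L)
    # 10 * 0.25 = 2.5 -> 3 (half up, not banker's)
    cl <- selectExtremeClusters(cf$fa, cf$vals, q = 0.25)
    expect_length(bestCluster(cl), 3L)
})

test_that("clusters are disjoint, ordered, and monotone in q", {
    set.seed(404)
    vals <- randomInstance(40, 3, tied = TRUE)
    fa <- nondominatedSort(vals)
    prevBest <- character()
    prevWorst <- character()
    for (q in c(0.1, 0.2, 0.3, 0.4, 0.5)) {
        cl <- selectExtremeClusters(fa, vals, q = q)
        expect_length(intersect(bestCluster(cl), worstCluster(cl)), 0L)
        expect_true(all(prevBest %in% bestCluster(cl)))
        expect_true(all(prevWorst %in% worstCluster(cl)))
        prevBest <- bestCluster(cl)
        prevWorst <- worstCluster(cl)
        f <- frontNumbers(fa)
        if (nrow(cl@ties) == 0L)
            expect_true(max(f[bestCluster(cl)]) <= min(f[worstCluster(cl)]))
    }
})

test_that("strict-decrease responder rule labels V2 < baseline as R", {
    long <- rbind(tinyLong("P1"),                      # 30 -> 25: R
                  tinyLong("P2", v2 = c("MDS-UPDRS III" = 30, "PANDA" = 22,
                                        "olfactory score" = 10)),  # 30: NR
                  tinyLong("P3", v2 = c("MDS-UPDRS III" = 31, "PANDA" = 22,
                                        "olfactory score" = 10)))  # 31: NR
    rl <- classifyResponders(makeCohort(long), "strict_decrease")
    expect_identical(responderCalls(rl),
                     c(P1 = "R", P2 = "NR", P3 = "NR"))
})

test_that("median split labels strictly-below-median percent change as R", {
    # percent changes -30, -20, -10, 0, +10 -> median -10 -> R = first two
    base <- 40
    pct <- c(-30, -20, -10, 0, 10)
    long <- do.call(rbind, lapply(seq_along(pct), function(i)
        tinyLong(sprintf("P%d", i),
                 baseline = c("MDS-UPDRS III" = base, "PANDA" = 20,
                              "olfactory score" = 8),
                 v2 = c("MDS-UPDRS III" = base * (1 + pct[i] / 100),
                        "PANDA" = 20, "olfactory score" = 8))))
    rl <- classifyResponders(makeCohort(long), "median_split_pct_change")
    expect_identical(responderCalls(rl),
                     c(P1 = "R", P2 = "R", P3 = "NR", P4 = "NR", P5 = "NR"))
})

test_that("degenerate and zero-baseline median splits behave as documented", {
    # identical percent change for all -> nobody strictly below the median
    long <- do.call(rbind, lapply(1:4, function(i) tinyLong(sprintf("P%d", i))))
    rl <- classifyResponders(makeCohort(long), "median_split_pct_change")
    expect_identical(unique(unname(responderCalls(rl))), "NR")
    # baseline 0 is excluded with a warning
    long2 <- rbind(tinyLong("P1"), tinyLong("P2"),
                   tinyLong("P3", baseline = c("MDS-UPDRS III" = 0,
                                               "PANDA" = 20,
                                               "olfactory score" = 8)))
    expect_warning(rl2 <- classifyResponders(makeCohort(long2),
                                             "median_split_pct_change"),
                   "baseline 0")
    expect_false("P3" %in% names(responderCalls(rl2)))
    expect_true("P3" %in% rl2@excluded$patient_id)
})

test_that("patients missing a motor visit are excluded from labeling", {
    long <- rbind(tinyLong("P1"), tinyLong("P2"))
    long <- long[!(long$patient_id == "P2" & long$visit == "V2" &
                   long$variable == "MDS-UPDRS III"), ]
    rl <- classifyResponders(makeCohort(long), "strict_decrease")
    expect_identical(names(responderCalls(rl)), "P1")
    expect_identical(rl@excluded$patient_id, "P2")
})
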