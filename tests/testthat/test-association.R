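test_that("rank normalization matches the direct rank + z oracle", {
    m <- cbind(clean = c(0.1, 0.5, 0.9),
               anycol = c(0.3, -1, 2))
    z <- matrixValues(rankNormalize(m))
    expect_equal(unname(z[, "clean"]), c(-1, 0, 1), tolerance = 1e-12)
    # tied column, frozen against the direct computation:
    # ranks (1.5, 1.5, 3, 4), mean 2.5, sample sd sqrt(1.5)
    m2 <- cbind(tied = c(0.2, 0.2, 0.7, 0.9))
    z2 <- matrixValues(rankNormalize(m2))[, "tied"]
    expect_equal(unname(z2),
                 c(-1, -1, 0.5, 1.5) / sqrt(1.5), tolerance = 1e-12)
    expect_equal(unname(z2), unname(rankZOracle(m2[, 1L])),
                 tolerance = 1e-12)
})

test_that("every complete rank-z column has mean 0 and sample sd 1", {
    set.seed(7)
    for (rep in 1:10) {
        m <- matrix(rnorm(25 * 6), ncol = 6,
                    dimnames = list(NULL, paste0("p", 1:6)))
        m[sample(length(m), 10)] <- round(m[sample(length(m), 10)], 1) # ties
        z <- matrixValues(rankNormalize(m))
        expect_true(all(abs(colMeans(z)) < 1e-9))
        expect_true(all(abs(apply(z, 2, sd) - 1) < 1e-9))
    }
})

test_that("constant columns are flagged degenerate and emitted as zeros", {
    m <- cbind(const = rep(1.5, 5), ok = 1:5)
    expect_warning(z <- rankNormalize(m), "degenerate")
    expect_identical(unname(matrixValues(z)[, "const"]), rep(0, 5))
    expect_identical(z@degenerate, c(const = TRUE, ok = FALSE))
})

test_that("missing cells keep their column normalized over observed rows", {
    m <- cbind(p = c(0.4, NA, 1.2, -0.3, 0.8, NA))
    z <- matrixValues(rankNormalize(m))[, "p"]
    expect_identical(is.na(z), is.na(m[, "p"]))
    obs <- z[!is.na(z)]
    expect_lt(abs(mean(obs)), 1e-9)
    expect_lt(abs(sd(obs) - 1), 1e-9)
})

test_that("cluster statistics are plain mean/sd of member z-values", {
    z <- new("RankZMatrix",
             values = matrix(c(1.0, 1.2, 0.8, -0.5, 0, 0.5),
                             ncol = 1,
                             dimnames = list(sprintf("P%d", 1:6), "p")),
             degenerate = c(p = FALSE))
    cl <- new("ClusterLabels", best = c("P1", "P2", "P3"),
              worst = c("P4", "P5", "P6"), q = 0.5,
              ties = data.frame())
    st <- clusterFeatureStats(z, cl)
    a1 <- st[st$cluster == "A1", ]
    expect_equal(a1$mean, 1.0, tolerance = 1e-12)
    expect_equal(a1$sd, 0.2, tolerance = 1e-12)
    expect_equal(a1$abs_mean, 1.0, tolerance = 1e-12)
    expect_identical(a1$effective_n, 3L)
})

test_that("a cluster spanning the whole cohort has mean approximately 0", {
    set.seed(12)
    n <- 20
    m <- matrix(rnorm(n * 4), ncol = 4,
                dimnames = list(sprintf("P%02d", 1:n), paste0("p", 1:4)))
    z <- rankNormalize(m)
    half <- sprintf("P%02d", 1:10)
    other <- sprintf("P%02d", 11:20)
    cl <- new("ClusterLabels", best = sprintf("P%02d", 1:n)[1:10],
              worst = other, q = 0.5, ties = data.frame())
    # union of both "clusters" = cohort: weighted means must cancel
    st <- clusterFeatureStats(z, cl)
    agg <- tapply(st$mean, st$parameter, sum)
    expect_true(all(abs(agg) < 1e-9))
})

test_that("single-member clusters are flagged and excluded from ranking", {
    z <- new("RankZMatrix",
             values = matrix(rnorm(8), ncol = 2,
                             dimnames = list(sprintf("P%d", 1:4),
                                             c("a", "b"))),
             degenerate = c(a = FALSE, b = FALSE))
    cl <- new("ClusterLabels", best = "P1", worst = "P4", q = 0.25,
              ties = data.frame())
    st <- clusterFeatureStats(z, cl)
    expect_true(all(st$flagged))
    rk <- rankParameters(st, "A1")
    expect_identical(nrow(rk), 0L)
    expect_match(attr(rk, "status"), "flagged")
})

test_that("parameter ranking is a nondominated sort on (-|mean|, sd)", {
    st <- data.frame(
        parameter = c("P", "Q"), cluster = "A1",
        mean = c(2.0, 1.0), sd = c(0.3, 1.0),
        abs_mean = c(2.0, 1.0), effective_n = 5L, flagged = FALSE,
        stringsAsFactors = FALSE)
    rk <- rankParameters(st, "A1")
    expect_identical(rk$front_number[match(c("P", "Q"), rk$parameter)],
                     c(1L, 2L))
    # conflicting coordinates: both on front 1
    st$sd <- c(1.0, 0.3)
    rk <- rankParameters(st, "A1")
    expect_identical(unique(rk$front_number), 1L)
    # negative means count by magnitude
    st2 <- data.frame(parameter = c("up", "down"), cluster = "A2",
                      mean = c(0.5, -2), sd = c(0.5, 0.5),
                      abs_mean = c(0.5, 2), effective_n = 5L,
                      flagged = FALSE, stringsAsFactors = FALSE)
    rk2 <- rankParameters(st2, "A2")
    expect_identical(rk2$parameter[rk2$front_number == 1L], "down")
})

test_that("rankings are invariant to strictly increasing raw transforms", {
    sim <- simulateCohort(syntheticConfig(nPatients = 30, nPlanted = 2,
                                          nNoise = 4, seed = 13))
    deltas <- objectiveDeltas(sim$cohort, sim$objectives)
    cl <- selectExtremeClusters(nondominatedSort(deltas), deltas, 0.2)
    raw <- matrixValues(featureLogRatios(sim$cohort))
    tr <- raw
    for (j in seq_len(ncol(raw))) tr[, j] <- exp(3 * raw[, j]) - 5
    st1 <- clusterFeatureStats(rankNormalize(raw), cl)
    st2 <- clusterFeatureStats(rankNormalize(tr), cl)
    expect_equal(st1, st2, tolerance = 1e-12)
    expect_equal(rankParameters(st1, "A1"), rankParameters(st2, "A1"),
                 tolerance = 1e-12)
})

test_that("a strongly planted parameter attains the top |mean| in A1 for
           most seeds", {
    hits <- 0L
    nSeeds <- 20L
    for (s in seq_len(nSeeds)) {
        sim <- simulateCohort(syntheticConfig(nPatients = 60, nPlanted = 1,
                                              rhoPlanted = 0.8, nNoise = 19,
                                              seed = 1000 + s))
        deltas <- objectiveDeltas(sim$cohort, sim$objectives)
        cl <- selectExtremeClusters(nondominatedSort(deltas), deltas, 0.2)
        st <- clusterFeatureStats(rankNormalize(featureLogRatios(sim$cohort)),
                                  cl)
        a1 <- st[st$cluster == "A1", ]
        if (a1$parameter[which.max(a1$abs_mean)] == sim$truth$planted)
            hits <- hits + 1L
    }
    expect_gt(hits / nSeeds, 0.5)
})
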