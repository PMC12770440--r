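#' @include transforms.R
NULL

# run code under a temporary RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    force(code)
}

.defaultObjectiveModels <- function() list(
    list(name = "MDS-UPDRS III", direction = "lower_is_better",
         baselineMean = 33, baselineSd = 10, scoreMin = 0, scoreMax = 132,
         effect = 4, noiseSd = 4),
    list(name = "PANDA", direction = "higher_is_better",
         baselineMean = 18, baselineSd = 5, scoreMin = 0, scoreMax = 30,
         effect = 1.5, noiseSd = 1.5),
    list(name = "olfactory score", direction = "higher_is_better",
         baselineMean = 8, baselineSd = 3, scoreMin = 0, scoreMax = 16,
         effect = 1.5, noiseSd = 1.5))

#' Configuration for the synthetic cohort simulator
#'
#' Defines a cohort with the statistical structure the multiobjective
#' analysis assumes: a latent per-patient responsiveness variable drives
#' correlated improvements across all clinical endpoints, a set of
#' "planted" physiological parameters whose log-ratios correlate with that
#' latent variable at \code{rhoPlanted}, and independent noise parameters.
#' Defaults emulate the study shape: 72 patients in 3 equal arms and the
#' three-endpoint objective set.
#'
#' @param nPatients number of patients (default 72).
#' @param arms arm labels (default the three supplementation arms).
#' @param armProportions arm proportions (default equal; sizes by largest
#'   remainder).
#' @param latentSd standard deviation of the latent responsiveness
#'   variable.
#' @param objectiveModels per-endpoint list: \code{name}, \code{direction},
#'   truncated-normal baseline (\code{baselineMean}, \code{baselineSd},
#'   clamped to \code{[scoreMin, scoreMax]}), and the change model: the
#'   oriented improvement is \code{effect} points per latent-sd plus
#'   Gaussian noise \code{noiseSd}, integer-rounded and clamped.
#' @param effectScale multiplier applied to every objective effect (0 gives
#'   endpoints unrelated to the latent variable).
#' @param nPlanted number of informative parameters.
#' @param rhoPlanted target correlation of planted log-ratios with the
#'   latent variable (Gaussian construction, exact in population).
#' @param nNoise number of null parameters.
#' @param baselineMeanlog,baselineSdlog lognormal parameter-baseline
#'   distribution (strictly positive, e.g. % of PBMC).
#' @param missingRate completely-at-random missingness fraction applied to
#'   every measurement cell.
#' @param seed integer; every stochastic draw derives from it.
#' @return a validated config list of class \code{"SyntheticConfig"}.
#' @export
syntheticConfig <- function(nPatients = 72,
                            arms = c("PA+BA", "2FL", "2FL+PA+BA"),
                            armProportions = NULL,
                            latentSd = 1,
                            objectiveModels = .defaultObjectiveModels(),
                            effectScale = 1,
                            nPlanted = 3, rhoPlanted = 0.8, nNoise = 27,
                            baselineMeanlog = log(5), baselineSdlog = 0.5,
                            missingRate = 0, seed = 1) {
    if (is.null(armProportions))
        armProportions <- rep(1 / length(arms), length(arms))
    if (length(arms) != length(armProportions))
        stop("arms and armProportions must have equal length")
    if (any(armProportions < 0) || abs(sum(armProportions) - 1) > 1e-8)
        stop("armProportions must be nonnegative and sum to 1")
    if (nPatients < 1 || nPlanted < 0 || nNoise < 0)
        stop("counts must be nonnegative (nPatients >= 1)")
    if (rhoPlanted < -1 || rhoPlanted > 1)
        stop("rhoPlanted must be in [-1, 1]")
    if (missingRate < 0 || missingRate >= 1)
        stop("missingRate must be in [0, 1)")
    if (latentSd <= 0) stop("latentSd must be positive")
    structure(list(
        nPatients = as.integer(nPatients), arms = arms,
        armProportions = armProportions, latentSd = latentSd,
        objectiveModels = objectiveModels, effectScale = effectScale,
        nPlanted = as.integer(nPlanted), rhoPlanted = rhoPlanted,
        nNoise = as.integer(nNoise), baselineMeanlog = baselineMeanlog,
        baselineSdlog = baselineSdlog, missingRate = missingRate,
        seed = as.integer(seed)), class = "SyntheticConfig")
}

.armAssignment <- function(n, arms, props) {
    cnt <- floor(props * n)
    rem <- n - sum(cnt)
    if (rem > 0) {
        frac <- props * n - cnt
        add <- order(frac, decreasing = TRUE)[seq_len(rem)]
        cnt[add] <- cnt[add] + 1L
    }
    rep(arms, cnt)
}

#' Simulate a synthetic clinical cohort with known ground truth
#'
#' Draws a latent responsiveness variable per patient; endpoint V2 scores
#' improve (in the endpoint's own better-direction) proportionally to it,
#' with noise, integer rounding and score-range clamping; planted
#' parameter log-ratios \code{ln(V2/baseline)} correlate with the latent
#' variable at the configured \code{rhoPlanted}, noise parameters are
#' independent. Deterministic for a fixed seed, and the caller's RNG state
#' is left untouched.
#'
#' @param config a [syntheticConfig()].
#' @return list with elements \code{cohort}
#'   (\linkS4class{ClinicalCohort}), \code{truth} (list: latent variable
#'   \code{r}, \code{planted} parameter names, \code{rho},
#'   \code{objectiveEffects}) and \code{objectives} (the objective table for
#'   [objectiveDeltas()]).
#' @examples
#' sim <- simulateCohort(syntheticConfig(nPatients = 24, seed = 7))
#' nPatients(sim$cohort)
#' @export
simulateCohort <- function(config) {
    stopifnot(inherits(config, "SyntheticConfig"))
    .withSeed(config$seed, {
        n <- config$nPatients
        ids <- sprintf("P%03d", seq_len(n))
        arm <- .armAssignment(n, config$arms, config$armProportions)
        r <- stats::rnorm(n, 0, config$latentSd)
        rStd <- r / config$latentSd

        rows <- list()
        effects <- numeric(0)
        for (om in config$objectiveModels) {
            base <- pmin(om$scoreMax, pmax(om$scoreMin,
                round(stats::rnorm(n, om$baselineMean, om$baselineSd))))
            sgn <- if (om$direction == "lower_is_better") -1 else 1
            eff <- om$effect * config$effectScale
            delta <- sgn * eff * rStd + stats::rnorm(n, 0, om$noiseSd)
            v2 <- pmin(om$scoreMax, pmax(om$scoreMin, round(base + delta)))
            effects[om$name] <- eff
            rows[[length(rows) + 1L]] <- data.frame(
                patient_id = rep(ids, 2L), arm = rep(arm, 2L),
                visit = rep(c("baseline", "V2"), each = n),
                variable = om$name, value = c(base, v2),
                stringsAsFactors = FALSE)
        }

        planted <- if (config$nPlanted > 0)
            sprintf("planted_%02d", seq_len(config$nPlanted)) else character()
        noise <- if (config$nNoise > 0)
            sprintf("noise_%02d", seq_len(config$nNoise)) else character()
        rho <- config$rhoPlanted
        for (p in c(planted, noise)) {
            L <- if (p %in% planted)
                rho * rStd + sqrt(1 - rho^2) * stats::rnorm(n)
            else stats::rnorm(n)
            base <- stats::rlnorm(n, config$baselineMeanlog,
                                  config$baselineSdlog)
            rows[[length(rows) + 1L]] <- data.frame(
                patient_id = rep(ids, 2L), arm = rep(arm, 2L),
                visit = rep(c("baseline", "V2"), each = n),
                variable = p, value = c(base, base * exp(L)),
                stringsAsFactors = FALSE)
        }

        long <- do.call(rbind, rows)
        if (config$missingRate > 0) {
            drop <- stats::runif(nrow(long)) < config$missingRate
            long <- long[!drop, , drop = FALSE]
        }
        specs <- objectiveSpecs(
            vapply(config$objectiveModels, `[[`, "", "name"),
            vapply(config$objectiveModels, `[[`, "", "direction"))
        cohort <- makeCohort(long, objectives = specs)
        names(r) <- ids
        list(cohort = cohort,
             truth = list(r = r, planted = planted, noise = noise,
                          rho = rho, objectiveEffects = effects,
                          seed = config$seed),
             objectives = specs)
    })
}

#' Ground-truth JSON for a simulated cohort
#' @param truth the \code{truth} element of [simulateCohort()] output.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
    jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Planted-parameter recovery of a parameter ranking
#'
#' A planted parameter counts as recovered when it lies on front 1 of at
#' least one of the supplied rankings. The default analysis supplies both
#' extreme-cluster rankings (A1 and A2), mirroring how best- and
#' worst-response parameter sets are pooled into one display.
#'
#' @param rankings a data.frame from [rankParameters()] or a list of them.
#' @param truth ground truth from [simulateCohort()].
#' @return list: \code{recovery} (fraction of planted parameters on front
#'   1; \code{NA} with \code{status = "not-applicable"} when no parameter
#'   was planted), \code{recovered} (named logical), \code{noiseFronts}
#'   (per noise parameter, its best front number across rankings).
#' @export
evaluateRecovery <- function(rankings, truth) {
    if (is.data.frame(rankings)) rankings <- list(rankings)
    all_par <- unique(unlist(lapply(rankings, `[[`, "parameter")))
    known <- c(truth$planted, truth$noise)
    if (length(setdiff(all_par, known)))
        stop("ranking names do not match ground truth: ",
             paste(setdiff(all_par, known), collapse = ", "))
    bestFront <- function(p) {
        f <- unlist(lapply(rankings, function(rk)
            rk$front_number[rk$parameter == p]))
        if (length(f)) min(f) else NA_integer_
    }
    if (length(truth$planted) == 0L)
        return(list(recovery = NA_real_, status = "not-applicable",
                    recovered = logical(0),
                    noiseFronts = vapply(truth$noise, bestFront, 1L)))
    recovered <- vapply(truth$planted, function(p) {
        f <- bestFront(p)
        !is.na(f) && f == 1L
    }, TRUE)
    list(recovery = mean(recovered), recovered = recovered,
         noiseFronts = vapply(truth$noise, bestFront, 1L))
}

#' Planted-signal recovery benchmark over many simulated cohorts
#'
#' Runs the full analysis (simulate, oriented deltas, nondominated sort,
#' extreme clusters, rank-normalized log-ratios, per-cluster parameter
#' ranking) over \code{nSeeds} independent cohorts and reports per-seed
#' and mean planted-parameter front-1 recovery, pooled over both
#' extreme-cluster rankings. Also reports each parameter's front-1
#' frequency, used for null-calibration checks.
#'
#' @param nSeeds number of simulated cohorts.
#' @param baseSeed first seed; cohort i uses \code{baseSeed + i - 1}.
#' @param nPatients,nPlanted,rhoPlanted,nNoise,effectScale passed to
#'   [syntheticConfig()].
#' @param q extreme-cluster fraction.
#' @param ... further [syntheticConfig()] arguments.
#' @return list: \code{meanRecovery}, \code{perSeed} (numeric vector),
#'   \code{front1Freq} (named, per parameter: fraction of seeds on front 1
#'   of either cluster ranking).
#' @export
recoveryBenchmark <- function(nSeeds = 100, baseSeed = 1, nPatients = 80,
                              nPlanted = 3, rhoPlanted = 0.8, nNoise = 27,
                              effectScale = 1, q = 0.2, ...) {
    perSeed <- numeric(nSeeds)
    f1count <- NULL
    for (i in seq_len(nSeeds)) {
        cfg <- syntheticConfig(nPatients = nPatients, nPlanted = nPlanted,
                               rhoPlanted = rhoPlanted, nNoise = nNoise,
                               effectScale = effectScale,
                               seed = baseSeed + i - 1L, ...)
        sim <- simulateCohort(cfg)
        deltas <- objectiveDeltas(sim$cohort, sim$objectives)
        fronts <- nondominatedSort(deltas)
        clusters <- selectExtremeClusters(fronts, deltas, q = q)
        z <- rankNormalize(featureLogRatios(sim$cohort))
        st <- clusterFeatureStats(z, clusters)
        rks <- list(A1 = rankParameters(st, "A1"),
                    A2 = rankParameters(st, "A2"))
        rec <- evaluateRecovery(rks, sim$truth)
        perSeed[i] <- rec$recovery
        onF1 <- vapply(c(sim$truth$planted, sim$truth$noise), function(p) {
            any(vapply(rks, function(rk)
                any(rk$parameter == p & rk$front_number == 1L), TRUE))
        }, TRUE)
        f1count <- if (is.null(f1count)) as.integer(onF1)
                   else f1count + as.integer(onF1)
    }
    names(f1count) <- c(sprintf("planted_%02d", seq_len(nPlanted)),
                        sprintf("noise_%02d", seq_len(nNoise)))[
                            seq_along(f1count)]
    list(meanRecovery = mean(perSeed), perSeed = perSeed,
         front1Freq = f1count / nSeeds)
}
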