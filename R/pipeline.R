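#' @include synthetic.R association.R
NULL

#' Read a pipeline configuration file
#'
#' YAML with either a \code{cohort:} section (\code{path}, optional
#' \code{format}, \code{sep}) or a \code{synthetic:} section (arguments of
#' [syntheticConfig()]), plus optional top-level \code{q},
#' \code{pseudocount} (\code{half_min}/\code{exclude}) and
#' \code{objectives} (list of \code{name}/\code{direction} pairs;
#' defaults to the three-endpoint set).
#'
#' @param path YAML file path.
#' @return config list for [runMoa()].
#' @export
readMoaConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
}

.configObjectives <- function(config) {
    if (is.null(config$objectives)) return(defaultObjectives())
    objectiveSpecs(vapply(config$objectives, `[[`, "", "name"),
                   vapply(config$objectives, `[[`, "", "direction"))
}

.moaCore <- function(cohort, objectives, q, pseudocount) {
    deltas <- objectiveDeltas(cohort, objectives)
    fronts <- nondominatedSort(deltas)
    clusters <- selectExtremeClusters(fronts, deltas, q = q)
    ratios <- featureLogRatios(cohort, policy = pseudocount)
    z <- rankNormalize(ratios)
    st <- clusterFeatureStats(z, clusters)
    list(deltas = deltas, fronts = fronts, clusters = clusters,
         ratios = ratios, rankZ = z, stats = st,
         rankings = list(A1 = rankParameters(st, "A1"),
                         A2 = rankParameters(st, "A2")))
}

#' Run the full multiobjective analysis
#'
#' End-to-end: load or simulate the cohort, compute oriented endpoint
#' deltas and parameter log-ratios, nondominated-sort patients into
#' fronts, select the extreme best/worst clusters, rank-normalize the
#' log-ratios, compute within-cluster statistics and the second-stage
#' parameter rankings, and classify responders under both single-endpoint
#' rules. Deterministic for a fixed config.
#'
#' @param config a config list (see [readMoaConfig()]) or a path to a YAML
#'   config file.
#' @return a \linkS4class{MoaResult}.
#' @examples
#' res <- runMoa(list(synthetic = list(nPatients = 40, seed = 3), q = 0.2))
#' nFronts(moaFronts(res))
#' @export
runMoa <- function(config) {
    if (is.character(config)) config <- readMoaConfig(config)
    q <- if (is.null(config$q)) 0.2 else config$q
    pseudocount <- if (is.null(config$pseudocount)) "half_min"
                   else config$pseudocount
    if (!is.numeric(q) || q <= 0 || q > 0.5)
        stop("configuration error: q must be in (0, 0.5]")

    if (!is.null(config$synthetic)) {
        cfg <- do.call(syntheticConfig, config$synthetic)
        sim <- simulateCohort(cfg)
        cohort <- sim$cohort
        objectives <- sim$objectives
        seed <- cfg$seed
        input <- list(source = "synthetic", config = unclass(cfg))
    } else if (!is.null(config$cohort)) {
        objectives <- .configObjectives(config)
        cohort <- readCohort(config$cohort$path,
                             format = if (is.null(config$cohort$format))
                                 "auto" else config$cohort$format,
                             sep = config$cohort$sep,
                             objectives = objectives)
        seed <- NULL
        input <- list(source = "file", path = config$cohort$path,
                      sha = unname(tools::md5sum(config$cohort$path)))
    } else stop("config must contain a 'cohort' or 'synthetic' section")

    core <- .moaCore(cohort, objectives, q, pseudocount)
    responders <- list(
        strict_decrease = classifyResponders(cohort, "strict_decrease"),
        median_split_pct_change =
            classifyResponders(cohort, "median_split_pct_change"))

    manifest <- list(
        software = paste("MOAstrat",
                         as.character(utils::packageVersion("MOAstrat"))),
        input = input,
        objectives = objectives,
        q = q,
        target_cluster_size = length(core$clusters@best),
        pseudocount_policy = pseudocount,
        rounding = "cluster target size round-half-up",
        tie_break = "within-front sum of per-objective ranks",
        dominance = paste("standard Pareto dominance: x dominates y iff",
                          "x_i <= y_i for all i and x_j < y_j for some j",
                          "(canonical minimize orientation)"),
        seed = seed,
        counts = list(
            n_patients = nPatients(cohort),
            n_objective_rows = nrow(core$deltas@values),
            n_excluded = nrow(core$deltas@excluded),
            n_parameters = length(parameterNames(cohort)),
            n_fronts = core$fronts@nFronts,
            pseudocount_applications = nrow(core$ratios@policyLog),
            tie_events = nrow(core$clusters@ties)))

    new("MoaResult", cohort = cohort, deltas = core$deltas,
        ratios = core$ratios, fronts = core$fronts,
        clusters = core$clusters, responders = responders,
        rankZ = core$rankZ, stats = core$stats, rankings = core$rankings,
        manifest = manifest)
}

#' Accessors for MoaResult components
#' @param x a \linkS4class{MoaResult}.
#' @return the named component.
#' @name moaAccessors
NULL

#' @rdname moaAccessors
#' @export
moaFronts <- function(x) { stopifnot(is(x, "MoaResult")); x@fronts }

#' @rdname moaAccessors
#' @export
moaClusters <- function(x) { stopifnot(is(x, "MoaResult")); x@clusters }

#' @rdname moaAccessors
#' @export
moaRankings <- function(x) { stopifnot(is(x, "MoaResult")); x@rankings }

#' @rdname moaAccessors
#' @export
moaStats <- function(x) { stopifnot(is(x, "MoaResult")); x@stats }

#' @rdname moaAccessors
#' @export
moaManifest <- function(x) { stopifnot(is(x, "MoaResult")); x@manifest }

#' @rdname moaAccessors
#' @export
moaResponders <- function(x) { stopifnot(is(x, "MoaResult")); x@responders }

#' Write the full analysis bundle to a directory
#'
#' Writes \code{cohort.csv}, \code{fronts.csv} (+
#' \code{fronts_summary.json}), \code{clusters.csv} (+
#' \code{clusters_provenance.json}), \code{parameter_ranking.csv},
#' \code{responders.csv} and \code{manifest.json}. Outputs carry no
#' timestamps, so identical configs give byte-identical bundles. On error
#' any partially written file is removed.
#'
#' @param x a \linkS4class{MoaResult}.
#' @param dir output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
writeMoaBundle <- function(x, dir) {
    stopifnot(is(x, "MoaResult"))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- file.path(dir, c("cohort.csv", "fronts.csv",
                              "fronts_summary.json", "clusters.csv",
                              "clusters_provenance.json",
                              "parameter_ranking.csv", "responders.csv",
                              "responders_median_split.csv",
                              "manifest.json"))
    ok <- FALSE
    on.exit(if (!ok) unlink(files))
    writeCohort(x@cohort, files[1L])
    writeFronts(x@fronts, files[2L], summaryPath = files[3L])
    writeClusters(x@clusters, patientIds(x@deltas), files[4L],
                  provenancePath = files[5L])
    writeParameterRanking(x@rankings, files[6L])
    writeResponders(x@responders$strict_decrease, files[7L])
    writeResponders(x@responders$median_split_pct_change, files[8L])
    jsonlite::write_json(x@manifest, files[9L], auto_unbox = TRUE,
                         digits = NA, dataframe = "rows", force = TRUE)
    ok <- TRUE
    invisible(dir)
}
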