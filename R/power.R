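#' @include AllClasses.R
NULL

#' Power of a fixed-effects one-way ANOVA
#'
#' Power of the one-way fixed-effects ANOVA F test for Cohen's effect size
#' f, computed from the noncentral F distribution: with k groups and N
#' observations in total, the test statistic under the alternative is
#' noncentral F with df1 = k-1, df2 = N-k and noncentrality
#' \eqn{\lambda = f^2 N}, and power is the probability that it exceeds the
#' central-F critical value at level \code{alpha}.
#'
#' @param f Cohen's f effect size (>= 0).
#' @param alpha type-I error rate in (0, 1).
#' @param k number of groups (>= 2).
#' @param nTotal total sample size (> k).
#' @return achieved power in (0, 1).
#' @examples
#' anovaPower(f = 0.4, alpha = 0.05, k = 3, nTotal = 72)  # 0.8534928
#' @export
anovaPower <- function(f, alpha = 0.05, k, nTotal) {
    stopifnot(f >= 0, alpha > 0, alpha < 1, k >= 2)
    if (nTotal <= k)
        stop("nTotal must exceed k (df2 = nTotal - k must be positive)")
    df1 <- k - 1
    df2 <- nTotal - k
    crit <- stats::qf(1 - alpha, df1, df2)
    stats::pf(crit, df1, df2, ncp = f^2 * nTotal, lower.tail = FALSE)
}

#' A priori sample size for a one-way ANOVA
#'
#' Smallest total sample size whose [anovaPower()] reaches
#' \code{targetPower}, incremented to the next multiple of k when
#' \code{balanced} (equal group sizes) is requested.
#'
#' @param f Cohen's f effect size (> 0).
#' @param alpha type-I error rate.
#' @param k number of groups.
#' @param targetPower requested power in (0, 1).
#' @param balanced force \code{totalN} to a multiple of k (default TRUE).
#' @param nMax search bound (solver error beyond it).
#' @return a \linkS4class{PowerDesign}.
#' @examples
#' requiredSampleSize(f = 0.4, alpha = 0.05, k = 3, targetPower = 0.85)
#' @export
requiredSampleSize <- function(f, alpha = 0.05, k, targetPower,
                               balanced = TRUE, nMax = 1e6) {
    stopifnot(f > 0, targetPower > 0, targetPower < 1, k >= 2)
    n <- k + 1
    while (anovaPower(f, alpha, k, n) < targetPower) {
        n <- n + 1
        if (n > nMax)
            stop("target power unreachable within nTotal <= ", nMax)
    }
    if (balanced && n %% k != 0)
        n <- n + (k - n %% k)
    new("PowerDesign",
        effectSize = f, alpha = alpha, kGroups = as.integer(k),
        targetPower = targetPower, totalN = as.integer(n),
        achievedPower = anovaPower(f, alpha, k, n),
        balanced = isTRUE(balanced))
}

#' Total sample size of a PowerDesign
#' @param x a \linkS4class{PowerDesign}.
#' @return integer.
#' @export
totalN <- function(x) {
    stopifnot(is(x, "PowerDesign"))
    x@totalN
}

#' Achieved power of a PowerDesign
#' @param x a \linkS4class{PowerDesign}.
#' @return numeric.
#' @export
achievedPower <- function(x) {
    stopifnot(is(x, "PowerDesign"))
    x@achievedPower
}

#' Serialize a PowerDesign to JSON
#' @param x a \linkS4class{PowerDesign}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePowerDesign <- function(x, path) {
    stopifnot(is(x, "PowerDesign"))
    jsonlite::write_json(list(
        effect_size_f = x@effectSize, alpha = x@alpha, k_groups = x@kGroups,
        target_power = x@targetPower, total_n = x@totalN,
        achieved_power = x@achievedPower, balanced = x@balanced),
        path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
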