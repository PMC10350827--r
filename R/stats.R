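#' Cliff's delta dominance effect size
#'
#' d = [#(x_i > y_j) - #(x_i < y_j)] / (n m), in [-1, 1]. The magnitude is
#' banded into the conventional categories: negligible (|d| < 0.148), small
#' (|d| < 0.34), medium (|d| < 0.475), large otherwise; values falling in
#' the printed gaps of the banding convention (e.g. 0.335) resolve to the
#' lower category.
#'
#' @param x,y non-empty numeric samples.
#' @return list: \code{d}, \code{category}.
#' @examples
#' cliffsDelta(c(1, 2, 3), c(2, 3, 4))$d # -5/9
#' @export
cliffsDelta <- function(x, y) {
    if (!length(x) || !length(y)) stop("empty sample")
    # rank-based O((n+m) log(n+m)) dominance count
    r <- rank(c(x, y), ties.method = "average")
    rx <- sum(r[seq_along(x)])
    n <- length(x); m <- length(y)
    U <- rx - n * (n + 1) / 2            # #(x>y) + 0.5 #(x==y)
    d <- 2 * U / (n * m) - 1
    list(d = d, category = effectSizeCategory(d))
}

#' @rdname cliffsDelta
#' @param d signed Cliff's delta.
#' @export
effectSizeCategory <- function(d) {
    a <- abs(d)
    ifelse(a < 0.148, "negligible",
    ifelse(a < 0.34, "small",
    ifelse(a < 0.475, "medium", "large")))
}

#' Mann-Whitney U test
#'
#' Rank-sum test with midranks for ties. The exact permutation distribution
#' is used when n*m <= 64 and there are no ties; otherwise the normal
#' approximation with tie-corrected variance and continuity correction.
#'
#' @param x,y numeric samples.
#' @param alternative \code{"two.sided"} (default), \code{"less"},
#'   \code{"greater"}.
#' @return list: \code{U} (for x), \code{p}, \code{exact} (logical).
#' @export
mannWhitney <- function(x, y, alternative = "two.sided") {
    n <- length(x); m <- length(y)
    if (n < 1 || m < 1) stop("both samples must be non-empty")
    pooled <- c(x, y)
    ties <- anyDuplicated(pooled) > 0
    if (length(unique(pooled)) == 1) {
        warning("constant pooled sample; p = 1")
        return(list(U = n * m / 2, p = 1, exact = FALSE))
    }
    exact <- (n * m <= 64) && !ties
    wt <- suppressWarnings(
        wilcox.test(x, y, alternative = alternative,
                    exact = exact, correct = TRUE))
    list(U = unname(wt$statistic), p = wt$p.value, exact = exact)
}

#' Kruskal-Wallis one-way test
#'
#' Tie-corrected H statistic with a chi-square reference on k - 1 degrees
#' of freedom.
#'
#' @param groups list of two or more non-empty numeric samples.
#' @return list: \code{H}, \code{p}, \code{df}.
#' @export
kruskalWallis <- function(groups) {
    if (length(groups) < 2 || any(!lengths(groups)))
        stop("need >= 2 non-empty groups")
    pooled <- unlist(groups)
    if (length(unique(pooled)) == 1) {
        warning("all values identical; p = 1")
        return(list(H = 0, p = 1, df = length(groups) - 1))
    }
    kt <- kruskal.test(groups)
    list(H = unname(kt$statistic), p = kt$p.value,
         df = unname(kt$parameter))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement, capped at 1,
#' order preserved relative to the input.
#'
#' @param p numeric vector of raw p-values in [0, 1].
#' @return adjusted p-values, same order as input.
#' @export
bhAdjust <- function(p) {
    if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
        stop("p-values must lie in [0, 1]")
    p.adjust(p, method = "BH")
}

#' Spearman rank correlation with strength bands
#'
#' Midrank-based rho with a t-approximation p-value. The magnitude is
#' banded as very weak / weak / moderate / strong / very strong with
#' midpoint cut-points 0.195, 0.395, 0.595 and 0.795, so that every rho
#' maps to exactly one band.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return list: \code{rho}, \code{p}, \code{band}.
#' @examples
#' spearmanCor(1:4, c(1, 3, 2, 4))$rho # 0.8
#' @export
spearmanCor <- function(x, y) {
    n <- length(x)
    if (n < 3 || length(y) != n) stop("need paired samples with n >= 3")
    if (length(unique(x)) == 1 || length(unique(y)) == 1)
        stop("undefined rho for constant input")
    rho <- cor(rank(x), rank(y))
    if (abs(rho) >= 1) {
        p <- 0
    } else {
        tstat <- rho * sqrt((n - 2) / (1 - rho^2))
        p <- 2 * pt(-abs(tstat), df = n - 2)
    }
    list(rho = rho, p = p, band = spearmanBand(rho))
}

#' @rdname spearmanCor
#' @param rho correlation value.
#' @export
spearmanBand <- function(rho) {
    a <- abs(rho)
    ifelse(a < 0.195, "very weak",
    ifelse(a < 0.395, "weak",
    ifelse(a < 0.595, "moderate",
    ifelse(a < 0.795, "strong", "very strong"))))
}

#' Significance stars from FDR-adjusted p-values
#'
#' @param pFdr adjusted p-values.
#' @return character: \code{"***"} below 0.001, \code{"**"} below 0.01,
#'   \code{"*"} below 0.05, \code{"ns"} otherwise.
#' @export
significanceStars <- function(pFdr) {
    ifelse(pFdr < 0.001, "***",
    ifelse(pFdr < 0.01, "**",
    ifelse(pFdr < 0.05, "*", "ns")))
}

#' LMS growth-chart z-score
#'
#' Converts a measurement to a z-score against an LMS reference (skewness
#' power L, median M, coefficient of variation S, interpolated linearly in
#' age within sex): z = ((x/M)^L - 1) / (L S) for L away from zero, and the
#' log-limit z = ln(x/M) / S otherwise.
#'
#' @param x positive measurement.
#' @param ref \linkS4class{LMSReference}.
#' @param sex sex label matching the reference table.
#' @param age age in the reference's age units; must lie inside the grid
#'   (no extrapolation).
#' @return z-score.
#' @export
lmsZscore <- function(x, ref, sex, age) {
    stopifnot(is(ref, "LMSReference"), x > 0)
    tb <- ref@table[ref@table$sex == sex, , drop = FALSE]
    if (!nrow(tb)) stop("sex '", sex, "' not in reference")
    if (age < min(tb$age_weeks) || age > max(tb$age_weeks))
        stop("age ", age, " outside reference grid [",
             min(tb$age_weeks), ", ", max(tb$age_weeks), "]")
    L <- approx(tb$age_weeks, tb$L, age)$y
    M <- approx(tb$age_weeks, tb$M, age)$y
    S <- approx(tb$age_weeks, tb$S, age)$y
    if (abs(L) < 1e-7) log(x / M) / S else ((x / M)^L - 1) / (L * S)
}

#' Read an LMS reference table
#'
#' CSV with columns \code{sex}, \code{age_weeks}, \code{L}, \code{M},
#' \code{S}; one row per (sex, age) grid point, ages strictly increasing
#' within sex.
#'
#' @param file CSV path.
#' @return \linkS4class{LMSReference}.
#' @export
readLMSReference <- function(file) {
    tb <- read.csv(file, stringsAsFactors = FALSE)
    new("LMSReference", table = tb)
}
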