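#' Simple linear regression of z-scores on a covariate
#'
#' Ordinary least squares with one predictor, reporting slope, intercept,
#' R-squared, adjusted R-squared, the overall F statistic and its p-value.
#'
#' @param x,y numeric vectors, n >= 3, x not constant.
#' @return list: \code{slope}, \code{intercept}, \code{r2}, \code{adj_r2},
#'   \code{F}, \code{p}, \code{n}.
#' @export
olsFit <- function(x, y) {
    n <- length(x)
    if (n < 3 || length(y) != n) stop("need paired samples with n >= 3")
    if (var(x) == 0) stop("constant predictor")
    fit <- lm(y ~ x)
    # summary.lm warns on exact fits; an exact line is a legitimate input
    sm <- suppressWarnings(summary(fit))
    Fst <- if (is.null(sm$fstatistic)) NA_real_ else unname(sm$fstatistic[1])
    p <- if (is.na(Fst)) NA_real_ else
        pf(Fst, sm$fstatistic[2], sm$fstatistic[3], lower.tail = FALSE)
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r2 = sm$r.squared, adj_r2 = sm$adj.r.squared,
         F = Fst, p = unname(p), n = n)
}

# tau-weighted check loss
.checkLoss <- function(r, tau) {
    sum(r * (tau - (r < 0)))
}

# IRLS on the eps-smoothed check loss; returns c(intercept, slope).
# Fast path used inside bootstrap loops (no vertex polish).
.irlsQuantile <- function(x, y, tau, start, eps, maxIter = 30L) {
    a <- start[1]; b <- start[2]
    X <- cbind(1, x)
    for (it in seq_len(maxIter)) {
        r <- y - a - b * x
        w <- sqrt(ifelse(r >= 0, tau, 1 - tau) / pmax(abs(r), eps))
        cf <- tryCatch(.lm.fit(X * w, y * w)$coefficients,
                       error = function(e) NULL)
        if (is.null(cf) || any(!is.finite(cf))) break
        if (abs(cf[1] - a) + abs(cf[2] - b) < 1e-10) { a <- cf[1]; b <- cf[2]; break }
        a <- cf[1]; b <- cf[2]
    }
    c(a, b)
}

#' Quantile (check-loss) regression with one predictor
#'
#' Minimizes the asymmetric absolute-residual check loss
#' \eqn{\sum_i \rho_\tau(y_i - a - b x_i)}. An optimal line interpolates
#' two data points, so the fit is found by iteratively reweighted least
#' squares on a smoothed loss followed by an exact search over lines
#' through pairs of low-residual points (all pairs for small n); the
#' returned line achieves a check loss no larger than that of the OLS line.
#'
#' @param x,y numeric vectors, n >= 5.
#' @param tau quantile level in (0, 1); 0.5 gives the conditional median.
#' @return list: \code{slope}, \code{intercept}, \code{tau}, \code{loss},
#'   \code{n}.
#' @export
quantileFit <- function(x, y, tau = 0.5) {
    n <- length(x)
    if (n < 5 || length(y) != n) stop("need paired samples with n >= 5")
    if (tau <= 0 || tau >= 1) stop("tau must lie in (0, 1)")
    if (var(x) == 0) stop("constant predictor")

    loss <- function(a, b) .checkLoss(y - a - b * x, tau)
    ols <- coef(lm(y ~ x))
    best <- list(a = unname(ols[1]), b = unname(ols[2]))
    best$loss <- loss(best$a, best$b)

    # IRLS on the eps-smoothed check loss, warm-started at OLS
    eps <- 1e-6 * (sd(y) + 1e-12)
    ab <- .irlsQuantile(x, y, tau, c(best$a, best$b), eps, maxIter = 60L)
    l <- loss(ab[1], ab[2])
    if (is.finite(l) && l < best$loss)
        best <- list(a = ab[1], b = ab[2], loss = l)

    # exact vertex polish: an optimum passes through two data points
    cand <- if (n <= 60) seq_len(n) else
        order(abs(y - best$a - best$b * x))[seq_len(40)]
    for (i in seq_along(cand)) {
        for (j in seq_len(i - 1L)) {
            ii <- cand[i]; jj <- cand[j]
            dx <- x[ii] - x[jj]
            if (abs(dx) < 1e-12) next
            b2 <- (y[ii] - y[jj]) / dx
            a2 <- y[ii] - b2 * x[ii]
            l2 <- loss(a2, b2)
            if (l2 < best$loss - 1e-12)
                best <- list(a = a2, b = b2, loss = l2)
        }
    }
    if (!is.finite(best$loss))
        stop("quantile fit failed: non-finite loss (n = ", n, ", tau = ", tau, ")")
    list(slope = best$b, intercept = best$a, tau = tau,
         loss = best$loss, n = n)
}

#' AIC for a median (quantile) regression fit
#'
#' Under the asymmetric-Laplace working likelihood the deviance reduces to
#' a function of the mean check loss: AIC = 2k + 2n log(mean check loss)
#' with k = 2 (slope and intercept). Only differences between models fitted
#' to the same data are meaningful. A perfect fit (zero loss) is reported
#' as -Inf.
#'
#' @param fit result of \code{\link{quantileFit}}.
#' @return AIC value.
#' @export
medianAIC <- function(fit) {
    k <- 2
    n <- fit$n
    meanLoss <- fit$loss / n
    if (meanLoss <= 0) return(-Inf)
    2 * k + 2 * n * log(meanLoss)
}

#' Extra sum-of-squares F-test for slope and intercept differences
#'
#' Hierarchical comparison of two groups' simple linear regressions.
#' Slope test: separate slopes + intercepts (full) vs shared slope with
#' separate intercepts (reduced); F = [(SS_red - SS_full)/df_diff] /
#' [SS_full/df_full]. Intercept ("elevation") test, conditional on a shared
#' slope: shared-slope model vs one pooled line.
#'
#' @param xa,ya group A data; \code{xb,yb} group B data; each n >= 3.
#' @param xb,yb see above.
#' @param alpha significance level used only to label the preferred model.
#' @return list: \code{F_slope}, \code{p_slope}, \code{F_intercept},
#'   \code{p_intercept}, \code{model} (one of \code{"separate"},
#'   \code{"shared-slope"}, \code{"shared"}), residual sums of squares.
#' @export
extraSSFtest <- function(xa, ya, xb, yb, alpha = 0.05) {
    na <- length(xa); nb <- length(xb)
    if (na < 3 || nb < 3) stop("each group needs n >= 3")
    x <- c(xa, xb); y <- c(ya, yb)
    g <- factor(rep(c("a", "b"), c(na, nb)))
    rssFull <- sum(resid(lm(ya ~ xa))^2) + sum(resid(lm(yb ~ xb))^2)
    dfFull <- na + nb - 4
    if (rssFull <= .Machine$double.eps * (na + nb) * max(1, var(y)))
        stop("degenerate fit: zero residual sum of squares in the full model")
    rssShared <- sum(resid(lm(y ~ x + g))^2)       # common slope
    rssPooled <- sum(resid(lm(y ~ x))^2)           # one line
    Fslope <- ((rssShared - rssFull) / 1) / (rssFull / dfFull)
    pSlope <- pf(max(Fslope, 0), 1, dfFull, lower.tail = FALSE)
    dfShared <- na + nb - 3
    Fint <- ((rssPooled - rssShared) / 1) / (rssShared / dfShared)
    pInt <- pf(max(Fint, 0), 1, dfShared, lower.tail = FALSE)
    model <- if (pSlope < alpha) "separate"
             else if (pInt < alpha) "shared-slope" else "shared"
    list(F_slope = Fslope, p_slope = pSlope,
         F_intercept = Fint, p_intercept = pInt,
         model = model, rss_full = rssFull, rss_shared_slope = rssShared,
         rss_pooled = rssPooled, df_full = dfFull)
}

#' WBV-adjusted group median z-scores
#'
#' For each group, fits a median regression of a segment's z-scores on the
#' paired whole-brain-volume z-scores and reports the fitted value at WBV
#' z = 0 (the intercept) -- the group's median deviation at control-typical
#' brain size. When exactly two groups are present, the difference between
#' their adjusted medians is tested with a seeded subject-level bootstrap.
#'
#' @param zSegment,zWbv paired per-subject z-scores.
#' @param group group labels (factor or character).
#' @param nBoot bootstrap resamples (default 2000).
#' @param seed integer seed for the bootstrap.
#' @return list: \code{adjusted} (named per-group adjusted median z),
#'   \code{slope} (per-group median-regression slope), \code{p}
#'   (bootstrap two-sided p for the two-group difference, NA otherwise),
#'   \code{n} per group.
#' @export
wbvAdjustedMedian <- function(zSegment, zWbv, group,
                              nBoot = 2000L, seed = 1L) {
    group <- as.character(group)
    stopifnot(length(zSegment) == length(zWbv),
              length(group) == length(zSegment))
    levs <- unique(group)
    ns <- table(group)
    if (any(ns < 5)) stop("every group needs n >= 5")
    adjOne <- function(zs, zw) {
        f <- quantileFit(zw, zs, tau = 0.5)
        c(intercept = f$intercept, slope = f$slope)
    }
    fits <- vapply(levs, function(g)
        adjOne(zSegment[group == g], zWbv[group == g]),
        c(intercept = 0, slope = 0))
    adjusted <- setNames(fits["intercept", ], levs)
    slope <- setNames(fits["slope", ], levs)
    p <- NA_real_
    if (length(levs) == 2) {
        i1 <- which(group == levs[1]); i2 <- which(group == levs[2])
        # resampled intercepts use the IRLS fitter (no vertex polish):
        # orders of magnitude faster and accurate to far below the
        # bootstrap's own Monte-Carlo noise
        eps <- 1e-6 * (sd(zSegment) + 1e-12)
        start <- rbind(adjusted, slope)
        bootOne <- function(idx, col) {
            zs <- zSegment[idx]; zw <- zWbv[idx]
            if (var(zw) == 0) return(NA_real_)
            .irlsQuantile(zw, zs, 0.5, start[, col], eps)[1]
        }
        boot <- .withSeed(seed, {
            vapply(seq_len(nBoot), function(b) {
                bootOne(sample(i1, length(i1), replace = TRUE), 1) -
                bootOne(sample(i2, length(i2), replace = TRUE), 2)
            }, numeric(1))
        })
        boot <- boot[is.finite(boot)]
        # percentile-bootstrap two-sided p for H0: difference = 0
        pl <- (sum(boot <= 0) + 1) / (length(boot) + 1)
        pg <- (sum(boot >= 0) + 1) / (length(boot) + 1)
        p <- min(1, 2 * min(pl, pg))
    }
    list(adjusted = adjusted, slope = slope, p = p,
         n = as.list(ns)[levs])
}
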