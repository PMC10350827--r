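#' Fit normative models for a set of measures
#'
#' One independent Gaussian-process model per measure and volume type, all
#' trained on the control cohort. Each model's restart stream is derived
#' deterministically from the master seed and the measure's position, so
#' the fitted battery is reproducible.
#'
#' @param controls \linkS4class{VolumetricExperiment} of controls.
#' @param measures character vector of measure names (segments and/or
#'   aggregates for \code{"absolute"}; relative measures for
#'   \code{"relative"}).
#' @param type \code{"absolute"} or \code{"relative"}.
#' @param seed master seed.
#' @param restarts optimisation restarts per model.
#' @param verbose log one line per fitted measure.
#' @return named list of \linkS4class{NormativeModel}s.
#' @export
fitNormativeModels <- function(controls, measures,
                               type = c("absolute", "relative"),
                               seed = 1L, restarts = 5L, verbose = FALSE) {
    type <- match.arg(type)
    mm <- measureMatrix(controls, type)
    missing <- setdiff(measures, rownames(mm))
    if (length(missing))
        stop("unknown measure(s): ", paste(missing, collapse = ", "))
    subjects <- as.data.frame(SummarizedExperiment::colData(controls))
    models <- lapply(seq_along(measures), function(i) {
        m <- fitNormative(subjects, mm[measures[i], ], measure = measures[i],
                          seed = .subSeed(seed, i), restarts = restarts)
        if (verbose)
            message(sprintf("[fit] type=%s measure=%s n=%d logLik=%.2f",
                            type, measures[i], ncol(mm), m@logLik))
        m
    })
    names(models) <- measures
    models
}

#' Deviation z-scores for a cohort against a model battery
#'
#' @param models named list of fitted \linkS4class{NormativeModel}s.
#' @param ve cohort \linkS4class{VolumetricExperiment}.
#' @param type \code{"absolute"} or \code{"relative"}.
#' @param threshold extreme-deviation threshold (SD units).
#' @return long data.frame (one row per subject per measure) with the
#'   \code{\link{zscore}} columns.
#' @export
deviationScores <- function(models, ve, type = c("absolute", "relative"),
                            threshold = 2.6) {
    type <- match.arg(type)
    mm <- measureMatrix(ve, type)
    out <- lapply(names(models), function(m)
        zscore(models[[m]], ve, mm[m, ], type = type, threshold = threshold))
    do.call(rbind, out)
}

.zMatrix <- function(dev) {
    ids <- unique(dev$subject_id)
    ms <- unique(dev$measure)
    z <- matrix(NA_real_, length(ms), length(ids),
                dimnames = list(ms, ids))
    z[cbind(match(dev$measure, ms), match(dev$subject_id, ids))] <- dev$z
    z
}

#' Groupwise comparison of deviation z-scores
#'
#' For every measure, compares the atypical cohort's z-scores with the
#' control cohort's using the Mann-Whitney U test and Cliff's delta, with
#' Benjamini-Hochberg adjustment across the measures of the table (one FDR
#' family per call). Also counts extreme deviations per group.
#'
#' @param devControl,devAtypical long deviation-score tables from
#'   \code{\link{deviationScores}} covering the same measures.
#' @param alpha significance level on the adjusted p-values.
#' @return data.frame, one row per measure: group medians and IQRs, U,
#'   raw and FDR-adjusted p, Cliff's delta and category, significance
#'   flag and stars, extreme-deviation counts.
#' @export
compareGroups <- function(devControl, devAtypical, alpha = 0.05) {
    ms <- unique(devAtypical$measure)
    if (!length(ms)) stop("empty atypical deviation table")
    if (!all(ms %in% devControl$measure))
        stop("control deviations missing some measures")
    rows <- lapply(ms, function(m) {
        za <- devAtypical$z[devAtypical$measure == m]
        zc <- devControl$z[devControl$measure == m]
        if (!length(za)) stop("empty atypical group for measure ", m)
        mw <- mannWhitney(za, zc)
        cd <- cliffsDelta(za, zc)
        qa <- quantile(za, c(0.25, 0.5, 0.75), names = FALSE)
        qc <- quantile(zc, c(0.25, 0.5, 0.75), names = FALSE)
        data.frame(
            measure = m,
            median_atypical = qa[2], iqr_lo_atypical = qa[1],
            iqr_hi_atypical = qa[3],
            median_control = qc[2], iqr_lo_control = qc[1],
            iqr_hi_control = qc[3],
            U = mw$U, p_raw = mw$p,
            cliffs_delta = cd$d, effect_category = cd$category,
            n_extreme_atypical = sum(devAtypical$extreme[devAtypical$measure == m]),
            n_extreme_control = sum(devControl$extreme[devControl$measure == m]),
            stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$p_fdr <- bhAdjust(out$p_raw)
    out$significant <- out$p_fdr < alpha
    out$stars <- significanceStars(out$p_fdr)
    rownames(out) <- NULL
    out
}

#' Age-at-scan regression battery
#'
#' Per measure and group: OLS fit of deviation z-scores against PMA at
#' scan with quantile (quartile and median) fits and the median-fit AIC,
#' plus Spearman correlation with its strength band. When two groups are
#' compared, the extra sum-of-squares F-tests for slope and intercept
#' differences are reported with FDR adjustment across measures.
#'
#' @param dev long deviation-score table (both groups together).
#' @param subjects subject records carrying \code{pma_scan} and the group
#'   variable.
#' @param groupVar name of the grouping column (default \code{"group"}).
#' @param taus quantile levels (default 0.25, 0.5, 0.75).
#' @param dropOutliers if TRUE, points with |z| > 5 are excluded with a
#'   message (default FALSE).
#' @param alpha significance level.
#' @param minN groups smaller than this are skipped with a warning.
#' @return list: \code{regressions} (per measure x group),
#'   \code{slope_comparison} (per measure, when exactly two groups).
#' @export
ageRegression <- function(dev, subjects, groupVar = "group",
                          taus = c(0.25, 0.5, 0.75), dropOutliers = FALSE,
                          alpha = 0.05, minN = 3L) {
    if (is(subjects, "SummarizedExperiment"))
        subjects <- as.data.frame(SummarizedExperiment::colData(subjects))
    idx <- match(dev$subject_id, subjects$subject_id)
    if (anyNA(idx)) stop("deviation table contains unknown subject ids")
    dev$pma_scan <- subjects$pma_scan[idx]
    dev$.group <- as.character(subjects[[groupVar]][idx])
    if (dropOutliers) {
        drop <- abs(dev$z) > 5
        if (any(drop)) {
            message("excluding ", sum(drop), " outlier point(s) with |z| > 5")
            dev <- dev[!drop, , drop = FALSE]
        }
    }
    ms <- unique(dev$measure)
    groups <- sort(unique(dev$.group))
    reg <- NULL; cmp <- NULL
    for (m in ms) {
        dm <- dev[dev$measure == m, , drop = FALSE]
        for (g in groups) {
            dg <- dm[dm$.group == g, , drop = FALSE]
            if (nrow(dg) < max(minN, 5L)) {
                warning("measure ", m, ", group ", g,
                        ": n = ", nrow(dg), " too small, skipped")
                next
            }
            ols <- olsFit(dg$pma_scan, dg$z)
            sp <- spearmanCor(dg$pma_scan, dg$z)
            qrow <- list()
            for (tau in taus) {
                qf <- quantileFit(dg$pma_scan, dg$z, tau)
                qrow[[paste0("slope_tau", tau)]] <- qf$slope
                qrow[[paste0("intercept_tau", tau)]] <- qf$intercept
                if (tau == 0.5) qrow$aic_median <- medianAIC(qf)
            }
            reg <- rbind(reg, data.frame(
                measure = m, group = g, n = ols$n,
                slope = ols$slope, intercept = ols$intercept,
                r2 = ols$r2, adj_r2 = ols$adj_r2,
                F = ols$F, p = ols$p,
                rho = sp$rho, rho_p = sp$p, rho_band = sp$band,
                as.data.frame(qrow), stringsAsFactors = FALSE))
        }
        if (length(groups) == 2) {
            d1 <- dm[dm$.group == groups[1], ]
            d2 <- dm[dm$.group == groups[2], ]
            if (nrow(d1) >= 3 && nrow(d2) >= 3) {
                ft <- extraSSFtest(d1$pma_scan, d1$z, d2$pma_scan, d2$z,
                                   alpha = alpha)
                cmp <- rbind(cmp, data.frame(
                    measure = m,
                    F_slope = ft$F_slope, p_slope = ft$p_slope,
                    F_intercept = ft$F_intercept,
                    p_intercept = ft$p_intercept,
                    model = ft$model, stringsAsFactors = FALSE))
            }
        }
    }
    if (!is.null(cmp)) {
        cmp$p_slope_fdr <- bhAdjust(cmp$p_slope)
        cmp$p_intercept_fdr <- bhAdjust(cmp$p_intercept)
        cmp$stars_slope <- significanceStars(cmp$p_slope_fdr)
    }
    rownames(reg) <- NULL
    list(regressions = reg, slope_comparison = cmp)
}

#' Whole-brain-volume covariation analysis
#'
#' Pairs every segment with its whole-brain reference (tissue segments and
#' composites with TTV, lateral ventricles with TBV, extra-cerebral CSF
#' with ICV), regresses the segment's z-scores on the whole-brain z-scores
#' per group (OLS + quantile fits) and reports WBV-adjusted group median
#' z-scores (the median-regression fit at whole-brain z = 0), with a
#' seeded bootstrap p-value for the two-group difference and FDR
#' adjustment across measures.
#'
#' @param dev long deviation-score table covering the segment measures and
#'   the whole-brain measures (TTV, TBV, ICV) for all subjects.
#' @param measures segment measures to analyse.
#' @param groupVar grouping values, one per row of the z matrix columns;
#'   given as a named vector (names = subject ids) or looked up from
#'   \code{subjects}.
#' @param subjects optional subject records for group lookup.
#' @param taus quantile levels.
#' @param nBoot,seed bootstrap controls.
#' @return data.frame, one row per measure x group, with regression
#'   coefficients, adjusted median z, bootstrap p and FDR.
#' @export
covariationAnalysis <- function(dev, measures, subjects,
                                groupVar = "group",
                                taus = c(0.25, 0.5, 0.75),
                                nBoot = 2000L, seed = 1L) {
    if (is(subjects, "SummarizedExperiment"))
        subjects <- as.data.frame(SummarizedExperiment::colData(subjects))
    z <- .zMatrix(dev)
    need <- unique(relativeDenominator(measures))
    need <- need[!is.na(need)]
    missing <- setdiff(need, rownames(z))
    if (length(missing))
        stop("missing whole-brain measure(s) in deviation table: ",
             paste(missing, collapse = ", "))
    grp <- setNames(as.character(subjects[[groupVar]]),
                    subjects$subject_id)[colnames(z)]
    rows <- NULL; pvals <- NULL
    for (i in seq_along(measures)) {
        m <- measures[i]
        wb <- relativeDenominator(m)
        if (is.na(wb)) stop("measure ", m, " has no whole-brain pairing")
        zs <- z[m, ]; zw <- z[wb, ]
        adj <- wbvAdjustedMedian(zs, zw, grp, nBoot = nBoot,
                                 seed = .subSeed(seed, i))
        for (g in unique(grp)) {
            sel <- grp == g
            ols <- olsFit(zw[sel], zs[sel])
            qrow <- list()
            for (tau in taus) {
                qf <- quantileFit(zw[sel], zs[sel], tau)
                qrow[[paste0("slope_tau", tau)]] <- qf$slope
                qrow[[paste0("intercept_tau", tau)]] <- qf$intercept
                if (tau == 0.5) qrow$aic_median <- medianAIC(qf)
            }
            rows <- rbind(rows, data.frame(
                measure = m, wbv = wb, group = g, n = sum(sel),
                slope = ols$slope, intercept = ols$intercept,
                r2 = ols$r2, adj_r2 = ols$adj_r2, F = ols$F, p = ols$p,
                adjusted_median_z = unname(adj$adjusted[g]),
                p_boot = adj$p,
                as.data.frame(qrow), stringsAsFactors = FALSE))
        }
        pvals <- c(pvals, adj$p)
    }
    padj <- bhAdjust(pvals)
    rows$p_boot_fdr <- padj[match(rows$measure, measures)]
    rownames(rows) <- NULL
    rows
}

#' Run the full normative-volumetry pipeline
#'
#' End-to-end orchestration: fit the normative battery on the controls,
#' score both cohorts, and write the aggregate, relative-volume, z-score,
#' group-comparison, age-regression, slope-comparison and covariation
#' reports as CSV files, plus a JSON run manifest. All randomness derives
#' from \code{seed}.
#'
#' @param controls,atypical \linkS4class{VolumetricExperiment}s.
#' @param outDir output directory (created if needed).
#' @param measures absolute measures to model (default: the 21 segment
#'   measures).
#' @param relativeMeasures relative measures to model (default: none, for
#'   speed; pass e.g. \code{segmentNames()}).
#' @param seed master seed.
#' @param restarts GP restarts per measure.
#' @param threshold extreme-deviation threshold.
#' @param alpha significance level.
#' @param taus quantile levels.
#' @param nBoot covariation bootstrap resamples.
#' @param subgroupVar optional column of the atypical colData defining a
#'   within-atypical subgroup contrast (e.g. \code{"chd"}).
#' @param dropOutliers forwarded to \code{\link{ageRegression}}.
#' @param covariation run the WBV covariation analysis (default TRUE).
#' @param verbose log progress lines.
#' @return invisibly, a list with every report table and the manifest.
#' @export
runNormativePipeline <- function(controls, atypical, outDir,
                                 measures = requiredSegmentNames(),
                                 relativeMeasures = character(0),
                                 seed = 1L, restarts = 5L, threshold = 2.6,
                                 alpha = 0.05, taus = c(0.25, 0.5, 0.75),
                                 nBoot = 2000L, subgroupVar = NULL,
                                 dropOutliers = FALSE, covariation = TRUE,
                                 verbose = FALSE) {
    if (ncol(atypical) == 0) stop("empty atypical group")
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    wbv <- c("TTV", "TBV", "ICV")
    fitMeasures <- union(measures, wbv)

    models <- fitNormativeModels(controls, fitMeasures, "absolute",
                                 seed = seed, restarts = restarts,
                                 verbose = verbose)
    devC <- deviationScores(models, controls, "absolute", threshold)
    devA <- deviationScores(models, atypical, "absolute", threshold)
    write.csv(devA, file.path(outDir, "zscores_atypical_absolute.csv"),
              row.names = FALSE)
    write.csv(devC, file.path(outDir, "zscores_control_absolute.csv"),
              row.names = FALSE)
    write.csv(data.frame(subject_id = colnames(atypical),
                         t(computeAggregates(atypical)), check.names = FALSE),
              file.path(outDir, "aggregates_atypical.csv"), row.names = FALSE)
    write.csv(data.frame(subject_id = colnames(atypical),
                         t(computeRelative(atypical)), check.names = FALSE),
              file.path(outDir, "relative_volumes_atypical.csv"),
              row.names = FALSE)

    selC <- devC[devC$measure %in% measures, ]
    selA <- devA[devA$measure %in% measures, ]
    comparison <- compareGroups(selC, selA, alpha = alpha)
    write.csv(comparison, file.path(outDir, "comparison_absolute.csv"),
              row.names = FALSE)

    comparisonRel <- NULL
    if (length(relativeMeasures)) {
        modelsR <- fitNormativeModels(controls, relativeMeasures, "relative",
                                      seed = .subSeed(seed, 7777L),
                                      restarts = restarts, verbose = verbose)
        devCR <- deviationScores(modelsR, controls, "relative", threshold)
        devAR <- deviationScores(modelsR, atypical, "relative", threshold)
        comparisonRel <- compareGroups(devCR, devAR, alpha = alpha)
        write.csv(comparisonRel, file.path(outDir, "comparison_relative.csv"),
                  row.names = FALSE)
    }

    allSubjects <- rbind(
        as.data.frame(SummarizedExperiment::colData(controls))[
            , c("subject_id", "pma_scan", "group")],
        as.data.frame(SummarizedExperiment::colData(atypical))[
            , c("subject_id", "pma_scan", "group")])
    devAll <- rbind(selC, selA)
    age <- ageRegression(devAll, allSubjects, groupVar = "group",
                         taus = taus, dropOutliers = dropOutliers,
                         alpha = alpha)
    write.csv(age$regressions, file.path(outDir, "age_regression.csv"),
              row.names = FALSE)
    if (!is.null(age$slope_comparison))
        write.csv(age$slope_comparison,
                  file.path(outDir, "age_slope_comparison.csv"),
                  row.names = FALSE)

    ageSub <- NULL
    if (!is.null(subgroupVar)) {
        cdA <- as.data.frame(SummarizedExperiment::colData(atypical))
        if (!subgroupVar %in% colnames(cdA))
            stop("subgroup variable '", subgroupVar, "' absent")
        cdA$.sub <- ifelse(cdA[[subgroupVar]],
                           paste0(subgroupVar, "+"), paste0(subgroupVar, "-"))
        ageSub <- ageRegression(selA[, ],
                                cdA[, c("subject_id", "pma_scan", ".sub")],
                                groupVar = ".sub", taus = taus,
                                dropOutliers = dropOutliers, alpha = alpha)
        write.csv(ageSub$regressions,
                  file.path(outDir, "age_regression_subgroup.csv"),
                  row.names = FALSE)
        if (!is.null(ageSub$slope_comparison))
            write.csv(ageSub$slope_comparison,
                      file.path(outDir, "age_slope_comparison_subgroup.csv"),
                      row.names = FALSE)
    }

    covar <- NULL
    if (covariation) {
        segMeasures <- intersect(measures, requiredSegmentNames())
        devFull <- rbind(devC, devA)   # keeps the whole-brain (TTV/TBV/ICV) rows
        covar <- covariationAnalysis(devFull, segMeasures, allSubjects,
                                     groupVar = "group", taus = taus,
                                     nBoot = nBoot, seed = .subSeed(seed, 31L))
        write.csv(covar, file.path(outDir, "covariation.csv"),
                  row.names = FALSE)
    }

    manifest <- list(
        seed = seed, restarts = restarts, threshold = threshold,
        alpha = alpha, taus = taus, n_boot = nBoot,
        n_control = ncol(controls), n_atypical = ncol(atypical),
        measures = measures, relative_measures = relativeMeasures,
        package_version = as.character(utils::packageVersion("NeoVolNorm")))
    jsonlite::write_json(manifest, file.path(outDir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(list(models = models, comparison = comparison,
                   comparison_relative = comparisonRel,
                   age = age, age_subgroup = ageSub,
                   covariation = covar, manifest = manifest))
}

#' Read an analysis configuration file
#'
#' YAML file mapping the pipeline's arguments: input CSV paths
#' (\code{volumes}, \code{demographics} for each cohort), \code{measures},
#' \code{seed}, \code{threshold}, \code{alpha}, \code{taus},
#' \code{n_boot}, \code{subgroup}, \code{outlier_rule}, \code{out_dir}.
#' \code{defaultAnalysisConfig()} returns the defaults.
#'
#' @param file YAML path.
#' @return named list of configuration values.
#' @export
readAnalysisConfig <- function(file) {
    cfg <- yaml::read_yaml(file)
    modifyList(defaultAnalysisConfig(), cfg)
}

#' @rdname readAnalysisConfig
#' @export
defaultAnalysisConfig <- function() {
    list(measures = requiredSegmentNames(),
         relative_measures = character(0),
         seed = 1L, restarts = 5L, threshold = 2.6, alpha = 0.05,
         taus = c(0.25, 0.5, 0.75), n_boot = 2000L,
         subgroup = NULL, outlier_rule = FALSE, out_dir = "reports")
}
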