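#' Specification of a synthetic neonatal cohort
#'
#' Describes the study conditions emulated by the generator: cohort size,
#' preterm fraction, sex ratio, the PMA-at-scan window, and per-segment
#' logistic growth parameters (asymptote, growth rate, inflection week,
#' multiplicative sex offset and coefficient of variation of the
#' heteroscedastic noise). Defaults mirror a preterm-to-term reference
#' cohort: 17.5\% preterm, 49.3\% female, 11.2\% non-singleton, scans
#' between 31 and 46 weeks PMA.
#'
#' @param n number of subjects.
#' @param seed integer master seed; each subject draws from its own
#'   sub-stream so extending the cohort never reshuffles earlier subjects.
#' @param preterm_fraction probability of preterm birth (GA < 37 weeks).
#' @param sex_ratio probability of female sex.
#' @param nonsingleton_fraction probability of a non-singleton pregnancy.
#' @param pma_range scan-age window in weeks.
#' @param sex_offset male/female multiplicative volume offset (fraction).
#' @param cv coefficient of variation of the volume noise (SD = cv * mean).
#' @param growth optional data.frame overriding the per-segment growth
#'   table (columns \code{segment}, \code{vmax}, \code{rate}, \code{t0},
#'   \code{sex_offset}, \code{cv}).
#' @return a \code{CohortSpec} list.
#' @examples
#' spec <- cohortSpec(n = 100, seed = 1)
#' ve <- generateControls(spec)
#' @export
cohortSpec <- function(n = 500L, seed = 1L, preterm_fraction = 0.175,
                       sex_ratio = 0.493, nonsingleton_fraction = 0.112,
                       pma_range = c(31, 46), sex_offset = 0.06,
                       cv = 0.08, growth = NULL) {
    stopifnot(n >= 0, preterm_fraction >= 0, preterm_fraction <= 1,
              sex_ratio >= 0, sex_ratio <= 1,
              nonsingleton_fraction >= 0, nonsingleton_fraction <= 1,
              length(pma_range) == 2, pma_range[1] < pma_range[2],
              cv > 0, sex_offset >= 0)
    if (is.null(growth)) growth <- .defaultGrowthTable(sex_offset, cv)
    if (any(growth$vmax <= 0)) stop("growth asymptotes must be positive")
    if (any(growth$cv <= 0)) stop("noise CV must be positive")
    structure(list(n = as.integer(n), seed = as.integer(seed),
                   preterm_fraction = preterm_fraction,
                   sex_ratio = sex_ratio,
                   nonsingleton_fraction = nonsingleton_fraction,
                   pma_range = pma_range, growth = growth),
              class = "CohortSpec")
}

# term-age magnitudes and growth ratios of realistic order: TTV of a few
# hundred cm^3 at 40 weeks, roughly doubling from 31 to 46 weeks; the
# cerebellum grows faster in this window (~3x) and eCSF is much flatter
.defaultGrowthTable <- function(sex_offset = 0.06, cv = 0.08) {
    vmax <- c(
        frontal_gm = 64, frontal_wm = 53, temporal_gm = 39, temporal_wm = 29,
        parietal_gm = 44, parietal_wm = 38, occipital_gm = 24,
        occipital_wm = 17, insula_gm = 7.3, insula_wm = 6,
        cingulate_gm = 8.5, cingulate_wm = 6.8, cerebellum = 30,
        brainstem = 7.3, caudate = 4.3, lentiform = 5.5, thalamus = 8.5,
        hippocampus = 2.7, amygdala = 1.8,
        ecsf = 58, lateral_ventricles = 3.9)
    g <- data.frame(segment = names(vmax), vmax = unname(vmax),
                    rate = 0.18, t0 = 34, sex_offset = sex_offset, cv = cv)
    g$rate[g$segment == "cerebellum"] <- 0.24
    g$t0[g$segment == "cerebellum"] <- 36
    g$rate[g$segment == "ecsf"] <- 0.10
    g$t0[g$segment == "ecsf"] <- 30
    g
}

.logisticMean <- function(pma, vmax, rate, t0) {
    vmax / (1 + exp(-rate * (pma - t0)))
}

#' Generate a synthetic control cohort
#'
#' Gestational age at birth is drawn from a two-component preterm/term
#' mixture honouring the preterm fraction; PMA at scan is drawn inside the
#' spec's window subject to PMA >= GA; per-segment volumes follow logistic
#' growth in PMA with a multiplicative sex offset and heteroscedastic
#' Gaussian noise (SD proportional to the mean). Aggregates are computed
#' from the segments, so sum constraints hold by construction. Fully
#' reproducible from the spec's seed.
#'
#' @param spec a \code{\link{cohortSpec}}.
#' @param group group label for the generated subjects.
#' @param idPrefix subject-id prefix.
#' @param streamOffset integer offset of the per-subject seed sub-streams
#'   (used to draw independent cohorts from one spec).
#' @return a \linkS4class{VolumetricExperiment}.
#' @export
generateControls <- function(spec, group = "control", idPrefix = "C",
                             streamOffset = 0L) {
    stopifnot(inherits(spec, "CohortSpec"))
    n <- spec$n
    g <- spec$growth
    segs <- g$segment
    vol <- matrix(NA_real_, nrow = length(segs), ncol = n,
                  dimnames = list(segs,
                                  if (n) sprintf("%s%04d", idPrefix, seq_len(n))))
    sex <- character(n); ga <- numeric(n); pma <- numeric(n)
    singleton <- logical(n)
    for (i in seq_len(n)) {
        s <- .withSeed(.subSeed(spec$seed, i + streamOffset), {
            sx <- if (runif(1) < spec$sex_ratio) "female" else "male"
            preterm <- runif(1) < spec$preterm_fraction
            gai <- if (preterm) {
                repeat { v <- rnorm(1, 33, 2.5); if (v >= 24 && v < 37) break }
                v
            } else {
                repeat { v <- rnorm(1, 39.7, 1.2); if (v >= 37 && v <= 43) break }
                v
            }
            lo <- spec$pma_range[1]; hi <- spec$pma_range[2]
            # preterm neonates are scanned either soon after birth or at
            # term-equivalent age; term neonates within a few weeks of birth
            early <- preterm && runif(1) < 0.4
            ok <- FALSE
            for (try in seq_len(30)) {
                pmai <- if (early) gai + 0.3 + rexp(1, 1 / 2.5)
                        else rnorm(1, 40.9, 2.6)
                if (pmai >= max(lo, gai + 0.3) && pmai <= hi) { ok <- TRUE; break }
            }
            if (!ok) pmai <- min(max(lo, gai + 0.3), hi)
            sg <- runif(1) >= spec$nonsingleton_fraction
            mult <- if (sx == "male") 1 + g$sex_offset / 2 else 1 - g$sex_offset / 2
            mu <- .logisticMean(pmai, g$vmax, g$rate, g$t0) * mult
            v <- rnorm(length(mu), mu, g$cv * mu)
            v <- pmax(v, 0.02 * mu)
            list(sex = sx, ga = gai, pma = pmai, singleton = sg, vol = v)
        })
        sex[i] <- s$sex; ga[i] <- s$ga; pma[i] <- s$pma
        singleton[i] <- s$singleton
        vol[, i] <- s$vol
    }
    subjects <- data.frame(
        subject_id = if (n) colnames(vol) else character(0),
        sex = sex, ga_birth = ga,
        pma_scan = pma, age_from_birth = pma - ga,
        group = rep(group, n), singleton = singleton,
        stringsAsFactors = FALSE)
    VolumetricExperiment(vol, subjects)
}

#' Specification of injected deviations for an atypical cohort
#'
#' Per-measure ground-truth deviations in predictive-SD units: a constant
#' mean shift plus an optional age-interaction slope (SD per week of PMA,
#' centred at 40 weeks) emulating a gradual deviation from the control
#' mean with advancing scan age.
#'
#' @param measure character vector of segment names.
#' @param mean_shift numeric, SD units (recycled).
#' @param age_slope_shift numeric, SD units per week (recycled, default 0).
#' @return data.frame with one row per deviated measure.
#' @export
deviationSpec <- function(measure, mean_shift, age_slope_shift = 0) {
    stopifnot(all(is.finite(mean_shift)), all(is.finite(age_slope_shift)))
    data.frame(measure = measure, mean_shift = mean_shift,
               age_slope_shift = age_slope_shift,
               stringsAsFactors = FALSE)
}

#' Generate a synthetic atypical cohort with known deviations
#'
#' Subjects are drawn exactly as controls (from an independent seed
#' sub-stream of the same spec), then each deviated measure is shifted by
#' \code{(mean_shift + age_slope_shift * (PMA - 40)) * predicted_sd} at
#' that subject's covariates, using the supplied control-fitted normative
#' models as the SD reference. The injected shifts are returned as a truth
#' table alongside the cohort.
#'
#' @param spec a \code{\link{cohortSpec}} (the same one the control models
#'   were trained on).
#' @param dev a \code{\link{deviationSpec}}.
#' @param models named list of fitted \linkS4class{NormativeModel}s
#'   covering every deviated measure.
#' @param n cohort size (default 25).
#' @param chd_fraction probability of a CHD flag (default 0.52).
#' @param preterm_fraction preterm-birth probability of the atypical
#'   cohort (default 0.40; clinical atypical cohorts are born earlier
#'   than reference cohorts).
#' @param sex_ratio probability of female sex (default 0.48).
#' @param group group label.
#' @param streamOffset sub-stream offset; defaults past the control stream.
#' @return list: \code{cohort} (a \linkS4class{VolumetricExperiment}),
#'   \code{truth} (data.frame subject_id, measure, injected_shift).
#' @export
generateAtypical <- function(spec, dev, models, n = 25L,
                             chd_fraction = 0.52, preterm_fraction = 0.40,
                             sex_ratio = 0.48, group = "atypical",
                             streamOffset = 1000000L) {
    stopifnot(inherits(spec, "CohortSpec"))
    missing <- setdiff(dev$measure, names(models))
    if (length(missing))
        stop("no fitted model for deviated measure(s): ",
             paste(missing, collapse = ", "))
    base <- spec; base$n <- as.integer(n)
    base$preterm_fraction <- preterm_fraction
    base$sex_ratio <- sex_ratio
    class(base) <- "CohortSpec"
    ve <- generateControls(base, group = group, idPrefix = "A",
                           streamOffset = streamOffset)
    subjects <- as.data.frame(SummarizedExperiment::colData(ve))
    subjects$chd <- .withSeed(.subSeed(spec$seed, streamOffset),
                              runif(nrow(subjects)) < chd_fraction)
    vol <- SummarizedExperiment::assay(ve, "volumes")
    truth <- NULL
    for (k in seq_len(nrow(dev))) {
        ms <- dev$measure[k]
        if (!ms %in% rownames(vol))
            stop("deviated measure '", ms, "' is not a base segment")
        pr <- predictNormative(models[[ms]], subjects)
        shift <- (dev$mean_shift[k] +
                  dev$age_slope_shift[k] * (subjects$pma_scan - 40)) *
                 pr$predicted_sd
        vol[ms, ] <- pmax(vol[ms, ] + shift, 0)
        truth <- rbind(truth, data.frame(
            subject_id = colnames(vol), measure = ms,
            injected_shift = shift, stringsAsFactors = FALSE))
    }
    list(cohort = VolumetricExperiment(vol, subjects),
         truth = truth)
}

#' @rdname generateAtypical
#' @param truth a truth table as returned in the \code{truth} element.
#' @param file output CSV path.
#' @export
writeTruthTable <- function(truth, file) {
    write.csv(truth, file, row.names = FALSE)
    invisible(file)
}
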